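mk_profile <- function(intensity, z_step = 10) {
  spheroidal:::new_axial_profile(seq_along(intensity) * z_step - z_step,
                                 intensity, z_step)
}

test_that("attenuation percentage is 100 I/I_max", {
  p <- mk_profile(rep(40, 6))
  expect_equal(attenuation_percentage(p), rep(100, 6))
  p2 <- mk_profile(c(10, 100, 50, 25))
  expect_equal(attenuation_percentage(p2), c(10, 100, 50, 25))
  expect_true(max(attenuation_percentage(p2)) == 100)
  p0 <- mk_profile(rep(0, 4))
  expect_error(attenuation_percentage(p0), "positive")
})

test_that("analyzable depth matches the Beer-Lambert closed form", {
  mu <- 0.01
  z <- seq(0, 300, by = 2)
  inten <- 1000 * exp(-mu * pmax(z - 20, 0)) * pmin(z / 20, 1)  # rising flank
  prof <- spheroidal:::new_axial_profile(z, inten, 2)
  d <- analyzable_depth(prof, 50, z_top = 20)
  # 50% crossing at ln 2 / mu past the maximum (corner rounding from the
  # one-sample smoothing shifts it by a few samples)
  expect_lt(abs((d$z_analyzable - d$z_ref) - log(2) / mu), 6)
  expect_false(d$uncapped)

  # never dropping below p_min -> extends to the last sample, uncapped
  shallow <- analyzable_depth(mk_profile(seq(100, 91, by = -1)), 50, z_top = 0)
  expect_true(shallow$uncapped)
  expect_equal(shallow$z_analyzable, 90)

  expect_error(analyzable_depth(prof, 0, z_top = 20), "strictly between")
  expect_error(analyzable_depth(prof, 100, z_top = 20), "strictly between")
})

test_that("depth is monotone non-increasing in p_min", {
  mu <- 0.02
  z <- seq(0, 250, by = 5)
  prof <- spheroidal:::new_axial_profile(z, 800 * exp(-mu * pmax(z - 30, 0)), 5)
  depths <- vapply(seq(10, 90, by = 10),
                   function(p) analyzable_depth(prof, p, z_top = 30)$depth,
                   numeric(1))
  expect_true(all(diff(depths) <= 0))
})

test_that("a z_limit reclassifies tissue-boundary crossings as uncapped", {
  mu <- 0.005
  z <- seq(0, 200, by = 10)
  inten <- 1000 * exp(-mu * pmax(z - 50, 0))
  inten[z > 150] <- 5  # tissue ends at 150; signal collapses to background
  prof <- spheroidal:::new_axial_profile(z, inten, 10)
  free <- analyzable_depth(prof, 50, z_top = 50)
  expect_false(free$uncapped)  # crossing exists, caused by the bottom edge
  capped <- analyzable_depth(prof, 50, z_top = 50, z_limit = 150, z_margin = 10)
  expect_true(capped$uncapped)
  expect_equal(capped$depth, 100)
})

test_that("visibility classes follow the vertical-diameter comparison", {
  expect_equal(classify_visibility(30, 80)$class, "full")
  expect_equal(classify_visibility(30, 40)$class, "half")
  expect_equal(classify_visibility(30, 20)$class, "not_analyzable")
  # equality joins the more permissive class
  expect_equal(classify_visibility(30, 60)$class, "full")
  expect_equal(classify_visibility(30, 30)$class, "half")
  # the three classes partition all (c, depth) combinations
  set.seed(41)
  for (i in 1:50) {
    cls <- classify_visibility(runif(1, 5, 60), runif(1, 0, 150))$class
    expect_true(cls %in% visibility_classes())
  }
})

test_that("simulated attenuation recovers the 50% depth at ln2/mu", {
  for (seed in c(7, 23)) {
    sc <- generate_scene(scene_spec(
      volume_shape = c(48, 96, 96), z_step = 5, mu = 0.01,
      background_level = 5, noise_sd = 2, texture_strength = 0.05,
      seed = seed, centers = matrix(c(60, 60, 120), 1), radii = 50))
    proj <- compute_projection(sc$stable)
    seg <- segment_spheroids(proj)
    m <- mask_from_labels(seg$labels, 1)
    f <- fit_ellipse(m, 1.3)
    e <- extrapolate_ellipsoid(f, m, proj, sc$stable)
    d <- analyzable_depth(e$profile, 50, z_limit = e$center["z"] + e$c,
                          z_margin = 5)
    expect_lt(abs((d$z_analyzable - d$z_ref) - log(2) / 0.01), 5)
  }
})

test_that("without attenuation every fitting spheroid is fully visible", {
  for (seed in c(7, 11, 23)) {
    sc <- sphere_scene(radius = 50, mu = 0, seed = seed)
    res <- run_pipeline(sc$stable, sc$marker, run_config(min_circularity = 0.6))
    expect_equal(res$spheroids$visibility[1], "full")
  }
})
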