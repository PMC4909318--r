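test_that("scenes are bit-identical for a fixed seed", {
  spec <- scene_spec(seed = 4)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$stable$voxels, b$stable$voxels)
  expect_identical(a$marker$voxels, b$marker$voxels)
  expect_identical(a$truth$spots, b$truth$spots)
})

test_that("positive-cell count is exact without a spacing constraint", {
  for (pf in c(0.1, 0.25)) {
    sc <- generate_scene(scene_spec(volume_shape = c(16, 80, 80),
                                    n_spheroids = 1, radius_range = c(30, 30),
                                    positive_fraction = pf, seed = 8))
    expect_equal(nrow(sc$truth$spots), round(pf * sc$truth$n_cells))
  }
})

test_that("spaced positives respect the hard-core distance", {
  sc <- half_scene(3)
  p <- sc$truth$spots
  if (nrow(p) > 1) {
    d <- as.matrix(dist(p[, c("x", "y", "z")]))
    expect_gte(min(d[upper.tri(d)]), 18)
  }
})

test_that("every true spot lies inside its spheroid", {
  sc <- generate_scene(scene_spec(volume_shape = c(20, 128, 128),
                                  n_spheroids = 2, radius_range = c(25, 40),
                                  seed = 14))
  e <- sc$truth$ellipsoids
  p <- sc$truth$spots
  for (i in seq_len(nrow(p))) {
    k <- p$spheroid[i]
    r2 <- ((p$x[i] - e$x[k]) / e$a[k])^2 + ((p$y[i] - e$y[k]) / e$b[k])^2 +
      ((p$z[i] - e$z[k]) / e$c[k])^2
    expect_lte(r2, 1)
  }
})

test_that("true 2D masks are the voxelization's projection", {
  sc <- generate_scene(scene_spec(volume_shape = c(16, 96, 96),
                                  n_spheroids = 2, radius_range = c(20, 30),
                                  seed = 15))
  proj_any <- apply(sc$truth$label_volume > 0, c(2, 3), any)
  expect_equal(sc$truth$masks > 0, proj_any)
})

test_that("without absorption the two spheroid halves are equally bright", {
  sc <- sphere_scene(radius = 45, mu = 0, seed = 16, zc = 110)
  lv <- sc$truth$label_volume
  zs <- 10
  z_idx <- slice.index(lv, 1)
  zc_slice <- 110 / zs + 1
  top <- sc$stable$voxels[lv > 0 & z_idx < zc_slice]
  bottom <- sc$stable$voxels[lv > 0 & z_idx > zc_slice]
  expect_lt(abs(mean(top) - mean(bottom)) / mean(top), 0.1)
})

test_that("the center profile's 50% depth follows Beer-Lambert", {
  mu <- 0.01
  sc <- generate_scene(scene_spec(
    volume_shape = c(48, 96, 96), z_step = 5, mu = mu,
    background_level = 5, noise_sd = 2, texture_strength = 0.05,
    seed = 17, centers = matrix(c(60, 60, 120), 1), radii = 50))
  prof <- axial_profile(sc$stable, 60 / 1.3, 60 / 1.3)
  d <- analyzable_depth(prof, 50, z_top = 70)
  expect_lt(abs((d$z_analyzable - d$z_ref) - log(2) / mu), 5)
})

test_that("infeasible placements fail loudly", {
  expect_error(generate_scene(scene_spec(volume_shape = c(10, 40, 40),
                                         n_spheroids = 1,
                                         radius_range = c(60, 60), seed = 1)),
               "does not fit")
  expect_error(generate_scene(scene_spec(volume_shape = c(20, 100, 100),
                                         n_spheroids = 8,
                                         radius_range = c(40, 45), seed = 1)),
               "could not place|does not fit")
})
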