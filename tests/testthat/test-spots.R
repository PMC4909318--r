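test_that("the optimal LoG scale tracks blob size", {
  grid <- log_scale_grid()
  step <- grid[2] / grid[1]
  for (s in c(2, 3, 5)) {
    o <- optimal_log_scale(blob_image(s), max_spot_radius = 8, pixel_size_xy = 1)
    expect_lt(abs(log(o$sigma / s)), log(step) * 1.01)
  }
  for (r in c(4, 6)) {
    o <- optimal_log_scale(disk_image(r), max_spot_radius = 8, pixel_size_xy = 1)
    expect_lt(abs(log(o$sigma / (r / sqrt(2)))), log(step) * 1.01)
  }
  m <- blob_image(3)
  expect_equal(optimal_log_scale(m, 8, 1)$sigma,
               optimal_log_scale(2 * m, 8, 1)$sigma)
  expect_error(optimal_log_scale(matrix(5, 20, 20), 8, 1), "constant")
})

test_that("spot detection finds isolated nuclei and respects merging", {
  one <- spaced_nuclei(1, 20, seed = 51)
  sp <- detect_spots(one$stack, spot_params(scale_sigma = 3,
                                            intensity_threshold = 200))
  expect_equal(nrow(sp), 1)
  expect_lt(sqrt(sum((unlist(sp[1, c("x_um", "y_um", "z_um")]) -
                        one$centers[1, ])^2)), 8)

  # two nuclei: far apart -> 2 spots, overlapping -> merged to 1
  mk_pair <- function(sep) {
    ctr <- rbind(c(100, 100, 70), c(100 + sep, 100, 70))
    list(centers = ctr,
         stack = render_nuclei_stack(c(16, 160, 160), ctr, 1.3, 10,
                                     nucleus_sigma = 3, intensity = 400,
                                     background_level = 100, noise_sd = 5,
                                     seed = 52))
  }
  far <- detect_spots(mk_pair(3 * 8)$stack,
                      spot_params(scale_sigma = 3, intensity_threshold = 200))
  expect_equal(nrow(far), 2)
  near <- detect_spots(mk_pair(0.3 * 8)$stack,
                       spot_params(scale_sigma = 3, intensity_threshold = 200))
  expect_equal(nrow(near), 1)
})

test_that("a dominating intensity threshold suppresses noise-only stacks", {
  set.seed(53)
  blank <- image_stack(array(pmax(0, round(rnorm(16 * 80 * 80, 100, 5))),
                             c(16, 80, 80)), 1.3, 10)
  sp <- detect_spots(blank, spot_params(scale_sigma = 3,
                                        intensity_threshold = 400))
  expect_equal(nrow(sp), 0)
})

test_that("merging is idempotent", {
  set.seed(54)
  cand <- tibble::tibble(
    x_px = runif(40, 0, 100), y_px = runif(40, 0, 100),
    z_slice = sample(1:10, 40, TRUE))
  cand$x_um <- cand$x_px * 1.3; cand$y_um <- cand$y_px * 1.3
  cand$z_um <- (cand$z_slice - 1) * 10
  cand$intensity <- runif(40, 100, 500)
  cand$response <- -runif(40)
  m1 <- spheroidal:::merge_spot_candidates(cand, 8)
  m2 <- spheroidal:::merge_spot_candidates(m1, 8)
  expect_equal(m1, m2)
  # all survivors are pairwise separated
  if (nrow(m1) > 1) {
    d <- as.matrix(dist(m1[, c("x_um", "y_um", "z_um")]))
    expect_true(all(d[upper.tri(d)] >= 8))
  }
})

test_that("ellipsoid cap volume matches the analytic integral", {
  a <- 10; b <- 20; cc <- 30
  expect_equal(ellipsoid_cap_volume(a, b, cc, 2 * cc), ellipsoid_volume(a, b, cc))
  expect_equal(ellipsoid_cap_volume(a, b, cc, cc), ellipsoid_volume(a, b, cc) / 2)
  # numeric integration of cross-sections as an independent check
  h <- 18
  f <- function(z) pi * a * b * (1 - ((z - cc) / cc)^2)
  expect_equal(ellipsoid_cap_volume(a, b, cc, h),
               stats::integrate(f, 0, h)$value, tolerance = 1e-6)
  expect_error(ellipsoid_cap_volume(a, b, cc, -1), "cap depth")
  expect_error(ellipsoid_cap_volume(a, b, cc, 2 * cc + 1), "cap depth")
})

test_that("assignment and counting follow the visibility classes", {
  labels <- matrix(0L, 50, 50)
  labels[10:30, 10:30] <- 1L
  info <- tibble::tibble(label = 1L, a = 20, b = 20, c = 30, z_top = 0,
                         analyzable_depth = 30, visibility = "half")
  mk_spots <- function(z) tibble::tibble(
    x_px = rep(20, length(z)), y_px = rep(20, length(z)),
    z_slice = 1L + round(z / 10), x_um = rep(26, length(z)),
    y_um = rep(26, length(z)), z_um = z,
    intensity = 500, response = -1, mode = "3d")
  # 7 spots in the upper half, depth = c -> doubled
  ac <- assign_and_count(mk_spots(seq(2, 26, length.out = 7)), labels, info)
  expect_equal(ac$counts$n_spots_corrected, 14)
  expect_equal(ac$counts$n_spots_raw, 7L)
  expect_true(all(ac$spots$in_analyzable_region))

  # full visibility keeps the raw count
  info$visibility <- "full"; info$analyzable_depth <- 60
  ac2 <- assign_and_count(mk_spots(c(5, 15, 55)), labels, info)
  expect_equal(ac2$counts$n_spots_corrected, 3)

  # not analyzable -> NA count, spots retained but flagged out
  info$visibility <- "not_analyzable"; info$analyzable_depth <- 10
  ac3 <- assign_and_count(mk_spots(c(5, 15)), labels, info)
  expect_true(is.na(ac3$counts$n_spots_corrected))
  expect_equal(ac3$counts$n_spots_raw, 2L)
  expect_false(any(ac3$spots$in_analyzable_region))

  # baseline mode counts raw regardless
  ac4 <- assign_and_count(mk_spots(c(5, 15)), labels, info, baseline_2d = TRUE)
  expect_equal(ac4$counts$n_spots_corrected, 2)

  # spots outside every mask stay unassigned
  out <- mk_spots(5); out$x_px <- 45; out$y_px <- 45
  ac5 <- assign_and_count(out, labels, info)
  expect_equal(ac5$spots$spheroid_label, 0L)
  expect_equal(ac5$counts$n_spots_raw, 0L)
})

test_that("corrected counts never fall below the analyzable-region count", {
  labels <- matrix(1L, 40, 40)
  info <- tibble::tibble(label = 1L, a = 20, b = 20, c = 25, z_top = 0,
                         analyzable_depth = 35, visibility = "half")
  sp <- tibble::tibble(x_px = runif(20, 5, 35), y_px = runif(20, 5, 35),
                       z_slice = 1L, x_um = runif(20, 5, 45),
                       y_um = runif(20, 5, 45), z_um = runif(20, 0, 50),
                       intensity = 500, response = -1, mode = "3d")
  ac <- assign_and_count(sp, labels, info)
  expect_gte(ac$counts$n_spots_corrected, sum(ac$spots$in_analyzable_region))
})

test_that("2.5D mode reads z from the height view", {
  nuc <- spaced_nuclei(6, 25, seed = 55)
  proj <- compute_projection(nuc$stack)
  sp <- detect_spots(proj, spot_params(scale_sigma = 3,
                                       intensity_threshold = 200,
                                       mode = "2.5d"))
  expect_gte(nrow(sp), 5)
  for (i in seq_len(nrow(sp))) {
    yx <- c(round(sp$y_px[i]) + 1, round(sp$x_px[i]) + 1)
    expect_equal(sp$z_slice[i], proj$height[yx[1], yx[2]])
  }
})
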