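test_that("range filter matches the naive neighborhood oracle", {
  expect_true(all(range_filter(matrix(5, 7, 7), 2) == 0))

  h <- matrix(5, 7, 7); h[4, 4] <- 9
  rf <- range_filter(h, 2)
  expect_equal(rf, range_oracle(h, 2))
  expect_equal(rf[4, 4], 4)
  expect_equal(rf[1, 1], 0)  # outside the disk around the bump

  set.seed(3)
  h2 <- matrix(sample(1:20, 256, TRUE), 16)
  for (r in c(1, 2, 3)) expect_equal(range_filter(h2, r), range_oracle(h2, r))
})

test_that("automatic z-range threshold separates a bimodal height histogram", {
  set.seed(4)
  n <- 4000
  low <- sample(0:2, round(0.7 * n), TRUE)
  high <- sample(20:40, n - length(low), TRUE)
  ri <- matrix(sample(c(low, high)), 50)
  thr <- auto_threshold_zrange(ri, n_slices = 45)
  expect_gt(thr, 2)
  expect_lt(thr, 20)

  expect_warning(fb <- auto_threshold_zrange(matrix(0, 10, 10), n_slices = 12),
                 "falling back")
  expect_equal(fb, 6)

  # pure-noise height view: ranges pile near the slice count, no
  # homogeneous foreground peak -> fallback
  set.seed(5)
  noisy <- matrix(sample(15:19, 900, TRUE), 30)
  expect_warning(fb2 <- auto_threshold_zrange(noisy, n_slices = 20),
                 "falling back|no homogeneous")
  expect_equal(fb2, 10)
})

test_that("background mean estimation matches a direct masked mean", {
  expect_equal(estimate_background_mean(matrix(10, 5, 5),
                                        matrix(FALSE, 5, 5)), 10)
  mip <- matrix(5, 6, 6); fg <- matrix(FALSE, 6, 6); fg[2:4, 2:4] <- TRUE
  mip[fg] <- 100
  expect_equal(estimate_background_mean(mip, fg), 5)
  set.seed(6)
  mip2 <- matrix(runif(64), 8); fg2 <- matrix(runif(64) < 0.4, 8)
  expect_equal(estimate_background_mean(mip2, fg2), mean(mip2[!fg2]))
  expect_error(estimate_background_mean(mip2, matrix(TRUE, 8, 8)), "background")
})

test_that("component labeling is 8-connected", {
  fg <- matrix(FALSE, 5, 5)
  fg[1, 1] <- fg[2, 2] <- fg[3, 3] <- TRUE  # diagonal chain
  fg[5, 5] <- TRUE
  lab <- spheroidal:::label_components8(fg)
  expect_equal(max(lab), 2L)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[5, 5] != lab[1, 1])
})

test_that("segmentation recovers well-separated spheroids and rejects noise", {
  sc <- generate_scene(scene_spec(volume_shape = c(20, 160, 160),
                                  n_spheroids = 4, radius_range = c(25, 40),
                                  mu = 0.005, min_gap = 15, seed = 11))
  proj <- compute_projection(sc$stable)
  seg <- segment_spheroids(proj)
  expect_equal(nrow(seg$spheroids), 4)
  for (k in seg$spheroids$label) {
    m <- mask_from_labels(seg$labels, k)
    overlaps <- vapply(seq_len(4), function(j) {
      tm <- sc$truth$masks == j
      sum(m & tm) / sum(tm)
    }, numeric(1))
    expect_gt(max(overlaps), 0.5)
  }
  # labels partition the foreground
  expect_true(all(sort(unique(as.integer(seg$labels))) %in% 0:4))
  expect_true(all(seg$spheroids$mean_mip >= seg$resolved$min_mip))

  set.seed(12)
  noise <- image_stack(array(pmax(0, round(rnorm(20 * 96 * 96, 100, 8))),
                             c(20, 96, 96)), 1.3, 10)
  seg0 <- suppressWarnings(segment_spheroids(compute_projection(noise)))
  expect_equal(nrow(seg0$spheroids), 0)
})

test_that("raising min_mip never increases the object count", {
  sc <- generate_scene(scene_spec(volume_shape = c(20, 160, 160),
                                  n_spheroids = 4, radius_range = c(25, 40),
                                  mu = 0.005, min_gap = 15, seed = 13))
  proj <- compute_projection(sc$stable)
  counts <- vapply(c(0, 100, 300, 450, 600, 2000), function(t) {
    nrow(segment_spheroids(proj, segmentation_params(min_mip = t))$spheroids)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 4)
  expect_equal(counts[length(counts)], 0)
})
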