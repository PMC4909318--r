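test_that("region matching implements the majority-overlap rule", {
  gt <- matrix(0L, 40, 40)
  gt[5:14, 5:14] <- 1L; gt[25:34, 25:34] <- 2L
  mr <- match_regions(gt, gt)
  expect_equal(c(mr$tp, mr$fp, mr$fn), c(2L, 0L, 0L))
  expect_equal(mr$sensitivity, 1)

  disjoint <- matrix(0L, 40, 40); disjoint[18:22, 18:22] <- 1L
  mr2 <- match_regions(disjoint, gt)
  expect_equal(c(mr2$tp, mr2$fp, mr2$fn), c(0L, 1L, 2L))

  # 10x10 GT square: 60-pixel cover -> TP; 45-pixel cover -> FN + FP
  gt1 <- matrix(0L, 40, 40); gt1[10:19, 10:19] <- 1L
  a60 <- matrix(0L, 40, 40); a60[10:19, 10:15] <- 1L
  expect_equal(match_regions(a60, gt1)$tp, 1L)
  a45 <- matrix(0L, 40, 40); a45[10:18, 10:14] <- 1L
  mr3 <- match_regions(a45, gt1)
  expect_equal(c(mr3$tp, mr3$fp, mr3$fn), c(0L, 1L, 1L))
})

test_that("a mask merging two GT regions matches the better-covered one", {
  gt <- matrix(0L, 40, 60)
  gt[10:29, 5:24] <- 1L    # 400 px
  gt[10:29, 30:44] <- 2L   # 300 px
  auto <- matrix(0L, 40, 60)
  auto[8:31, 3:46] <- 1L   # covers both fully
  mr <- match_regions(auto, gt)
  expect_equal(mr$tp, 1L)
  expect_equal(mr$fn, 1L)
  expect_equal(mr$fp, 0L)  # the mask belongs to a GT region
  expect_equal(mr$merged_events, 1L)
  expect_equal(mr$pairs$gt_label, 1L)
})

test_that("Wilson interval matches the closed form and stays in [0, 1]", {
  w <- sensitivity_wilson(10, 0)
  expect_equal(w$sensitivity, 1)
  expect_equal(round(w$ci_low, 3), 0.722)
  expect_equal(round(w$ci_high, 3), 1)

  # plug z into the algebraic formula independently
  z <- qnorm(0.975); n <- 10; p <- 1
  lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  expect_equal(w$ci_low, lo)

  # exhaustive scan: containment and bounds for all tp, fn <= 50
  grid <- expand.grid(tp = 0:50, fn = 0:50)
  grid <- grid[grid$tp + grid$fn > 0, ]
  ws <- sensitivity_wilson(grid$tp, grid$fn)
  expect_true(all(ws$ci_low >= 0 & ws$ci_high <= 1))
  expect_true(all(ws$ci_low <= ws$sensitivity + 1e-12 &
                    ws$sensitivity <= ws$ci_high + 1e-12))

  # width shrinks with n at fixed p-hat
  widths <- vapply(c(4, 8, 16, 32), function(n)
    diff(unlist(sensitivity_wilson(n / 2, n / 2)[c("ci_low", "ci_high")])),
    numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(sensitivity_wilson(0, 0), "positive")
})

test_that("contour accuracy weights misclassified pixels by a sigmoid of distance", {
  gt <- matrix(FALSE, 60, 60); gt[20:39, 20:39] <- TRUE
  expect_equal(as.numeric(contour_accuracy(gt, gt, 0.5)), 1)

  # one extra pixel exactly 3 px (1.5 um) beyond the contour: f(x0) = 1/2
  am <- gt; am[30, 42] <- TRUE
  e <- (1 - as.numeric(contour_accuracy(am, gt, 0.5))) * sum(gt)
  expect_equal(e, 0.5, tolerance = 1e-6)

  # far dilation: every rim pixel contributes ~1 (brute-force oracle)
  big <- matrix(FALSE, 60, 60); big[10:49, 10:49] <- TRUE
  acc <- contour_accuracy(big, gt, 1)  # extra pixels up to 10 um away
  sym <- xor(big, gt)
  contour <- spheroidal:::contour_pixels(gt)
  cpts <- which(contour, arr.ind = TRUE)
  spts <- which(sym, arr.ind = TRUE)
  dists <- apply(spts, 1, function(p)
    min(sqrt((cpts[, 1] - p[1])^2 + (cpts[, 2] - p[2])^2)))
  e_oracle <- sum(1 / (1 + exp(-2 * (dists - 1.5)))) / sum(gt)
  expect_equal(1 - as.numeric(acc), e_oracle, tolerance = 1e-6)

  expect_error(contour_accuracy(gt, matrix(FALSE, 60, 60), 1), "empty")
})

test_that("accuracy decreases monotonically under dilation", {
  gt <- matrix(FALSE, 80, 80); gt[30:49, 30:49] <- TRUE
  accs <- c()
  m <- gt
  for (i in 1:6) {
    accs <- c(accs, as.numeric(contour_accuracy(m, gt, 1)))
    m <- m | spheroidal:::shift_mat(m, 1, 0, FALSE) |
      spheroidal:::shift_mat(m, -1, 0, FALSE) |
      spheroidal:::shift_mat(m, 0, 1, FALSE) |
      spheroidal:::shift_mat(m, 0, -1, FALSE)
  }
  expect_true(all(diff(accs) < 0))
  expect_equal(accs[1], 1)
})

test_that("sub-pixel boundary jitter barely changes the accuracy", {
  set.seed(61)
  gt <- rasterize_ellipse(c(80, 80), 39, 39, 25, 22, 0.3)  # ~1700 px
  jit <- gt
  rim <- spheroidal:::contour_pixels(gt)
  flip <- which(rim) [runif(sum(rim)) < 0.5]
  jit[flip] <- FALSE  # deflate half the contour by one pixel
  acc <- contour_accuracy(jit, gt, 1)
  expect_gt(as.numeric(acc), 0.95)
})

test_that("validate_segmentation combines matching and accuracies", {
  sc <- generate_scene(scene_spec(volume_shape = c(20, 160, 160),
                                  n_spheroids = 4, radius_range = c(22, 38),
                                  mu = 0.005, min_gap = 15, seed = 3))
  seg <- segment_spheroids(compute_projection(sc$stable))
  classes <- tibble::tibble(label = 1:4, gt_class = c(1L, 1L, 4L, 1L))
  vr <- validate_segmentation(seg$labels, sc$truth$masks, 1.3,
                              gt_classes = classes)
  expect_equal(vr$match$tp, 4L)
  expect_gt(vr$mean_accuracy, 0.8)
  expect_true(all(c("gt_class", "accuracy") %in% names(vr$pairs)))
  expect_equal(sum(vr$by_class$n), 4)
  out <- write_validation_report(vr, tempfile("valrep"))
  expect_true(file.exists(out$json))
  js <- jsonlite::read_json(out$json)
  expect_equal(js$tp, 4L)
})
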