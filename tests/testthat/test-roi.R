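test_that("polygon ROIs round-trip through the ImageJ binary format", {
  coords <- cbind(x = c(5, 25, 25, 5), y = c(5, 5, 20, 20))
  tf <- withr::local_tempfile(fileext = ".roi")
  write_imagej_roi(tf, coords, gt_class = 3)
  roi <- read_imagej_roi(tf)
  expect_equal(roi$type, "polygon")
  expect_equal(roi$gt_class, 3L)
  expect_equal(unname(roi$coords), unname(coords))
  expect_equal(unname(roi$bounds), c(5, 5, 20, 25))
})

test_that("the parser reads a hand-assembled ROI byte layout", {
  # header assembled independently from the documented field offsets:
  # "Iout", version, type byte at 6, bounds at 8..15, n at 16,
  # stroke color (ARGB) at 40, coordinates (x then y, box-relative) at 64
  be_short <- function(v) writeBin(as.integer(v), raw(), size = 2,
                                   endian = "big")
  buf <- c(charToRaw("Iout"), be_short(227), as.raw(c(0, 0)),
           be_short(2), be_short(3), be_short(9), be_short(8),  # t l b r
           be_short(3),                      # n = 3 vertices
           raw(16),                          # x1..y2 floats
           be_short(0), raw(4),              # stroke width, shape size
           as.raw(c(255, 255, 0, 0)),        # opaque red -> class 1
           raw(4), be_short(0), be_short(0), raw(2), be_short(0),
           raw(4), raw(4),
           be_short(c(0, 5, 2)), be_short(c(0, 1, 7)))
  roi <- read_imagej_roi(buf)
  expect_equal(roi$type, "polygon")
  expect_equal(roi$gt_class, 1L)
  expect_equal(unname(roi$coords),
               cbind(c(3, 8, 5), c(2, 3, 9)))
  expect_error(read_imagej_roi(as.raw(rep(0, 70))), "Iout")
})

test_that("polygon rasterization fills the expected area", {
  sq <- read_imagej_roi(local({
    tf <- tempfile(fileext = ".roi")
    write_imagej_roi(tf, cbind(x = c(10, 20, 20, 10), y = c(10, 10, 18, 18)))
    tf
  }))
  m <- roi_to_mask(sq, c(40, 40))
  expect_lt(abs(sum(m) - 10 * 8) / 80, 0.2)  # ~ polygon area in px
  # triangle area ~ half the bounding box
  tf <- tempfile(fileext = ".roi")
  write_imagej_roi(tf, cbind(x = c(0, 20, 0), y = c(0, 0, 20)))
  tri <- roi_to_mask(read_imagej_roi(tf), c(30, 30))
  expect_lt(abs(sum(tri) - 200) / 200, 0.15)
})

test_that("RoiManager archives round-trip with class colors", {
  rois <- list(sep = list(coords = cbind(x = c(5, 15, 15, 5),
                                         y = c(5, 5, 15, 15)), gt_class = 1),
               brd = list(coords = cbind(x = c(20, 30, 30, 20),
                                         y = c(20, 20, 30, 30)), gt_class = 5))
  zf <- withr::local_tempfile(fileext = ".zip")
  write_roi_zip(zf, rois)
  back <- read_roi_zip(zf)
  expect_length(back, 2)
  expect_equal(sort(unname(vapply(back, `[[`, 0L, "gt_class"))), c(1L, 5L))

  gt <- read_ground_truth(zf, c(40, 40))
  expect_equal(sort(unique(as.integer(gt$labels))), 0:2)
  expect_equal(gt$classes$gt_class[order(gt$classes$name)], c(5L, 1L))
})

test_that("all five ground-truth classes map to their contour colors", {
  for (cls in 1:5) {
    tf <- tempfile(fileext = ".roi")
    write_imagej_roi(tf, cbind(x = c(1, 9, 5), y = c(1, 1, 9)), gt_class = cls)
    expect_equal(read_imagej_roi(tf)$gt_class, cls)
  }
})
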