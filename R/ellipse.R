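#' Fit an ellipse to a binary mask
#'
#' Finds the ellipse whose rasterized indicator minimizes the sum of
#' squared differences against the mask, i.e. the symmetric-difference
#' area. The fit is initialized from the mask's second-order central
#' moments (the equal-moments ellipse) and refined with a derivative-free
#' Nelder-Mead search on the five parameters (center, semi-axes,
#' orientation); for convex, compact masks the moment estimate is already
#' within a pixel of the optimum.
#'
#' @param mask Logical matrix (`[y, x]`), at least 5 foreground pixels.
#' @param pixel_size_xy Pixel size in um; the returned geometry is in um.
#' @param maxit Maximum refinement iterations (default 150).
#' @return Object of class `ellipse_fit`: center `xc`, `yc` (um, 0-based
#'   pixel frame), semi-axes `a >= b` (um), `orientation` (radians in
#'   `[0, pi)`), `fit_error` (symmetric-difference area / mask area) and
#'   the pixel-unit parameters in `$px`.
#' @examples
#' m <- rasterize_ellipse(c(64, 64), xc = 31, yc = 31, a = 20, b = 20, theta = 0)
#' fit <- fit_ellipse(m, pixel_size_xy = 1)
#' fit$a; fit$b
#' @export
fit_ellipse <- function(mask, pixel_size_xy = 1, maxit = 150) {
  stopifnot(is.matrix(mask))
  idx <- which(mask)
  if (length(idx) < 5) stop("mask must contain at least 5 pixels")
  arr <- arrayInd(idx, dim(mask))
  ys <- arr[, 1] - 1; xs <- arr[, 2] - 1  # 0-based pixel centers
  cx <- mean(xs); cy <- mean(ys)
  S <- stats::cov(cbind(xs, ys)) * (length(xs) - 1) / length(xs)
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[2] <= 1e-9) stop("degenerate (collinear) mask; cannot fit an ellipse")
  a0 <- 2 * sqrt(ev$values[1]); b0 <- 2 * sqrt(ev$values[2])
  theta0 <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi

  # evaluation window: mask bounding box padded by the major axis
  pad <- ceiling(a0) + 2L
  y1 <- max(1L, min(arr[, 1]) - pad); y2 <- min(nrow(mask), max(arr[, 1]) + pad)
  x1 <- max(1L, min(arr[, 2]) - pad); x2 <- min(ncol(mask), max(arr[, 2]) + pad)
  win <- mask[y1:y2, x1:x2]
  gx <- matrix(rep((x1:x2) - 1, each = y2 - y1 + 1), nrow = y2 - y1 + 1)
  gy <- matrix(rep((y1:y2) - 1, times = x2 - x1 + 1), nrow = y2 - y1 + 1)

  objective <- function(p) {
    a <- exp(p[3]); b <- exp(p[4])
    ct <- cos(p[5]); st <- sin(p[5])
    dx <- gx - p[1]; dy <- gy - p[2]
    u <- (dx * ct + dy * st) / a
    v <- (-dx * st + dy * ct) / b
    inside <- (u * u + v * v) <= 1
    sum(inside != win)
  }
  p0 <- c(cx, cy, log(a0), log(b0), theta0)
  opt <- stats::optim(p0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     reltol = 1e-3 / max(1, length(idx))))
  p <- opt$par
  a <- exp(p[3]); b <- exp(p[4]); th <- p[5] %% pi
  if (b > a) { tmp <- a; a <- b; b <- tmp; th <- (th + pi / 2) %% pi }
  structure(list(
    xc = p[1] * pixel_size_xy, yc = p[2] * pixel_size_xy,
    a = a * pixel_size_xy, b = b * pixel_size_xy,
    orientation = th,
    fit_error = opt$value / length(idx),
    px = list(xc = p[1], yc = p[2], a = a, b = b),
    area_px = length(idx), pixel_size_xy = pixel_size_xy),
    class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> center (%.1f, %.1f) um, a = %.1f, b = %.1f um, theta = %.1f deg, err = %.3f\n",
              x$xc, x$yc, x$a, x$b, x$orientation * 180 / pi, x$fit_error))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ellipse_fit <- function(x, ...) {
  tibble::tibble(
    term = c("xc", "yc", "a", "b", "orientation"),
    estimate = c(x$xc, x$yc, x$a, x$b, x$orientation),
    unit = c("um", "um", "um", "um", "rad"))
}

#' @export
glance.ellipse_fit <- function(x, ...) {
  tibble::tibble(fit_error = x$fit_error, area_px = x$area_px,
                 aspect_ratio = x$a / x$b)
}

#' Rasterize an ellipse into a logical mask
#'
#' Pixel centers (0-based) inside the ellipse are set to `TRUE`. Used for
#' fitting round-trips and by the synthetic scene generator.
#'
#' @param dim_yx Image dimensions `c(ny, nx)`.
#' @param xc,yc Center, 0-based pixel coordinates.
#' @param a,b Semi-axes in pixels.
#' @param theta Orientation in radians.
#' @return Logical matrix.
#' @export
rasterize_ellipse <- function(dim_yx, xc, yc, a, b, theta = 0) {
  gx <- matrix(rep(seq_len(dim_yx[2]) - 1, each = dim_yx[1]), nrow = dim_yx[1])
  gy <- matrix(rep(seq_len(dim_yx[1]) - 1, times = dim_yx[2]), nrow = dim_yx[1])
  ct <- cos(theta); st <- sin(theta)
  dx <- gx - xc; dy <- gy - yc
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  (u * u + v * v) <= 1
}

# Maximum Feret diameter of a pixel set (pixel units): the largest
# pairwise distance over the convex hull of pixel centers, plus one pixel
# so the caliper spans the pixel footprint rather than center-to-center.
feret_diameter <- function(mask) {
  arr <- arrayInd(which(mask), dim(mask))
  pts <- cbind(arr[, 2], arr[, 1])
  if (nrow(pts) == 1) return(1)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  dmax <- 0
  for (i in seq_len(nrow(hp))) {
    d2 <- (hp[, 1] - hp[i, 1])^2 + (hp[, 2] - hp[i, 2])^2
    dmax <- max(dmax, max(d2))
  }
  sqrt(dmax) + 1
}

#' Circularity (Podczeck shape factor) of a mask
#'
#' Area over the circle circumscribed on the maximum Feret diameter:
#' `A / (pi * (F_max / 2)^2)`. Equals 1 for a disk and approximately `b/a`
#' for an ellipse with semi-axes `a >= b`; laterally merged (dumbbell)
#' objects score markedly lower, which is what the elliptical-shape filter
#' exploits. A perimeter-based variant `4*pi*A/P^2` is available via
#' `method = "perimeter"`.
#'
#' @param mask Logical matrix, non-empty.
#' @param method `"feret"` (default) or `"perimeter"`.
#' @return Circularity in `(0, 1]` (up to rasterization error).
#' @export
circularity <- function(mask, method = c("feret", "perimeter")) {
  method <- match.arg(method)
  area <- sum(mask)
  stopifnot(area > 0)
  if (method == "feret") {
    f <- feret_diameter(mask)
    if (f == 0) return(1)
    min(1, area / (pi * (f / 2)^2))
  } else {
    per <- sum(outer_rim(mask))
    if (per == 0) return(1)
    min(1, 4 * pi * area / per^2)
  }
}

#' Partition spheroids by circularity
#'
#' Splits a spheroid feature table into elliptical (circularity at or
#' above the threshold) and non-elliptical objects. Overlapping or
#' incorrectly merged spheroids produce irregular 2D masks with low
#' circularity and are rejected here rather than split.
#'
#' @param spheroids Tibble with a `circularity` column (see
#'   [segment_spheroids()] plus [circularity()] per mask).
#' @param min_circularity Threshold in `[0, 1]`. Default 0.8.
#' @return List with tibbles `kept` and `rejected`; both gain a
#'   `roundness_class` column (`"elliptical"` / `"non-elliptical"`).
#' @export
filter_by_circularity <- function(spheroids, min_circularity = 0.8) {
  stopifnot(min_circularity >= 0, min_circularity <= 1,
            "circularity" %in% names(spheroids))
  ok <- spheroids$circularity >= min_circularity
  spheroids$roundness_class <- ifelse(ok, "elliptical", "non-elliptical")
  list(kept = spheroids[ok, , drop = FALSE],
       rejected = spheroids[!ok, , drop = FALSE])
}
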