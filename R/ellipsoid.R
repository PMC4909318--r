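# Interpolated (grouped-data) median for slice-quantized values: the
# plain median of hundreds of rim heights snaps to a whole slice and
# amplifies any sub-slice tie imbalance; linear interpolation within the
# median bin recovers the sub-slice position. `w` is the bin width.
grouped_median <- function(x, w) {
  tab <- table(x)
  v <- as.numeric(names(tab))
  n <- sum(tab)
  cum <- cumsum(tab)
  i <- which(cum >= n / 2)[1]
  lower <- v[i] - w / 2
  below <- if (i > 1) cum[[i - 1]] else 0
  unname(lower + (n / 2 - below) / tab[[i]] * w)
}

# Pixels of the mask with at least one background 4-neighbor (the
# 8-connected inner boundary); pixels on the image border count as rim.
outer_rim <- function(mask) {
  nb <- shift_mat(mask, 1, 0, FALSE) & shift_mat(mask, -1, 0, FALSE) &
    shift_mat(mask, 0, 1, FALSE) & shift_mat(mask, 0, -1, FALSE)
  mask & !nb
}

#' Axial intensity profile through a point
#'
#' Mean intensity over the 3x3 xy-neighborhood of `(xc_px, yc_px)` for
#' every slice, optionally restricted to a z-window (um) around a center.
#' This is the depth profile used to locate the spheroid top and to
#' quantify signal attenuation; z = 0 um corresponds to the first slice.
#'
#' @param stack An [image_stack()].
#' @param xc_px,yc_px 0-based pixel coordinates of the profile column.
#' @param z_center_um,half_width_um Optional window `z_center +/-
#'   half_width` (um), clipped to the stack.
#' @return Object of class `axial_profile`: `z_um`, `intensity`, `i_max`,
#'   `z_at_max`, `z_step`; `z_top`/`z_analyzable` are `NA` until set by
#'   [extrapolate_ellipsoid()] / [analyzable_depth()].
#' @export
axial_profile <- function(stack, xc_px, yc_px, z_center_um = NULL,
                          half_width_um = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  yi <- pmin(pmax(round(yc_px) + 1 + (-1:1), 1L), d[2])
  xi <- pmin(pmax(round(xc_px) + 1 + (-1:1), 1L), d[3])
  z_um <- (seq_len(d[1]) - 1) * stack$z_step
  keep <- rep(TRUE, d[1])
  if (!is.null(z_center_um) && !is.null(half_width_um))
    keep <- z_um >= z_center_um - half_width_um &
      z_um <= z_center_um + half_width_um
  if (!any(keep)) stop("profile window lies entirely outside the stack")
  inten <- vapply(which(keep), function(z) mean(stack$voxels[z, yi, xi]),
                  numeric(1))
  new_axial_profile(z_um[keep], inten, stack$z_step)
}

new_axial_profile <- function(z_um, intensity, z_step) {
  i_max <- max(intensity)
  structure(list(z_um = z_um, intensity = intensity, i_max = i_max,
                 z_at_max = z_um[which.max(intensity)], z_step = z_step,
                 z_top = NA_real_, z_analyzable = NA_real_),
            class = "axial_profile")
}

#' @export
print.axial_profile <- function(x, ...) {
  cat(sprintf("<axial_profile> %d samples, z in [%.0f, %.0f] um, I_max = %.4g at z = %.0f um\n",
              length(x$z_um), min(x$z_um), max(x$z_um), x$i_max, x$z_at_max))
  invisible(x)
}

# Gaussian smoothing of a profile at scale = 1 z-step (in samples: sd 1).
smooth_profile <- function(intensity) {
  k <- gauss_kernel(1)
  n <- length(intensity)
  r <- (length(k) - 1) / 2
  out <- numeric(n)
  for (s in seq_along(k)) {
    idx <- pmin(pmax(seq_len(n) + (s - r - 1), 1L), n)
    out <- out + k[s] * intensity[idx]
  }
  out
}

# First inflection (zero of the second difference) of the smoothed profile
# above (shallower than) the spheroid center, with linear sub-slice
# interpolation. The scan descends from the profile start -- the flat
# background side -- and returns the first convex-to-concave transition
# (the rising edge at the spheroid top); the cell-scale texture inside
# the tissue produces further crossings, but only after this first edge.
# Crossings where both second differences are tiny relative to the
# strongest curvature (background noise) are ignored. Returns um or NA.
find_z_top <- function(profile, z_c_um = Inf) {
  s <- smooth_profile(profile$intensity)
  n <- length(s)
  if (n < 4) return(NA_real_)
  d2 <- c(NA, s[3:n] - 2 * s[2:(n - 1)] + s[1:(n - 2)], NA)
  lim <- 0.05 * max(abs(d2[2:(n - 1)]))
  for (i in 2:(n - 1)) {
    if (profile$z_um[i] >= z_c_um) break
    lo <- d2[i]; hi <- d2[i + 1]
    if (!is.na(lo) && !is.na(hi) && lo > 0 && hi < 0 &&
        (abs(lo) > lim || abs(hi) > lim)) {
      frac <- abs(lo) / (abs(lo) + abs(hi))
      return(profile$z_um[i] + frac * (profile$z_um[i + 1] - profile$z_um[i]))
    }
  }
  NA_real_
}

#' Extrapolate a fitted 2D ellipse to a 3D ellipsoid
#'
#' The ellipsoid keeps the 2D ellipse's lateral center, semi-axes and
#' orientation; its third semi-axis `c` lies along z. The axial center
#' `z_c` is the median height-view z over the mask's outer rim (where the
#' short chords make the MIP arrive near the equatorial plane), and the
#' top coordinate `z_top` is the inflection point of the smoothed axial
#' profile above the profile maximum, so that `c = |z_c - z_top|`. Masks
#' with equivalent radius `sqrt(area/pi)` below `min_radius` are too small
#' for a reliable axial read-out at typical z-steps; for those (and when
#' no inflection is found) the vertical semi-axis falls back to the mean
#' in-plane semi-axis `(a + b) / 2`.
#'
#' @param ellipse An [fit_ellipse()] result.
#' @param mask Logical matrix of the spheroid's 2D mask.
#' @param proj The [compute_projection()] pair for the same (stable) channel.
#' @param stack The stable-channel [image_stack()].
#' @param min_radius Minimum equivalent 2D radius (um) for the axial
#'   estimate. Default 24.
#' @return Object of class `ellipsoid3d`: `center` (x, y, z in um),
#'   semi-axes `a`, `b`, `c` (um), `orientation_xy`, `volume` (um^3),
#'   `fallback_used`, and the `axial_profile` in `$profile` (with `z_top`
#'   filled in).
#' @export
extrapolate_ellipsoid <- function(ellipse, mask, proj, stack, min_radius = 24) {
  stopifnot(inherits(ellipse, "ellipse_fit"), inherits(proj, "projection_pair"),
            inherits(stack, "image_stack"))
  rim <- outer_rim(mask)
  if (!any(rim)) stop("mask has no rim pixels")
  z_c <- grouped_median((proj$height[rim] - 1) * stack$z_step, stack$z_step)
  half_width <- 4 * ellipse$a  # generous window, clipped to the stack
  prof <- axial_profile(stack, ellipse$px$xc, ellipse$px$yc,
                        z_center_um = z_c, half_width_um = half_width)
  area_um2 <- sum(mask) * proj$pixel_size_xy^2
  r_equiv <- sqrt(area_um2 / pi)
  fallback <- FALSE
  if (r_equiv < min_radius) {
    cc <- (ellipse$a + ellipse$b) / 2
    z_top <- z_c - cc
    fallback <- TRUE
  } else {
    z_top <- find_z_top(prof, z_c)
    if (is.na(z_top) || z_top >= z_c) {
      warning("no inflection point found above the spheroid center; using the mean in-plane semi-axis")
      cc <- (ellipse$a + ellipse$b) / 2
      z_top <- z_c - cc
      fallback <- TRUE
    } else {
      cc <- abs(z_c - z_top)
    }
  }
  prof$z_top <- z_top
  structure(list(
    center = c(x = ellipse$xc, y = ellipse$yc, z = z_c),
    a = ellipse$a, b = ellipse$b, c = cc,
    orientation_xy = ellipse$orientation,
    volume = ellipsoid_volume(ellipse$a, ellipse$b, cc),
    fallback_used = fallback, profile = prof),
    class = "ellipsoid3d")
}

#' @export
print.ellipsoid3d <- function(x, ...) {
  cat(sprintf("<ellipsoid3d> center (%.0f, %.0f, %.0f) um, semi-axes %.1f x %.1f x %.1f um, V = %.3g um^3\n",
              x$center[1], x$center[2], x$center[3], x$a, x$b, x$c, x$volume))
  invisible(x)
}

#' Ellipsoid volume
#'
#' `(4/3) * pi * a * b * c` for semi-axes in um.
#'
#' @param a,b,c Semi-axes (um), all positive. Alternatively pass an
#'   `ellipsoid3d` object as `a`.
#' @return Volume in um^3.
#' @examples
#' ellipsoid_volume(10, 20, 30)
#' @export
ellipsoid_volume <- function(a, b = NULL, c = NULL) {
  if (inherits(a, "ellipsoid3d")) { b <- a$b; c <- a$c; a <- a$a }
  if (any(c(a, b, c) <= 0)) stop("ellipsoid semi-axes must be positive")
  4 / 3 * pi * a * b * c
}
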