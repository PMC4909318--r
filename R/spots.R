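#' Spot detection parameters
#'
#' @param max_spot_radius Maximal expected spot (nucleus) radius in um;
#'   local minima closer than this are merged. Default 8 (average nucleus
#'   diameter 16 um would be oversized; 8 um matches a typical nucleus).
#' @param scale_sigma LoG scale in um, or `"auto"` to optimize it on the
#'   marker-channel MIP with [optimal_log_scale()]. When set, must lie in
#'   `[max_spot_radius/10, max_spot_radius]`.
#' @param intensity_threshold Minimum original-image intensity at a spot
#'   center, or `"auto"` for the median spheroid intensity in the MIP
#'   (see [spot_intensity_threshold()]).
#' @param mode `"3d"` (volumetric LoG) or `"2.5d"` (LoG on the MIP with z
#'   read from the height view).
#' @param min_response_frac Relative response floor: minima whose blob
#'   strength falls below this fraction of the image's strongest blob
#'   response are discarded as noise curvature. Default 0.05.
#' @return A list of class `spot_params`.
#' @export
spot_params <- function(max_spot_radius = 8, scale_sigma = "auto",
                        intensity_threshold = "auto", mode = c("3d", "2.5d"),
                        min_response_frac = 0.05) {
  mode <- match.arg(mode)
  stopifnot(max_spot_radius > 0,
            min_response_frac >= 0, min_response_frac < 1)
  if (is.numeric(scale_sigma) &&
      (scale_sigma < max_spot_radius / 10 || scale_sigma > max_spot_radius))
    stop("`scale_sigma` must lie in [max_spot_radius/10, max_spot_radius]")
  structure(list(max_spot_radius = max_spot_radius, scale_sigma = scale_sigma,
                 intensity_threshold = intensity_threshold, mode = mode,
                 min_response_frac = min_response_frac),
            class = "spot_params")
}

# Scale-normalized negated LoG response of a 2D image; sigma in pixels.
log_response_mat <- function(m, sigma_px) {
  -sigma_px^2 * laplacian_mat(gauss_blur_mat(m, sigma_px), 1)
}

#' Optimal LoG scale from the MIP
#'
#' Grid-searches the Gaussian scale sigma over 20 log-spaced values in
#' `[max_spot_radius/10, max_spot_radius]` and scores each scale by the
#' strongest scale-normalized blob response in the image (the classical
#' scale-selection score): the image-wide sum of a Laplacian response is
#' identically ~0 (zero-sum kernel), and minima-sum variants reward the
#' many edge-ripple minima that small scales produce, so the peak
#' response is the well-posed score. It is maximal at sigma = s for
#' Gaussian blobs of standard deviation s and near r/sqrt(2) for disks
#' of radius r.
#'
#' @param mip Intensity matrix (marker-channel MIP), non-constant.
#' @param max_spot_radius Maximal spot radius in um. Default 8.
#' @param pixel_size_xy Pixel size in um.
#' @param n_scales Number of grid points. Default 20.
#' @return Object of class `log_scale_opt`: `sigma` (um) and `curve`
#'   (tibble of `sigma_um`, `score`).
#' @export
optimal_log_scale <- function(mip, max_spot_radius = 8, pixel_size_xy = 1,
                              n_scales = 20) {
  stopifnot(is.matrix(mip))
  if (max(mip) == min(mip)) stop("MIP is constant; cannot optimize the LoG scale")
  sigmas <- exp(seq(log(max_spot_radius / 10), log(max_spot_radius),
                    length.out = n_scales))
  score <- vapply(sigmas, function(s_um) {
    max(log_response_mat(mip, s_um / pixel_size_xy))
  }, numeric(1))
  structure(list(sigma = sigmas[which.max(score)],
                 curve = tibble::tibble(sigma_um = sigmas, score = score)),
            class = "log_scale_opt")
}

#' @export
print.log_scale_opt <- function(x, ...) {
  cat(sprintf("<log_scale_opt> optimal sigma = %.2f um over %d scales\n",
              x$sigma, nrow(x$curve)))
  invisible(x)
}

#' Spot intensity threshold from the segmented spheroids
#'
#' Median spheroid intensity in the MIP: the median of the stable-channel
#' MIP over the union of all 2D spheroid masks -- one threshold per
#' image. Because the stable stain is constant within a spheroid up to
#' attenuation, this threshold tracks the overall signal level, and for
#' marker-positive nuclei about twice as bright as the tissue it passes
#' exactly the spots above the 50%-attenuation plane -- the same
#' analyzable region the corrected counting extrapolates from.
#'
#' @param mip Stable-channel MIP (the channel the spheroids are defined
#'   in).
#' @param labels Label matrix from [segment_spheroids()].
#' @return Scalar threshold.
#' @export
spot_intensity_threshold <- function(mip, labels) {
  stopifnot(identical(dim(mip), dim(labels)))
  if (!any(labels > 0)) stop("no segmented foreground to take the median over")
  stats::median(mip[labels > 0])
}

# Greedy non-maximum suppression: process candidates by ascending LoG
# response value (most blob-like = most negative first after negation
# ordering), keep a candidate only if no kept spot lies within
# `radius_um` (anisotropy-aware 3D distance).
merge_spot_candidates <- function(cand, radius_um) {
  if (nrow(cand) == 0) return(cand)
  ord <- order(cand$response)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  kx <- ky <- kz <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kx)) {
      d2 <- (cand$x_um[i] - kx)^2 + (cand$y_um[i] - ky)^2 + (cand$z_um[i] - kz)^2
      if (any(d2 < radius_um^2)) next
    }
    kept[i] <- TRUE
    kx <- c(kx, cand$x_um[i]); ky <- c(ky, cand$y_um[i]); kz <- c(kz, cand$z_um[i])
  }
  cand[kept, , drop = FALSE]
}

#' Detect marker-positive nuclei
#'
#' Nuclei appear as bright blobs in the marker channel; they are detected
#' as local minima of the scale-normalized Laplacian-of-Gaussian response
#' (26-connectivity in 3D mode, 8-connectivity in 2.5D mode, where the
#' stack is replaced by its MIP and z is read from the height view).
#' Minima within `max_spot_radius` of a stronger minimum are merged so a
#' textured nucleus yields one spot while separate nuclei stay distinct,
#' and spots dimmer than `intensity_threshold` in the original image are
#' dropped.
#'
#' @param x An [image_stack()] (3D mode) or [compute_projection()] pair
#'   (2.5D mode).
#' @param params A [spot_params()] list; `scale_sigma` and
#'   `intensity_threshold` must be resolved to numbers here (the pipeline
#'   resolves `"auto"` values; see [optimal_log_scale()] and
#'   [spot_intensity_threshold()]). An unresolved `intensity_threshold`
#'   defaults to 0 with a warning (keep all spots).
#' @return Tibble of spots: `x_px`, `y_px`, `z_slice` (0-based pixel
#'   coordinates / 1-based slice), `x_um`, `y_um`, `z_um`, `intensity`
#'   (original image at the center), `response` (LoG response, negative =
#'   blob-like), `mode`.
#' @export
detect_spots <- function(x, params = spot_params()) {
  stopifnot(inherits(params, "spot_params"))
  sigma <- params$scale_sigma
  if (identical(sigma, "auto"))
    stop("`scale_sigma` = \"auto\" must be resolved with optimal_log_scale() before detect_spots()")
  thr <- params$intensity_threshold
  if (identical(thr, "auto")) {
    warning("`intensity_threshold` = \"auto\" without segmentation context; using 0")
    thr <- 0
  }
  if (params$mode == "3d") {
    stopifnot(inherits(x, "image_stack"))
    px <- x$pixel_size_xy; zs <- x$z_step
    blur <- gauss_blur_arr3(x$voxels, sigma / zs, sigma / px, sigma / px)
    resp <- sigma^2 * laplacian_arr3(blur, zs, px)
    minima <- which(local_minima_arr3(resp) & resp < 0)
    if (length(minima) == 0) return(empty_spot_tbl(params$mode))
    idx <- arrayInd(minima, dim(resp))
    # spot intensity = original-image peak near the minimum; the voxel
    # grid (10 um slices) can sample an off-center value otherwise
    peak <- vapply(seq_len(nrow(idx)), function(i) {
      zi <- pmin(pmax(idx[i, 1] + (-1:1), 1L), dim(resp)[1])
      yi <- pmin(pmax(idx[i, 2] + (-1:1), 1L), dim(resp)[2])
      xi <- pmin(pmax(idx[i, 3] + (-1:1), 1L), dim(resp)[3])
      max(x$voxels[zi, yi, xi])
    }, numeric(1))
    cand <- tibble::tibble(
      x_px = idx[, 3] - 1, y_px = idx[, 2] - 1, z_slice = idx[, 1],
      x_um = (idx[, 3] - 1) * px, y_um = (idx[, 2] - 1) * px,
      z_um = (idx[, 1] - 1) * zs,
      intensity = peak, response = resp[minima])
  } else {
    stopifnot(inherits(x, "projection_pair"))
    px <- x$pixel_size_xy; zs <- x$z_step
    resp <- -log_response_mat(x$mip, sigma / px)
    minima <- which(local_minima_mat(resp) & resp < 0)
    if (length(minima) == 0) return(empty_spot_tbl(params$mode))
    idx <- arrayInd(minima, dim(resp))
    zsl <- x$height[minima]
    peak <- vapply(seq_len(nrow(idx)), function(i) {
      yi <- pmin(pmax(idx[i, 1] + (-1:1), 1L), dim(resp)[1])
      xi <- pmin(pmax(idx[i, 2] + (-1:1), 1L), dim(resp)[2])
      max(x$mip[yi, xi])
    }, numeric(1))
    cand <- tibble::tibble(
      x_px = idx[, 2] - 1, y_px = idx[, 1] - 1, z_slice = zsl,
      x_um = (idx[, 2] - 1) * px, y_um = (idx[, 1] - 1) * px,
      z_um = (zsl - 1) * zs,
      intensity = peak, response = resp[minima])
  }
  cand <- cand[cand$response <= params$min_response_frac * min(cand$response),
               , drop = FALSE]
  out <- merge_spot_candidates(cand, params$max_spot_radius)
  out <- out[out$intensity >= thr, , drop = FALSE]
  out$mode <- params$mode
  out
}

empty_spot_tbl <- function(mode) {
  tibble::tibble(x_px = numeric(), y_px = numeric(), z_slice = integer(),
                 x_um = numeric(), y_um = numeric(), z_um = numeric(),
                 intensity = numeric(), response = numeric(),
                 mode = character())
}

#' Volume of an ellipsoid cap
#'
#' Volume of an ellipsoid with semi-axes `a`, `b` (in-plane) and `c`
#' (vertical) truncated at depth `h` below its top:
#' `pi * a * b * h^2 * (3c - h) / (3 c^2)`. Reduces to half the ellipsoid
#' at `h = c` and to the full volume at `h = 2c`.
#'
#' @param a,b,c Semi-axes (um).
#' @param h Cap depth from the top (um), in `[0, 2c]`.
#' @return Cap volume (um^3).
#' @export
ellipsoid_cap_volume <- function(a, b, c, h) {
  stopifnot(a > 0, b > 0, c > 0)
  if (h < 0 || h > 2 * c) stop("cap depth must lie in [0, 2c]")
  pi * a * b * h^2 * (3 * c - h) / (3 * c^2)
}

#' Assign spots to spheroids and correct counts for attenuation
#'
#' A spot belongs to the spheroid whose 2D mask contains its (x, y)
#' position (masks are disjoint, so ties are impossible); spots outside
#' all masks stay unassigned. Raw counts are the assigned spots per
#' spheroid. Corrected counts depend on the visibility class: `full`
#' spheroids keep the raw count; for `half` spheroids only spots above the
#' analyzable-depth plane (`z <= z_top + depth`) are counted and scaled by
#' the volume ratio `V_ellipsoid / V_cap(depth)` -- at `depth = c` this is
#' the classical doubling of the upper hemisphere; `not_analyzable`
#' spheroids get `NA` (their spots remain in the table, flagged). With
#' `baseline_2d = TRUE` the corrected count is simply the raw 2D count
#' for every spheroid (the uncorrected MIP analysis used for comparison).
#'
#' @param spots Spot tibble from [detect_spots()].
#' @param labels Label matrix from [segment_spheroids()].
#' @param spheroid_info Tibble with one row per spheroid: `label`, `a`,
#'   `b`, `c` (um), `z_top` (um), `analyzable_depth` (um),
#'   `visibility` (`"full"`, `"half"`, `"not_analyzable"`).
#' @param baseline_2d Use the uncorrected baseline counting. Default FALSE.
#' @return List: `spots` (input plus `spheroid_label`,
#'   `in_analyzable_region`), `counts` (tibble `label`, `n_spots_raw`,
#'   `n_spots_corrected`, `visibility`).
#' @export
assign_and_count <- function(spots, labels, spheroid_info,
                             baseline_2d = FALSE) {
  lab <- integer(nrow(spots))
  if (nrow(spots) > 0) {
    ii <- cbind(round(spots$y_px) + 1, round(spots$x_px) + 1)
    ii[, 1] <- pmin(pmax(ii[, 1], 1L), nrow(labels))
    ii[, 2] <- pmin(pmax(ii[, 2], 1L), ncol(labels))
    lab <- labels[ii]
  }
  spots$spheroid_label <- lab
  spots$in_analyzable_region <- FALSE
  counts <- spheroid_info[, "label", drop = FALSE]
  counts$n_spots_raw <- 0L
  counts$n_spots_corrected <- NA_real_
  counts$visibility <- spheroid_info$visibility
  for (k in seq_len(nrow(spheroid_info))) {
    si <- spheroid_info[k, ]
    in_sph <- which(spots$spheroid_label == si$label)
    counts$n_spots_raw[k] <- length(in_sph)
    if (baseline_2d) {
      spots$in_analyzable_region[in_sph] <- TRUE
      counts$n_spots_corrected[k] <- length(in_sph)
      next
    }
    if (is.na(si$visibility) || si$visibility == "not_analyzable") next
    depth <- min(si$analyzable_depth, 2 * si$c)
    in_region <- in_sph[spots$z_um[in_sph] <= si$z_top + depth]
    spots$in_analyzable_region[in_region] <- TRUE
    if (si$visibility == "full") {
      counts$n_spots_corrected[k] <- length(in_sph)
    } else {
      v_cap <- ellipsoid_cap_volume(si$a, si$b, si$c, depth)
      if (v_cap <= 0) stop("zero cap volume for a half-visible spheroid")
      v_full <- ellipsoid_volume(si$a, si$b, si$c)
      counts$n_spots_corrected[k] <- length(in_region) * v_full / v_cap
    }
  }
  list(spots = spots, counts = counts)
}
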