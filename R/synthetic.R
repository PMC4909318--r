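#' Specification of a synthetic spheroid scene
#'
#' Describes a two-channel synthetic confocal stack: ellipsoidal spheroids
#' filled with cell-scale Gaussian-blob texture (stable channel), a subset
#' of cells marked positive (marker channel), Beer-Lambert attenuation
#' with a constant absorption coefficient inside tissue and zero outside,
#' anisotropic Gaussian blur for the PSF, and Gaussian camera noise on a
#' constant background. Defaults mirror a 10x/0.4 NA spinning-disk
#' acquisition: 10 um z-step, 1.3 um lateral pixels, 12 um cells.
#'
#' @param volume_shape Stack dimensions `c(z, y, x)` in voxels.
#' @param pixel_size_xy,z_step Calibration in um.
#' @param n_spheroids Number of spheroids to place.
#' @param radius_range Range of lateral semi-axes (um).
#' @param axial_ratio_range Range of `c/a` ratios (1 = spheres).
#' @param cell_diameter Cell diameter (um); sets texture blob size.
#' @param packing_fraction Fraction of the ellipsoid volume occupied by
#'   cells (sets the cell count). Default 0.6.
#' @param positive_fraction Fraction of cells that are marker-positive.
#' @param min_spot_spacing Minimum pairwise distance (um) enforced between
#'   positive cells (0 = none).
#' @param mu Absorption coefficient inside tissue (1/um).
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas (um).
#' @param background_level,noise_sd Camera background and noise (intensity).
#' @param cell_intensity Stable-channel tissue intensity. The whole-cell
#'   stain is modeled as constant inside tissue (the attenuation model's
#'   first assumption) with cell-scale modulation on top.
#' @param spot_intensity Marker-channel nucleus blob amplitude.
#' @param texture_strength Relative amplitude of the cell-scale
#'   modulation of the stable channel (0 = perfectly uniform tissue).
#'   Default 0.25.
#' @param min_gap Minimum lateral gap between spheroid rims (um) when
#'   placements are sampled. Default 5.
#' @param allow_overlap Allow laterally overlapping placements.
#' @param centers,radii,axial_ratios Optional explicit placements: matrix
#'   of centers (um, columns x, y, z) and vectors of lateral semi-axes and
#'   `c/a` ratios; when given, sampling is skipped.
#' @param seed Integer seed; scenes are bit-identical given the seed.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(volume_shape = c(20, 128, 128), pixel_size_xy = 1.3,
                       z_step = 10, n_spheroids = 3,
                       radius_range = c(25, 45), axial_ratio_range = c(1, 1),
                       cell_diameter = 12, packing_fraction = 0.6,
                       positive_fraction = 0.2, min_spot_spacing = 0,
                       mu = 0.01, psf_sigma_xy = 1, psf_sigma_z = 4,
                       background_level = 100, noise_sd = 5,
                       cell_intensity = 500, spot_intensity = 2000,
                       texture_strength = 0.25,
                       min_gap = 5, allow_overlap = FALSE,
                       centers = NULL, radii = NULL, axial_ratios = NULL,
                       seed = 1L) {
  stopifnot(length(volume_shape) == 3, all(volume_shape >= 1),
            pixel_size_xy > 0, z_step > 0, cell_diameter > 0,
            positive_fraction >= 0, positive_fraction <= 1,
            mu >= 0, packing_fraction > 0)
  structure(as.list(environment()), class = "scene_spec")
}

# Add a separable Gaussian blob (amplitude `amp`, sd `sigma_um`) at the
# voxel-frame position (zc, yc, xc) [1-based, fractional allowed].
add_blob <- function(vol, zc, yc, xc, amp, sigma_z_vox, sigma_xy_vox) {
  d <- dim(vol)
  rz <- ceiling(3 * sigma_z_vox); rxy <- ceiling(3 * sigma_xy_vox)
  zi <- max(1, floor(zc - rz)):min(d[1], ceiling(zc + rz))
  yi <- max(1, floor(yc - rxy)):min(d[2], ceiling(yc + rxy))
  xi <- max(1, floor(xc - rxy)):min(d[3], ceiling(xc + rxy))
  wz <- exp(-((zi - zc)^2) / (2 * sigma_z_vox^2))
  wy <- exp(-((yi - yc)^2) / (2 * sigma_xy_vox^2))
  wx <- exp(-((xi - xc)^2) / (2 * sigma_xy_vox^2))
  vol[zi, yi, xi] <- vol[zi, yi, xi] + amp * (wz %o% wy %o% wx)
  vol
}

# Uniform sample inside the unit ball (rejection, vectorized batches).
runif_ball <- function(n) {
  out <- matrix(numeric(0), 0, 3)
  while (nrow(out) < n) {
    cand <- matrix(stats::runif(3 * 2 * n, -1, 1), ncol = 3)
    keep <- rowSums(cand^2) <= 1
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic two-channel spheroid scene
#'
#' Deterministic given `spec$seed`. Pipeline: place ellipsoids, fill them
#' with cell-scale texture (stable channel) and mark a fixed fraction of
#' cells positive (marker channel), attenuate every voxel by
#' `exp(-mu * tissue path length above it)`, blur with the anisotropic
#' PSF, then add background and Gaussian noise and quantize to 16 bits.
#' Attenuation acts identically on both channels.
#'
#' @param spec A [scene_spec()].
#' @return Object of class `synthetic_scene`: `stable` and `marker`
#'   [image_stack()]s, `spec`, and `truth` (list: `ellipsoids` tibble,
#'   `spots` tibble of positive-cell positions in um, `masks` 2D label
#'   image of the true projected masks, `label_volume`, `n_cells`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  d <- spec$volume_shape
  px <- spec$pixel_size_xy; zs <- spec$z_step
  ext <- c((d[1] - 1) * zs, (d[2] - 1) * px, (d[3] - 1) * px)  # z, y, x um
  if (!is.null(spec$centers)) {
    centers <- as.matrix(spec$centers)  # columns x, y, z (um)
    radii <- rep_len(spec$radii, nrow(centers))
    ratios <- rep_len(if (is.null(spec$axial_ratios)) 1 else spec$axial_ratios,
                      nrow(centers))
  } else {
    n <- spec$n_spheroids
    radii <- stats::runif(n, spec$radius_range[1], spec$radius_range[2])
    ratios <- stats::runif(n, spec$axial_ratio_range[1], spec$axial_ratio_range[2])
    # rejection-sample placements; a greedy sequence can paint itself
    # into a corner, so the whole configuration is restarted as needed
    placed <- FALSE
    for (restart in 1:25) {
      centers <- matrix(NA_real_, n, 3)
      failed <- FALSE
      for (k in seq_len(n)) {
        r <- radii[k]; cz <- r * ratios[k]
        if (2 * r >= min(ext[2], ext[3]) || 2 * cz > ext[1])
          stop("spheroid does not fit in the volume; enlarge it or shrink radius_range")
        ok <- FALSE
        for (try in 1:200) {
          x <- stats::runif(1, r, ext[3] - r)
          y <- stats::runif(1, r, ext[2] - r)
          z <- stats::runif(1, min(cz, ext[1] / 2), max(cz, ext[1] - cz))
          if (!spec$allow_overlap && k > 1) {
            dd <- sqrt((centers[seq_len(k - 1), 1] - x)^2 +
                         (centers[seq_len(k - 1), 2] - y)^2)
            if (any(dd < radii[seq_len(k - 1)] + r + spec$min_gap)) next
          }
          centers[k, ] <- c(x, y, z)
          ok <- TRUE
          break
        }
        if (!ok) { failed <- TRUE; break }
      }
      if (!failed) { placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping spheroids; shrink radius_range or enlarge the volume")
  }
  n <- nrow(centers)
  c_axes <- radii * ratios

  # tissue occupancy and per-voxel labels (first spheroid wins overlaps)
  label_vol <- array(0L, d)
  zg <- (seq_len(d[1]) - 1) * zs
  yg <- (seq_len(d[2]) - 1) * px
  xg <- (seq_len(d[3]) - 1) * px
  for (k in seq_len(n)) {
    zi <- which(abs(zg - centers[k, 3]) <= c_axes[k])
    yi <- which(abs(yg - centers[k, 2]) <= radii[k])
    xi <- which(abs(xg - centers[k, 1]) <= radii[k])
    if (!length(zi) || !length(yi) || !length(xi)) next
    u2 <- ((zg[zi] - centers[k, 3]) / c_axes[k])^2
    v2 <- ((yg[yi] - centers[k, 2]) / radii[k])^2
    w2 <- ((xg[xi] - centers[k, 1]) / radii[k])^2
    inside <- outer(outer(u2, v2, `+`), w2, `+`) <= 1
    sub <- label_vol[zi, yi, xi, drop = FALSE]
    sub[inside & sub == 0L] <- k
    label_vol[zi, yi, xi] <- sub
  }

  # cells
  v_cell <- 4 / 3 * pi * (spec$cell_diameter / 2)^3
  sigma_um <- spec$cell_diameter / 4
  cells <- list()
  for (k in seq_len(n)) {
    vol_k <- 4 / 3 * pi * radii[k]^2 * c_axes[k]
    n_cells <- max(1L, round(spec$packing_fraction * vol_k / v_cell))
    b <- runif_ball(n_cells)
    pos <- cbind(x = centers[k, 1] + b[, 1] * radii[k],
                 y = centers[k, 2] + b[, 2] * radii[k],
                 z = centers[k, 3] + b[, 3] * c_axes[k])
    cells[[k]] <- tibble::tibble(spheroid = k, x = pos[, "x"],
                                 y = pos[, "y"], z = pos[, "z"])
  }
  cells <- do.call(rbind, cells)
  n_total <- nrow(cells)

  # positive subset. Without a spacing constraint: an exact-count random
  # subset of the cells. With one: a stationary hard-core (Matern II)
  # process per spheroid -- candidates are drawn in the ellipsoid
  # enlarged by the spacing radius so points near the tissue boundary
  # compete with (discarded) outside candidates; plain greedy spacing
  # inside the domain would over-seed the surface and bias any
  # volume-proportional count comparison.
  n_pos <- round(spec$positive_fraction * n_total)
  if (spec$min_spot_spacing > 0) {
    s <- spec$min_spot_spacing
    pos_list <- list()
    for (k in seq_len(n)) {
      n_cells_k <- sum(cells$spheroid == k)
      target <- round(spec$positive_fraction * n_cells_k)
      if (target < 1) next
      ae <- radii[k] + s; ce <- c_axes[k] + s
      n_cand <- max(100L, 25L * target)
      b <- runif_ball(n_cand)
      cand <- cbind(x = centers[k, 1] + b[, 1] * ae,
                    y = centers[k, 2] + b[, 2] * ae,
                    z = centers[k, 3] + b[, 3] * ce)
      marks <- sample.int(n_cand)
      keep <- logical(n_cand)
      for (i in seq_len(n_cand)) {
        d2 <- (cand[, 1] - cand[i, 1])^2 + (cand[, 2] - cand[i, 2])^2 +
          (cand[, 3] - cand[i, 3])^2
        rival <- d2 < s^2 & marks < marks[i]
        keep[i] <- !any(rival)
      }
      inside <- ((cand[, 1] - centers[k, 1]) / radii[k])^2 +
        ((cand[, 2] - centers[k, 2]) / radii[k])^2 +
        ((cand[, 3] - centers[k, 3]) / c_axes[k])^2 <= 1
      sel <- which(keep & inside)
      if (length(sel) > target) sel <- sample(sel, target)
      if (length(sel))
        pos_list[[length(pos_list) + 1]] <- tibble::tibble(
          spheroid = k, x = cand[sel, 1], y = cand[sel, 2], z = cand[sel, 3])
    }
    positives <- if (length(pos_list)) do.call(rbind, pos_list) else
      cells[integer(0), , drop = FALSE]
  } else {
    positives <- cells[sample.int(n_total)[seq_len(n_pos)], , drop = FALSE]
  }

  # render channels (blob positions in voxel frame, 1-based). The stable
  # channel is a whole-cell label, constant inside tissue up to
  # cell-scale modulation; the marker is nuclear, so its blobs stay
  # nucleus-sized and isolated.
  stable <- array(0, d)
  stable[label_vol > 0] <- spec$cell_intensity
  marker <- array(0, d)
  cell_sigma <- spec$cell_diameter / 3
  amp_jitter <- stats::runif(n_total, 0.7, 1.3)
  for (i in seq_len(n_total)) {
    stable <- add_blob(stable, cells$z[i] / zs + 1, cells$y[i] / px + 1,
                       cells$x[i] / px + 1,
                       spec$texture_strength * spec$cell_intensity * amp_jitter[i],
                       cell_sigma / zs, cell_sigma / px)
  }
  for (i in seq_len(nrow(positives))) {
    marker <- add_blob(marker, positives$z[i] / zs + 1,
                       positives$y[i] / px + 1, positives$x[i] / px + 1,
                       spec$spot_intensity, sigma_um / zs, sigma_um / px)
  }

  # Beer-Lambert attenuation: path length of tissue strictly above a voxel
  if (spec$mu > 0) {
    tissue <- label_vol > 0
    cum <- apply(tissue, c(2, 3), cumsum)          # inclusive, dims (z, y, x)
    att <- exp(-spec$mu * zs * (cum - tissue))
    stable <- stable * att
    marker <- marker * att
  }

  # optics and camera
  stable <- gauss_blur_arr3(stable, spec$psf_sigma_z / zs,
                            spec$psf_sigma_xy / px, spec$psf_sigma_xy / px)
  marker <- gauss_blur_arr3(marker, spec$psf_sigma_z / zs,
                            spec$psf_sigma_xy / px, spec$psf_sigma_xy / px)
  quantize <- function(a) {
    a <- a + spec$background_level +
      stats::rnorm(length(a), sd = spec$noise_sd)
    array(pmin(pmax(round(a), 0), 65535), d)
  }
  stable <- quantize(stable)
  marker <- quantize(marker)

  # 2D ground-truth masks: topmost tissue label per column
  masks <- matrix(0L, d[2], d[3])
  for (z in rev(seq_len(d[1]))) {
    sl <- label_vol[z, , ]
    masks[sl > 0] <- sl[sl > 0]
  }

  structure(list(
    stable = image_stack(stable, px, zs, channel = "stable",
                         cell_diameter = spec$cell_diameter),
    marker = image_stack(marker, px, zs, channel = "marker",
                         cell_diameter = spec$cell_diameter),
    spec = spec,
    truth = list(
      ellipsoids = tibble::tibble(
        label = seq_len(n), x = centers[, 1], y = centers[, 2],
        z = centers[, 3], a = radii, b = radii, c = c_axes,
        volume = 4 / 3 * pi * radii^2 * c_axes),
      spots = positives,
      masks = masks, label_volume = label_vol,
      n_cells = n_total)),
    class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d spheroid(s), %d cells (%d positive), volume %s voxels\n",
              nrow(x$truth$ellipsoids), x$truth$n_cells, nrow(x$truth$spots),
              paste(x$spec$volume_shape, collapse = " x ")))
  invisible(x)
}

#' Render isolated nuclei into a blank stack
#'
#' Gaussian-blob nuclei at given positions on a constant background --
#' the minimal test bed for the spot detector (no spheroid, no
#' attenuation).
#'
#' @param volume_shape `c(z, y, x)` voxels.
#' @param centers_um Matrix with columns x, y, z (um).
#' @param pixel_size_xy,z_step Calibration (um).
#' @param nucleus_sigma Blob sigma (um). Default 3.
#' @param intensity Blob amplitude.
#' @param background_level,noise_sd Background and noise.
#' @param seed Seed for the noise.
#' @return An [image_stack()].
#' @export
render_nuclei_stack <- function(volume_shape, centers_um, pixel_size_xy = 1.3,
                                z_step = 10, nucleus_sigma = 3,
                                intensity = 500, background_level = 100,
                                noise_sd = 5, seed = 1L) {
  withr::with_seed(seed, {
    a <- array(0, volume_shape)
    for (i in seq_len(nrow(centers_um)))
      a <- add_blob(a, centers_um[i, 3] / z_step + 1,
                    centers_um[i, 2] / pixel_size_xy + 1,
                    centers_um[i, 1] / pixel_size_xy + 1,
                    intensity, nucleus_sigma / z_step,
                    nucleus_sigma / pixel_size_xy)
    a <- a + background_level + stats::rnorm(length(a), sd = noise_sd)
    image_stack(array(pmin(pmax(round(a), 0), 65535), volume_shape),
                pixel_size_xy, z_step, channel = "marker")
  })
}
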