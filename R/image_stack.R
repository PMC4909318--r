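#' Calibrated 3D image stack
#'
#' Container for a single-channel confocal z-stack with anisotropic voxels.
#' Voxels are stored as a 3D array indexed `[z, y, x]`, with the z index
#' increasing with imaging depth into the sample (away from the objective);
#' the "top" of an object is therefore its lowest-z side. Stacks acquired in
#' the opposite order can be reversed with [flip_stack()].
#'
#' The 2.5D method assumes the z-step is no larger than the average cell
#' diameter; a coarser sampling triggers a warning (not an error) because
#' the projections are still well-defined, only the axial estimates degrade.
#'
#' @param voxels 3D numeric array `[z, y, x]` of non-negative, finite
#'   intensities (arbitrary units).
#' @param pixel_size_xy Lateral pixel size in micrometers.
#' @param z_step Axial slice spacing in micrometers.
#' @param channel Channel name (informational), e.g. `"RFP"` or `"EdU"`.
#' @param cell_diameter Average cell diameter in micrometers, used only for
#'   the z-sampling warning. Default 12.
#'
#' @return An object of class `image_stack` with fields `voxels`,
#'   `pixel_size_xy`, `z_step`, `channel`.
#' @examples
#' st <- image_stack(array(1, c(3, 4, 5)), pixel_size_xy = 1.3, z_step = 10)
#' dim(st$voxels)
#' @export
image_stack <- function(voxels, pixel_size_xy, z_step, channel = "",
                        cell_diameter = 12) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("`voxels` must be a 3D array indexed [z, y, x]")
  if (!all(is.finite(voxels)))
    stop("all voxel intensities must be finite")
  if (min(voxels) < 0)
    stop("voxel intensities must be >= 0")
  if (!is.numeric(pixel_size_xy) || pixel_size_xy <= 0)
    stop("`pixel_size_xy` must be > 0")
  if (!is.numeric(z_step) || z_step <= 0)
    stop("`z_step` must be > 0")
  if (z_step > cell_diameter)
    warning(sprintf(
      "z_step (%.3g um) exceeds the average cell diameter (%.3g um); axial estimates will be coarse",
      z_step, cell_diameter))
  structure(
    list(voxels = voxels, pixel_size_xy = pixel_size_xy, z_step = z_step,
         channel = channel),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %s%d slices x %d x %d px, %.3g um/px, z-step %.3g um\n",
              if (nzchar(x$channel)) paste0(x$channel, ": ") else "",
              d[1], d[2], d[3], x$pixel_size_xy, x$z_step))
  invisible(x)
}

#' Reverse the slice order of a stack
#'
#' For stacks acquired with z decreasing into the sample, so that the
#' package's depth convention (z index grows with depth) holds.
#'
#' @param stack An [image_stack()].
#' @return An `image_stack` with slices reversed.
#' @export
flip_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack$voxels)[1]
  stack$voxels <- stack$voxels[rev(seq_len(nz)), , , drop = FALSE]
  stack
}

#' Maximum intensity projection and height view
#'
#' Collapses a stack along z. For every pixel the MIP keeps the maximum
#' intensity over all slices and the height view (Z-buffer) the slice index
#' at which that maximum occurred (ties broken toward the first, i.e.
#' shallowest, slice). The height view is locally homogeneous over objects
#' and noisy over background, which is what the 2D segmentation exploits.
#'
#' @param stack An [image_stack()] with at least two slices.
#' @return An object of class `projection_pair`: `mip` (matrix `[y, x]`),
#'   `height` (integer matrix of 1-based slice indices), `n_slices`,
#'   `z_step`, `pixel_size_xy`, `channel`.
#' @examples
#' a <- array(0, c(4, 6, 6)); a[3, 2, 5] <- 9
#' p <- compute_projection(image_stack(a, 1, 10))
#' p$mip[2, 5]; p$height[2, 5]
#' @export
compute_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (d[1] < 2)
    stop("stack must have at least 2 slices to compute a projection")
  mip <- stack$voxels[1, , ]
  height <- matrix(1L, d[2], d[3])
  for (z in 2:d[1]) {
    cur <- stack$voxels[z, , ]
    upd <- cur > mip
    mip[upd] <- cur[upd]
    height[upd] <- z
  }
  structure(
    list(mip = mip, height = height, n_slices = d[1],
         z_step = stack$z_step, pixel_size_xy = stack$pixel_size_xy,
         channel = stack$channel),
    class = "projection_pair")
}

#' @export
print.projection_pair <- function(x, ...) {
  cat(sprintf("<projection_pair> %d x %d px over %d slices (%.3g um/px, z-step %.3g um)\n",
              nrow(x$mip), ncol(x$mip), x$n_slices, x$pixel_size_xy, x$z_step))
  invisible(x)
}
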