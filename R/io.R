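#' Read a calibrated image stack from a multi-page TIFF
#'
#' Loads one channel from a grayscale multi-page TIFF (including
#' OME-TIFFs saved as plain pages). Calibration is taken from the YAML
#' sidecar written by [write_stack()] (`<path>.cal.yaml`); explicit
#' arguments override it and are required when neither is available.
#'
#' @param path TIFF path with >= 2 z-slices.
#' @param pixel_size_xy,z_step Calibration overrides (um).
#' @param channel Channel name to attach.
#' @param flip_z Reverse slice order on load (for stacks acquired with z
#'   decreasing into the sample). Default FALSE.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_xy = NULL, z_step = NULL,
                       channel = "", flip_z = FALSE) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) stop("stack must have at least 2 z-slices")
  if (length(dim(pages[[1]])) != 2)
    stop("only single-sample (grayscale) TIFF pages are supported")
  sidecar <- paste0(path, ".cal.yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (is.null(pixel_size_xy)) pixel_size_xy <- meta$pixel_size_xy
    if (is.null(z_step)) z_step <- meta$z_step
  }
  if (is.null(pixel_size_xy) || is.null(z_step))
    stop("missing calibration: supply `pixel_size_xy` and `z_step` or use a calibrated TIFF")
  d <- dim(pages[[1]])
  vox <- array(0, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) vox[z, , ] <- pages[[z]]
  st <- image_stack(vox, pixel_size_xy, z_step, channel = channel)
  if (flip_z) st <- flip_stack(st)
  st
}

#' Write an image stack as a calibrated multi-page TIFF
#'
#' 16-bit grayscale pages plus a small YAML sidecar (`<path>.cal.yaml`)
#' carrying the calibration in micrometers, so [read_stack()] round-trips
#' voxel values and calibration exactly. Intensities must fit 16 bits.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (max(stack$voxels) > 65535)
    stop("intensities exceed the 16-bit range")
  pages <- lapply(seq_len(dim(stack$voxels)[1]),
                  function(z) stack$voxels[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none",
                  reduce = FALSE)
  yaml::write_yaml(list(pixel_size_xy = stack$pixel_size_xy,
                        z_step = stack$z_step, unit = "micron",
                        channel = stack$channel),
                   paste0(path, ".cal.yaml"))
  invisible(path)
}

#' Write a label image as a 16-bit single-plane TIFF
#'
#' @param labels Integer label matrix (values < 65536).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535) stop("too many labels for a 16-bit TIFF")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read a label image written by [write_label_tiff()]
#' @param path TIFF path.
#' @return Integer matrix.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Write a synthetic scene and its ground truth to disk
#'
#' Saves both channels as calibrated TIFF stacks plus a ground-truth
#' bundle: the true 2D label masks (TIFF), true ellipsoids and positive
#' cells (JSON), and the scene parameters.
#'
#' @param scene A [generate_scene()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(stable = file.path(dir, "stable.tif"),
                marker = file.path(dir, "marker.tif"),
                masks = file.path(dir, "true_masks.tif"),
                truth = file.path(dir, "truth.json"))
  write_stack(scene$stable, paths$stable)
  write_stack(scene$marker, paths$marker)
  write_label_tiff(scene$truth$masks, paths$masks)
  spec <- scene$spec
  spec$centers <- if (is.null(spec$centers)) NULL else as.data.frame(spec$centers)
  jsonlite::write_json(list(
    spec = spec[!vapply(spec, is.null, logical(1))],
    ellipsoids = scene$truth$ellipsoids,
    spots = scene$truth$spots,
    n_cells = scene$truth$n_cells), paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
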