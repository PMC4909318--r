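#' Segmentation parameters
#'
#' Parameters of the 2D spheroid segmentation. Defaults follow the
#' method's standard settings: cell diameter 12 um, range-filter radius
#' 3 um (one fourth of a cell diameter), and data-driven ("auto")
#' thresholds for the height-view range and the minimum mean MIP intensity.
#'
#' @param cell_diameter Average cell diameter (um). Default 12.
#' @param r_range Neighborhood radius of the range filter (um). Default 3.
#' @param max_z_range Threshold on the range-filtered height view, in
#'   z-slice units, or `"auto"` to derive it from the histogram of the
#'   range image (extent of its first peak).
#' @param min_mip Threshold on the mean MIP intensity of a segmented
#'   object, or `"auto"` for the mean background intensity of the MIP.
#' @param min_object_area Minimum object area (um^2) kept after
#'   thresholding; defaults to one cell's footprint, pi*(cell_diameter/2)^2.
#' @param keep_border Keep objects touching the image border (they are
#'   flagged in the output either way). Default TRUE.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(cell_diameter = 12, r_range = 3,
                                max_z_range = "auto", min_mip = "auto",
                                min_object_area = NULL, keep_border = TRUE) {
  stopifnot(cell_diameter > 0, r_range > 0)
  if (is.null(min_object_area))
    min_object_area <- pi * (cell_diameter / 2)^2
  structure(list(cell_diameter = cell_diameter, r_range = r_range,
                 max_z_range = max_z_range, min_mip = min_mip,
                 min_object_area = min_object_area,
                 keep_border = keep_border),
            class = "segmentation_params")
}

#' Range filter (local max - min) over a disk neighborhood
#'
#' For every pixel, the difference between the maximum and minimum value
#' within a disk of radius `r_px` pixels. Applied to the height view it
#' measures local z-inhomogeneity: spheroid surfaces are smooth in z,
#' background pixels jump randomly between slices. Neighborhoods at the
#' image border are clipped to valid pixels.
#'
#' @param height Numeric matrix (typically the height view, `[y, x]`).
#' @param r_px Disk radius in pixels (>= 1).
#' @return Matrix of the same shape with per-pixel local ranges.
#' @examples
#' h <- matrix(5, 7, 7); h[4, 4] <- 9
#' range_filter(h, 2)[4, 4]
#' @export
range_filter <- function(height, r_px) {
  stopifnot(is.matrix(height), r_px >= 1)
  off <- disk_offsets(r_px)
  mx <- matrix(-Inf, nrow(height), ncol(height))
  mn <- matrix(Inf, nrow(height), ncol(height))
  for (i in seq_len(nrow(off))) {
    s_max <- shift_mat(height, off$dy[i], off$dx[i], fill = -Inf)
    s_min <- shift_mat(height, off$dy[i], off$dx[i], fill = Inf)
    mx <- pmax(mx, s_max)
    mn <- pmin(mn, s_min)
  }
  mx - mn
}

#' Automatic threshold on the range-filtered height view
#'
#' Derives the `max_z_range` threshold from the histogram of the integer
#' z-ranges: the histogram (bin width one slice) is smoothed with a 3-bin
#' moving average, the first nonzero peak located, and the threshold set at
#' the first bin after the peak whose (smoothed) count falls below 10% of
#' the peak count -- the "extent of the first peak". Spheroid pixels form
#' this low-range peak; background ranges spread toward the slice count.
#'
#' Degenerate histograms (constant range image, no resolvable low-range
#' peak) fall back to half the slice count with a warning.
#'
#' @param range_image Matrix of z-ranges from [range_filter()].
#' @param n_slices Number of slices in the originating stack; used for the
#'   fallback. If `NULL`, `max(range_image) + 1` is used as a stand-in.
#' @return Threshold in z-slice units (foreground = range <= threshold).
#' @export
auto_threshold_zrange <- function(range_image, n_slices = NULL) {
  v <- as.integer(round(range_image))
  maxr <- max(v)
  fallback <- if (is.null(n_slices)) (maxr + 1) / 2 else n_slices / 2
  if (length(unique(v)) < 2) {
    warning("range image is degenerate (constant); falling back to half the slice count")
    return(fallback)
  }
  counts <- tabulate(v + 1L, nbins = maxr + 1L)  # bins for ranges 0..maxr
  s <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  s[1] <- (counts[1] + counts[2]) / 3
  s[length(s)] <- (counts[length(counts) - 1] + counts[length(counts)]) / 3
  peak <- NA_integer_
  for (i in seq_len(length(s) - 1)) {
    if (s[i] > 0 && s[i] >= s[i + 1]) { peak <- i; break }
  }
  if (is.na(peak)) {
    warning("no peak found in range histogram; falling back to half the slice count")
    return(fallback)
  }
  after <- which(s < 0.1 * s[peak] & seq_along(s) > peak)
  if (length(after) == 0) {
    warning("range histogram has no resolvable first peak; falling back to half the slice count")
    return(fallback)
  }
  thr <- after[1] - 1  # bin index -> range value
  if (thr > maxr / 2) {
    warning("no homogeneous low-range peak in the height view; falling back to half the slice count")
    return(fallback)
  }
  thr
}

#' Mean background intensity of the MIP
#'
#' Arithmetic mean of the MIP over pixels outside the foreground mask;
#' this is the automatic value of the `min_mip` object-intensity threshold.
#'
#' @param mip Intensity matrix.
#' @param foreground Logical matrix of the same shape.
#' @return Mean background intensity (scalar).
#' @export
estimate_background_mean <- function(mip, foreground) {
  stopifnot(is.matrix(mip), identical(dim(mip), dim(foreground)))
  if (all(foreground))
    stop("foreground covers the whole image; background mean undefined")
  mean(mip[!foreground])
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so 4-connected
# labels are merged across diagonal adjacencies with a union-find pass.
label_components8 <- function(fg) {
  l4 <- matrix(as.integer(EBImage::bwlabel(fg * 1)), nrow(fg), ncol(fg))
  n <- max(l4)
  if (n <= 1) return(l4)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (dxy in list(c(1, 1), c(1, -1))) {
    nb <- shift_mat(l4, dxy[1], dxy[2], fill = 0)
    sel <- l4 > 0 & nb > 0 & l4 != nb
    if (!any(sel)) next
    pairs <- unique(cbind(as.integer(l4[sel]), as.integer(nb[sel])))
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- matrix(0L, nrow(fg), ncol(fg))
  out[l4 > 0] <- relab[l4[l4 > 0]]
  out
}

relabel_sequential <- function(labels, keep) {
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (length(keep) == 0) return(out)
  m <- match(labels, keep)
  out[!is.na(m)] <- m[!is.na(m)]
  out
}

#' Segment 2D spheroid masks from a projection pair
#'
#' The 2D segmentation pipeline: range-filter the height view, threshold
#' at `max_z_range` (foreground = locally homogeneous, range <= threshold),
#' fill holes and drop objects smaller than one cell footprint, label
#' 8-connected components, and finally discard components whose mean MIP
#' intensity falls below `min_mip` (spurious dim objects). Objects touching
#' the image border are kept but flagged.
#'
#' @param proj A [compute_projection()] result.
#' @param params A [segmentation_params()] list.
#' @return An object of class `spheroid_segmentation`: `labels` (integer
#'   label matrix, 0 = background), `spheroids` (tibble with one row per
#'   object: `label`, `area_px`, `area_um2`, `mean_mip`, centroid
#'   `xc_px`/`yc_px` (0-based), `touches_border`), and `resolved` (the
#'   thresholds actually used).
#' @export
segment_spheroids <- function(proj, params = segmentation_params()) {
  stopifnot(inherits(proj, "projection_pair"))
  px <- proj$pixel_size_xy
  r_px <- max(1L, round(params$r_range / px))
  rng <- range_filter(proj$height, r_px)
  thr <- params$max_z_range
  if (identical(thr, "auto")) thr <- auto_threshold_zrange(rng, proj$n_slices)
  fg <- rng <= thr
  # majority smoothing: thresholding the height view leaves single-pixel
  # speckle and boundary roughness that would distort Feret diameters
  nb <- fg * 1
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- nb + shift_mat(fg * 1, dy, dx, fill = 0)
  }
  fg <- nb >= 5
  labels <- label_components8(fg)
  labels <- matrix(as.integer(EBImage::fillHull(labels)), nrow(fg), ncol(fg))
  # drop sub-cellular speckle
  min_area_px <- ceiling(params$min_object_area / px^2)
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area_px)
  labels <- relabel_sequential(labels, keep)
  fg2 <- labels > 0
  min_mip <- params$min_mip
  if (identical(min_mip, "auto")) min_mip <- estimate_background_mean(proj$mip, fg2)
  n <- max(labels)
  if (n == 0) {
    return(structure(list(labels = labels, spheroids = empty_spheroid_tbl(),
                          resolved = list(max_z_range = thr, min_mip = min_mip,
                                          r_px = r_px)),
                     class = "spheroid_segmentation"))
  }
  idx <- which(labels > 0)
  lab_v <- labels[idx]
  mean_mip <- as.numeric(tapply(proj$mip[idx], lab_v, mean))
  keep2 <- which(mean_mip >= min_mip)
  labels <- relabel_sequential(labels, keep2)
  n <- max(labels)
  if (n == 0) {
    return(structure(list(labels = labels, spheroids = empty_spheroid_tbl(),
                          resolved = list(max_z_range = thr, min_mip = min_mip,
                                          r_px = r_px)),
                     class = "spheroid_segmentation"))
  }
  idx <- which(labels > 0)
  arr <- arrayInd(idx, dim(labels))
  lab_v <- labels[idx]
  area_px <- tabulate(lab_v, n)
  tb <- tibble::tibble(
    label = seq_len(n),
    area_px = area_px,
    area_um2 = area_px * px^2,
    mean_mip = as.numeric(tapply(proj$mip[idx], lab_v, mean)),
    xc_px = as.numeric(tapply(arr[, 2] - 1, lab_v, mean)),
    yc_px = as.numeric(tapply(arr[, 1] - 1, lab_v, mean)),
    touches_border = as.logical(tapply(
      arr[, 1] == 1 | arr[, 1] == nrow(labels) |
        arr[, 2] == 1 | arr[, 2] == ncol(labels), lab_v, any)))
  if (!params$keep_border && any(tb$touches_border)) {
    keep3 <- tb$label[!tb$touches_border]
    labels <- relabel_sequential(labels, keep3)
    tb <- tb[!tb$touches_border, ]
    tb$label <- seq_len(nrow(tb))
  }
  structure(list(labels = labels, spheroids = tb,
                 resolved = list(max_z_range = thr, min_mip = min_mip,
                                 r_px = r_px)),
            class = "spheroid_segmentation")
}

empty_spheroid_tbl <- function() {
  tibble::tibble(label = integer(), area_px = integer(), area_um2 = numeric(),
                 mean_mip = numeric(), xc_px = numeric(), yc_px = numeric(),
                 touches_border = logical())
}

#' @export
print.spheroid_segmentation <- function(x, ...) {
  cat(sprintf("<spheroid_segmentation> %d object(s); max_z_range = %.3g, min_mip = %.4g\n",
              nrow(x$spheroids), x$resolved$max_z_range, x$resolved$min_mip))
  invisible(x)
}

#' Extract one object's logical mask from a label image
#'
#' @param labels Integer label matrix.
#' @param label Label to extract.
#' @return Logical matrix.
#' @export
mask_from_labels <- function(labels, label) {
  labels == label
}
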