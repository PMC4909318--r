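#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an axial intensity profile
#'
#' Depth profile I(z) with the detected top coordinate, profile maximum
#' and (when set) the analyzable-depth limit.
#'
#' @param object An [axial_profile()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.axial_profile <- function(object, ...) {
  df <- tibble::tibble(z_um = object$z_um, intensity = object$intensity)
  marks <- tibble::tibble(
    what = c("z_top", "z_at_max", "z_analyzable"),
    z = c(object$z_top, object$z_at_max, object$z_analyzable))
  marks <- marks[!is.na(marks$z), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$z_um, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (µm, depth into sample)", y = "mean intensity",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(marks))
    p <- p + ggplot2::geom_vline(
      data = marks, ggplot2::aes(xintercept = .data$z, colour = .data$what),
      linetype = "dashed")
  p
}

#' Plot the LoG scale-optimization curve
#'
#' Blob-strength score against the Gaussian scale; the maximum marks the
#' scale used for spot detection.
#'
#' @param object An [optimal_log_scale()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.log_scale_opt <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$sigma_um, .data$score)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$sigma, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "LoG scale σ (µm)", y = "blob strength") +
    ggplot2::theme_minimal()
}

ellipse_path <- function(xc, yc, a, b, theta, n = 90) {
  t <- seq(0, 2 * pi, length.out = n)
  tibble::tibble(x = xc + a * cos(t) * cos(theta) - b * sin(t) * sin(theta),
                 y = yc + a * cos(t) * sin(theta) + b * sin(t) * cos(theta))
}

#' Overlay segmentation, ellipses and spots on the MIP
#'
#' @param result A [run_pipeline()] result.
#' @param max_intensity Display clip for the MIP (default: its maximum).
#' @return A ggplot (MIP raster, fitted ellipse outlines colored by
#'   visibility class, detected spots as points).
#' @export
plot_overlay <- function(result, max_intensity = NULL) {
  stopifnot(inherits(result, "spheroid_analysis"))
  mip <- result$projection$mip
  px <- result$projection$pixel_size_xy
  if (is.null(max_intensity)) max_intensity <- max(mip)
  df <- tibble::tibble(
    x = rep((seq_len(ncol(mip)) - 1) * px, each = nrow(mip)),
    y = rep((seq_len(nrow(mip)) - 1) * px, times = ncol(mip)),
    intensity = pmin(as.numeric(mip), max_intensity))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
  sph <- result$spheroids
  sph <- sph[!is.na(sph$a_um), , drop = FALSE]
  if (nrow(sph)) {
    paths <- do.call(rbind, lapply(seq_len(nrow(sph)), function(k) {
      e <- ellipse_path(sph$x_um[k], sph$y_um[k], sph$a_um[k], sph$b_um[k],
                        sph$orientation[k])
      e$label <- sph$label[k]
      e$visibility <- ifelse(is.na(sph$visibility[k]), "unclassified",
                             sph$visibility[k])
      e
    }))
    p <- p + ggplot2::geom_path(
      data = paths,
      ggplot2::aes(group = .data$label, colour = .data$visibility))
  }
  if (nrow(result$spots))
    p <- p + ggplot2::geom_point(
      data = result$spots, ggplot2::aes(.data$x_um, .data$y_um),
      colour = "red", shape = 1, size = 1)
  p
}
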