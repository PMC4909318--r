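#' Pipeline configuration
#'
#' All tunable parameters of the full 2.5D analysis, with the method's
#' standard defaults: cell diameter 12 um, range-filter radius 3 um,
#' data-driven height-range and MIP-intensity thresholds, minimum
#' equivalent radius 24 um for the axial estimate, 50% minimum retained
#' intensity, and 8 um maximal spot radius with an auto-optimized LoG
#' scale.
#'
#' @param cell_diameter Average cell diameter (um). Default 12.
#' @param r_range Range-filter radius (um). Default 3.
#' @param max_z_range Height-range threshold (slices) or `"auto"`.
#' @param min_mip Object mean-MIP threshold or `"auto"`.
#' @param min_radius Minimum equivalent 2D radius (um) for the axial
#'   ellipsoid estimate. Default 24.
#' @param attenuation_percentage Minimal retained signal percentage
#'   defining the analyzable depth. Default 50.
#' @param max_spot_radius Maximal spot radius (um). Default 8.
#' @param spot_scale LoG scale (um) or `"auto"`.
#' @param min_circularity Circularity threshold separating elliptical
#'   from non-elliptical masks. Default 0.8.
#' @param spot_mode `"3d"` or `"2.5d"`.
#' @param baseline_2d Run the uncorrected 2D MIP analysis instead of the
#'   attenuation-aware one. Default FALSE.
#' @param flip_z Reverse slice order on input stacks. Default FALSE.
#' @param keep_border Keep (flagged) border-touching spheroids. Default TRUE.
#' @param wavelength_gap_nm Gap between the stable and marker emission
#'   wavelengths (nm), if known. The attenuation measured on the stable
#'   channel is applied to the marker channel, which assumes similar
#'   wavelengths; a gap above 150 nm triggers a warning unless
#'   `acknowledge_wavelength_gap` is set.
#' @param acknowledge_wavelength_gap Accept a large wavelength gap
#'   silently. Default FALSE.
#' @param seed Seed recorded with the run. Default 1.
#' @return List of class `run_config`.
#' @export
run_config <- function(cell_diameter = 12, r_range = 3, max_z_range = "auto",
                       min_mip = "auto", min_radius = 24,
                       attenuation_percentage = 50, max_spot_radius = 8,
                       spot_scale = "auto", min_circularity = 0.8,
                       spot_mode = c("3d", "2.5d"), baseline_2d = FALSE,
                       flip_z = FALSE, keep_border = TRUE,
                       wavelength_gap_nm = NA_real_,
                       acknowledge_wavelength_gap = FALSE, seed = 1L) {
  spot_mode <- match.arg(spot_mode)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the [run_config()] argument names; missing keys keep their
#' defaults, unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full 2.5D spheroid analysis
#'
#' Orchestrates the whole method on one two-channel stack: projection of
#' the stable channel, 2D segmentation, ellipse fitting and the
#' circularity filter, ellipsoid extrapolation, attenuation
#' classification, spot detection in the marker channel, and
#' attenuation-corrected per-spheroid counting. With
#' `config$baseline_2d = TRUE` the ellipsoid and attenuation stages are
#' skipped and every spot inside a 2D mask counts uncorrected (the
#' baseline MIP analysis used for comparison).
#'
#' Per-spheroid failures (degenerate masks, unusable profiles) are
#' downgraded to warnings; the affected spheroid keeps `NA` features.
#'
#' @param stable Stable-channel (whole-cell label) [image_stack()].
#' @param marker Marker-channel (e.g. EdU) [image_stack()].
#' @param config A [run_config()].
#' @return Object of class `spheroid_analysis`: `spheroids` (one row per
#'   retained 2D object with the output feature set), `spots` (spot
#'   table), `summary` (list: object counts, per-visibility-class counts,
#'   foreground/background MIP ratio, resolved thresholds, config echo),
#'   plus the stable-channel `projection` and `labels` for plotting.
#' @export
run_pipeline <- function(stable, marker, config = run_config()) {
  stopifnot(inherits(stable, "image_stack"), inherits(marker, "image_stack"),
            inherits(config, "run_config"))
  if (!isTRUE(all.equal(stable$pixel_size_xy, marker$pixel_size_xy)) ||
      !isTRUE(all.equal(stable$z_step, marker$z_step)))
    stop("stable and marker channels must share one calibration")
  if (!is.na(config$wavelength_gap_nm) && config$wavelength_gap_nm > 150 &&
      !config$acknowledge_wavelength_gap && !config$baseline_2d)
    warning("stable and marker wavelengths differ by > 150 nm; the cross-channel attenuation assumption may not hold (set `acknowledge_wavelength_gap = TRUE` to silence)")
  if (config$flip_z) {
    stable <- flip_stack(stable)
    marker <- flip_stack(marker)
  }
  px <- stable$pixel_size_xy

  proj <- compute_projection(stable)
  seg <- segment_spheroids(proj, segmentation_params(
    cell_diameter = config$cell_diameter, r_range = config$r_range,
    max_z_range = config$max_z_range, min_mip = config$min_mip,
    keep_border = config$keep_border))
  sph <- seg$spheroids

  n <- nrow(sph)
  sph$circularity <- NA_real_
  for (k in seq_len(n))
    sph$circularity[k] <- circularity(mask_from_labels(seg$labels, sph$label[k]))
  sph$roundness_class <- ifelse(sph$circularity >= config$min_circularity,
                                "elliptical", "non-elliptical")

  ell_cols <- tibble::tibble(
    label = sph$label,
    x_um = NA_real_, y_um = NA_real_, z_um = NA_real_,
    a_um = NA_real_, b_um = NA_real_, c_um = NA_real_,
    orientation = NA_real_, fit_error = NA_real_,
    volume_um3 = NA_real_, z_top_um = NA_real_,
    analyzable_depth_um = NA_real_, depth_uncapped = NA,
    visibility = NA_character_)
  profiles <- vector("list", n)
  for (k in seq_len(n)) {
    if (sph$roundness_class[k] != "elliptical") next
    mask <- mask_from_labels(seg$labels, sph$label[k])
    res <- tryCatch({
      fit <- fit_ellipse(mask, px)
      if (config$baseline_2d) {
        list(fit = fit, ell = NULL, depth = NULL)
      } else {
        ell <- extrapolate_ellipsoid(fit, mask, proj, stable,
                                     min_radius = config$min_radius)
        dep <- analyzable_depth(ell$profile,
                                p_min = config$attenuation_percentage,
                                z_limit = ell$center["z"] + ell$c,
                                z_margin = stable$z_step)
        list(fit = fit, ell = ell, depth = dep)
      }
    }, error = function(e) {
      warning(sprintf("spheroid %d skipped: %s", sph$label[k],
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    ell_cols$x_um[k] <- res$fit$xc; ell_cols$y_um[k] <- res$fit$yc
    ell_cols$a_um[k] <- res$fit$a; ell_cols$b_um[k] <- res$fit$b
    ell_cols$orientation[k] <- res$fit$orientation
    ell_cols$fit_error[k] <- res$fit$fit_error
    if (!is.null(res$ell)) {
      ell_cols$z_um[k] <- res$ell$center["z"]
      ell_cols$c_um[k] <- res$ell$c
      ell_cols$volume_um3[k] <- res$ell$volume
      ell_cols$z_top_um[k] <- res$ell$profile$z_top
      ell_cols$analyzable_depth_um[k] <- res$depth$depth
      ell_cols$depth_uncapped[k] <- res$depth$uncapped
      ell_cols$visibility[k] <-
        classify_visibility(res$ell, res$depth$depth)$class
      profiles[[k]] <- res$ell$profile
    }
  }
  sph <- dplyr::left_join(sph, ell_cols, by = "label")

  # marker channel: spot detection and counting
  mproj <- compute_projection(marker)
  spots <- empty_spot_tbl(config$spot_mode)
  spots$spheroid_label <- integer(0)
  spots$in_analyzable_region <- logical(0)
  scale_used <- NA_real_
  thr_used <- NA_real_
  if (n > 0) {
    scale_used <- config$spot_scale
    if (identical(scale_used, "auto"))
      scale_used <- optimal_log_scale(mproj$mip, config$max_spot_radius,
                                      px)$sigma
    thr_used <- spot_intensity_threshold(proj$mip, seg$labels)
    sp <- spot_params(max_spot_radius = config$max_spot_radius,
                      scale_sigma = scale_used,
                      intensity_threshold = thr_used,
                      mode = config$spot_mode)
    detected <- detect_spots(if (config$spot_mode == "3d") marker else mproj,
                             sp)
    info <- tibble::tibble(label = sph$label, a = sph$a_um, b = sph$b_um,
                           c = sph$c_um, z_top = sph$z_top_um,
                           analyzable_depth = sph$analyzable_depth_um,
                           visibility = sph$visibility)
    ac <- assign_and_count(detected, seg$labels, info,
                           baseline_2d = config$baseline_2d)
    spots <- ac$spots
    sph <- dplyr::left_join(
      sph, ac$counts[, c("label", "n_spots_raw", "n_spots_corrected")],
      by = "label")
  } else {
    sph$n_spots_raw <- integer(0)
    sph$n_spots_corrected <- numeric(0)
  }

  vis_counts <- table(factor(sph$visibility, levels = visibility_classes()))
  summary <- list(
    n_objects = n,
    n_elliptical = sum(sph$roundness_class == "elliptical", na.rm = TRUE),
    visibility_counts = as.list(vis_counts),
    fg_bg_ratio = sum(seg$labels > 0) / max(1, sum(seg$labels == 0)),
    resolved = list(max_z_range = seg$resolved$max_z_range,
                    min_mip = seg$resolved$min_mip,
                    spot_scale = scale_used,
                    spot_intensity_threshold = thr_used),
    config = unclass(config))
  structure(list(spheroids = sph, spots = spots, summary = summary,
                 projection = proj, labels = seg$labels,
                 profiles = profiles),
            class = "spheroid_analysis")
}

#' @export
print.spheroid_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<spheroid_analysis> %d object(s), %d elliptical; visibility full/half/none = %s/%s/%s; %d spot(s)\n",
              s$n_objects, s$n_elliptical,
              s$visibility_counts$full, s$visibility_counts$half,
              s$visibility_counts$not_analyzable, nrow(x$spots)))
  invisible(x)
}

#' @export
tidy.spheroid_analysis <- function(x, ...) x$spheroids

#' @export
glance.spheroid_analysis <- function(x, ...) {
  s <- x$summary
  tibble::tibble(n_objects = s$n_objects, n_elliptical = s$n_elliptical,
                 n_full = s$visibility_counts$full,
                 n_half = s$visibility_counts$half,
                 n_not_analyzable = s$visibility_counts$not_analyzable,
                 n_spots = nrow(x$spots), fg_bg_ratio = s$fg_bg_ratio)
}

#' Write analysis results to disk
#'
#' Per-spheroid features and the spot table as CSV (coordinates both in
#' 0-based pixels and um), the run summary as JSON, and the label mask as
#' 16-bit TIFF. Output is byte-identical across re-runs on the same
#' inputs and configuration.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "spheroid_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(spheroids = file.path(dir, "spheroids.csv"),
                spots = file.path(dir, "spots.csv"),
                summary = file.path(dir, "summary.json"),
                labels = file.path(dir, "labels.tif"))
  utils::write.csv(result$spheroids, paths$spheroids, row.names = FALSE)
  utils::write.csv(result$spots, paths$spots, row.names = FALSE)
  jsonlite::write_json(result$summary, paths$summary, auto_unbox = TRUE,
                       digits = NA)
  write_label_tiff(result$labels, paths$labels)
  invisible(paths)
}

#' Merge run summaries from several imaged fields
#'
#' Wells are often covered by multiple stacks (fields); this aggregates
#' their per-class spheroid counts and total spot numbers.
#'
#' @param results List of [run_pipeline()] results.
#' @return One-row tibble of aggregate counts.
#' @export
aggregate_runs <- function(results) {
  gl <- do.call(rbind, lapply(results, glance))
  tibble::tibble(n_fields = nrow(gl),
                 n_objects = sum(gl$n_objects),
                 n_full = sum(gl$n_full), n_half = sum(gl$n_half),
                 n_not_analyzable = sum(gl$n_not_analyzable),
                 n_spots = sum(gl$n_spots),
                 mean_fg_bg_ratio = mean(gl$fg_bg_ratio))
}
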