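#' Match automatic segmentation regions against ground truth
#'
#' For every ground-truth region `M_j` a candidate automatic region `m_i`
#' covering more than 50% of `M_j`'s area is sought; matched pairs are
#' true positives, unmatched ground-truth regions false negatives, and
#' automatic regions covering no ground-truth region false positives.
#' Since two automatic regions cannot each cover more than half of the
#' same `M_j`, a candidate is unique per ground-truth region; the converse
#' (one `m_i` dominating several `M_j`, e.g. a mask merging spheroids) is
#' resolved by assigning `m_i` to the `M_j` with the largest covered
#' fraction, the others becoming false negatives, and the event is
#' recorded in `merged_events`.
#'
#' @param auto_labels Integer label matrix of the automatic segmentation.
#' @param gt_labels Integer label matrix of the ground truth (same frame).
#' @param conf Confidence level for the Wilson interval. Default 0.95.
#' @return Object of class `match_result`: `tp`, `fp`, `fn`, `pairs`
#'   (tibble `gt_label`, `auto_label`, `covered_fraction`), `sensitivity`,
#'   `wilson_low`, `wilson_high`, `merged_events`.
#' @export
match_regions <- function(auto_labels, gt_labels, conf = 0.95) {
  stopifnot(identical(dim(auto_labels), dim(gt_labels)))
  gt_ids <- setdiff(sort(unique(as.integer(gt_labels))), 0L)
  auto_ids <- setdiff(sort(unique(as.integer(auto_labels))), 0L)
  idx <- which(gt_labels > 0)
  ov <- tibble::tibble(gt = as.integer(gt_labels[idx]),
                       auto = as.integer(auto_labels[idx]))
  ov <- ov[ov$auto > 0, , drop = FALSE]
  gt_area <- tabulate(as.integer(gt_labels[idx]),
                      nbins = max(gt_ids, 0L))
  cand <- tibble::tibble(gt_label = integer(), auto_label = integer(),
                         covered_fraction = numeric())
  if (nrow(ov) > 0) {
    agg <- stats::aggregate(list(n = rep(1L, nrow(ov))),
                            by = list(gt = ov$gt, auto = ov$auto), FUN = sum)
    agg$frac <- agg$n / gt_area[agg$gt]
    agg <- agg[agg$frac > 0.5, , drop = FALSE]
    cand <- tibble::tibble(gt_label = agg$gt, auto_label = agg$auto,
                           covered_fraction = agg$frac)
  }
  merged_events <- 0L
  pairs <- cand[0, ]
  if (nrow(cand) > 0) {
    # one auto region may dominate several GT regions: keep largest fraction
    cand <- cand[order(cand$auto_label, -cand$covered_fraction), ]
    dup <- duplicated(cand$auto_label)
    merged_events <- sum(dup)
    pairs <- cand[!dup, , drop = FALSE]
  }
  tp <- nrow(pairs)
  fn <- length(gt_ids) - tp
  belongs <- unique(cand$auto_label)  # auto regions covering >50% of some GT
  fp <- length(setdiff(auto_ids, belongs))
  sens <- if (tp + fn > 0) sensitivity_wilson(tp, fn, conf) else
    tibble::tibble(sensitivity = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  structure(list(tp = tp, fp = fp, fn = fn, pairs = pairs,
                 sensitivity = sens$sensitivity,
                 wilson_low = sens$ci_low, wilson_high = sens$ci_high,
                 merged_events = merged_events, conf = conf),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP = %d, FP = %d, FN = %d; sensitivity = %.3f [%.3f, %.3f]\n",
              x$tp, x$fp, x$fn, x$sensitivity, x$wilson_low, x$wilson_high))
  invisible(x)
}

#' Sensitivity with Wilson score interval
#'
#' Detection sensitivity `TP / (TP + FN)` with the Wilson score interval,
#' which keeps good coverage at small n and never leaves `[0, 1]`:
#' `(p + z^2/2n +/- z*sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)`.
#'
#' @param tp,fn True positive and false negative counts (vectors allowed);
#'   `tp + fn` must be positive.
#' @param conf Confidence level. Default 0.95.
#' @return Tibble: `sensitivity`, `ci_low`, `ci_high`.
#' @examples
#' sensitivity_wilson(10, 0)
#' @export
sensitivity_wilson <- function(tp, fn, conf = 0.95) {
  n <- tp + fn
  if (any(n <= 0)) stop("tp + fn must be positive")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- tp / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(sensitivity = p, ci_low = pmax(0, center - half),
                 ci_high = pmin(1, center + half))
}

# 8-connected contour: mask pixels with >= 1 background 8-neighbor
# (pixels on the image border count as contour).
contour_pixels <- function(mask) {
  inner <- mask
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    inner <- inner & shift_mat(mask, dy, dx, FALSE)
  }
  mask & !inner
}

#' Sigmoid-weighted contour accuracy of a matched mask pair
#'
#' Every pixel of the symmetric difference between the automatic mask
#' `m_i` and its ground-truth partner `M_j` is penalized by a sigmoid
#' `f(x) = 1 / (1 + exp(-k (x - x0)))` of its Euclidean distance (um)
#' from `M_j`'s contour, so sub-pixel boundary jitter contributes little
#' while gross errors saturate at weight 1. The penalty
#' `e_i = sum(f) / area(M_j)` gives the accuracy `1 - e_i` (1 for
#' identical masks; may go negative for grossly oversized candidates --
#' see the `clamped` attribute for a floor-at-zero convenience value).
#'
#' @param auto_mask,gt_mask Logical matrices in the same frame.
#' @param pixel_size_xy Pixel size in um.
#' @param x0 Sigmoid midpoint in um. Default 1.5.
#' @param k Sigmoid steepness in 1/um. Default 2.
#' @return Accuracy `1 - e_i` (scalar, attribute `clamped` = max(0, .)).
#' @export
contour_accuracy <- function(auto_mask, gt_mask, pixel_size_xy = 1,
                             x0 = 1.5, k = 2) {
  stopifnot(identical(dim(auto_mask), dim(gt_mask)))
  area <- sum(gt_mask)
  if (area == 0) stop("ground-truth mask is empty")
  contour <- contour_pixels(gt_mask)
  dist_px <- EBImage::distmap(matrix(as.numeric(!contour), nrow(gt_mask)))
  dist_um <- as.numeric(dist_px) * pixel_size_xy
  dim(dist_um) <- dim(gt_mask)
  sym <- xor(auto_mask, gt_mask)
  f <- 1 / (1 + exp(-k * (dist_um[sym] - x0)))
  acc <- 1 - sum(f) / area
  attr(acc, "clamped") <- max(0, acc)
  acc
}

#' Validate a segmentation against ground-truth masks
#'
#' Full ground-truth comparison: region matching, Wilson-interval
#' sensitivity, and per-pair contour accuracies, optionally broken down
#' by ground-truth class (1 well separated, 2 overlapping a brighter
#' spheroid, 3 overlapping a dimmer one, 4 touching, 5 at the image
#' border).
#'
#' @param auto_labels Automatic label matrix.
#' @param gt_labels Ground-truth label matrix.
#' @param pixel_size_xy Pixel size in um.
#' @param gt_classes Optional tibble `label`, `gt_class` (1..5).
#' @param conf Confidence level. Default 0.95.
#' @return Object of class `validation_report`: the `match_result`, a
#'   `pairs` tibble with per-pair `accuracy` (and `gt_class` if given),
#'   `mean_accuracy`, and a `by_class` breakdown when classes are known.
#' @export
validate_segmentation <- function(auto_labels, gt_labels, pixel_size_xy = 1,
                                  gt_classes = NULL, conf = 0.95) {
  mr <- match_regions(auto_labels, gt_labels, conf)
  pairs <- mr$pairs
  if (nrow(pairs) > 0) {
    pairs$accuracy <- vapply(seq_len(nrow(pairs)), function(i) {
      as.numeric(contour_accuracy(auto_labels == pairs$auto_label[i],
                                  gt_labels == pairs$gt_label[i],
                                  pixel_size_xy))
    }, numeric(1))
  } else pairs$accuracy <- numeric(0)
  by_class <- NULL
  if (!is.null(gt_classes)) {
    pairs$gt_class <- gt_classes$gt_class[match(pairs$gt_label, gt_classes$label)]
    matched <- gt_classes$label %in% pairs$gt_label
    by_class <- dplyr::summarise(
      dplyr::group_by(
        dplyr::mutate(gt_classes, matched = matched,
                      accuracy = pairs$accuracy[match(gt_classes$label, pairs$gt_label)]),
        .data$gt_class),
      n = dplyr::n(), n_matched = sum(.data$matched),
      mean_accuracy = mean(.data$accuracy, na.rm = TRUE), .groups = "drop")
  }
  structure(list(match = mr, pairs = pairs,
                 mean_accuracy = if (nrow(pairs)) mean(pairs$accuracy) else NA_real_,
                 by_class = by_class),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  print(x$match)
  cat(sprintf("  mean contour accuracy over %d matched pair(s): %.3f\n",
              nrow(x$pairs), x$mean_accuracy))
  invisible(x)
}

#' Write a validation report to disk
#'
#' @param report A [validate_segmentation()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (`json`, `csv`).
#' @export
write_validation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "validation.json")
  csv_path <- file.path(dir, "validation_pairs.csv")
  m <- report$match
  jsonlite::write_json(list(
    tp = m$tp, fp = m$fp, fn = m$fn,
    sensitivity = m$sensitivity, wilson_low = m$wilson_low,
    wilson_high = m$wilson_high, merged_events = m$merged_events,
    mean_accuracy = report$mean_accuracy,
    by_class = report$by_class), json_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$pairs, csv_path, row.names = FALSE)
  invisible(list(json = json_path, csv = csv_path))
}
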