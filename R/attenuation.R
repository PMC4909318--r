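#' Percentage of signal retained after attenuation
#'
#' `P_att(z) = 100 * I(z) / I_max` along an axial profile; the profile
#' maximum (near the spheroid top, where the light path through tissue is
#' shortest) is taken as the attenuation-free reference, so `P_att`
#' attains 100 there.
#'
#' @param profile An [axial_profile()].
#' @return Numeric vector of percentages, one per profile sample.
#' @export
attenuation_percentage <- function(profile) {
  stopifnot(inherits(profile, "axial_profile"))
  if (profile$i_max <= 0) stop("profile maximum must be positive")
  100 * profile$intensity / profile$i_max
}

#' Analyzable depth of a spheroid
#'
#' Depth below the spheroid top that still retains at least `p_min`
#' percent of the unattenuated signal. The smoothed profile is scanned
#' strictly beyond its maximum for the first crossing of
#' `P_att(z) <= p_min` (linear sub-slice interpolation); the rising flank
#' near the top can never trigger it. The returned depth is measured from
#' `z_top`, the first z-coordinate of the spheroid. Profiles that never
#' drop below `p_min` extend to the last sample and are flagged uncapped.
#'
#' A crossing can also be caused by the tissue simply ending (the signal
#' falls to background below the spheroid, where the absorption is zero);
#' when the spheroid's vertical extent is known, pass its bottom
#' coordinate as `z_limit` so only crossings inside tissue count as
#' attenuation -- beyond it the spheroid is fully analyzable.
#'
#' @param profile An [axial_profile()] with `z_top` set (or pass `z_top`).
#' @param p_min Minimal retained percentage, in (0, 100). Default 50.
#' @param z_top Override for the profile's top coordinate (um).
#' @param z_limit Optional lowest z (um) where a crossing still counts
#'   (typically `z_c + c`, the spheroid bottom); crossings beyond it are
#'   tissue-boundary effects and the depth is capped there, flagged
#'   uncapped.
#' @param z_margin Resolution margin (um) for the boundary test: a
#'   crossing within `z_margin` of `z_limit` cannot be distinguished from
#'   the blurred bottom edge and is treated as boundary-capped. Default
#'   0; the pipeline passes one z-step.
#' @return List: `depth` (um, `z_analyzable - z_top`), `z_analyzable`
#'   (um), `z_ref` (um, the smoothed-profile maximum the crossing search
#'   starts from), `uncapped` (logical), `p_min`.
#' @export
analyzable_depth <- function(profile, p_min = 50, z_top = NULL,
                             z_limit = NULL, z_margin = 0) {
  stopifnot(inherits(profile, "axial_profile"))
  if (p_min <= 0 || p_min >= 100) stop("`p_min` must lie strictly between 0 and 100")
  if (is.null(z_top)) z_top <- profile$z_top
  if (is.na(z_top)) stop("z_top is unknown; extrapolate the ellipsoid first or pass `z_top`")
  s <- smooth_profile(profile$intensity)
  if (max(s) <= 0) stop("profile maximum must be positive")
  p <- 100 * s / max(s)
  i_max <- which.max(s)
  n <- length(p)
  z_cross <- NA_real_
  if (i_max < n) {
    for (i in (i_max + 1):n) {
      if (p[i] <= p_min) {
        p0 <- p[i - 1]; p1 <- p[i]
        frac <- if (p0 > p1) (p0 - p_min) / (p0 - p1) else 1
        z_cross <- profile$z_um[i - 1] + frac * (profile$z_um[i] - profile$z_um[i - 1])
        break
      }
    }
  }
  uncapped <- is.na(z_cross)
  if (uncapped) z_cross <- profile$z_um[n]
  if (!is.null(z_limit) && z_cross > z_limit - z_margin) {
    z_cross <- z_limit
    uncapped <- TRUE
  }
  list(depth = z_cross - z_top, z_analyzable = z_cross,
       z_ref = profile$z_um[i_max], uncapped = uncapped, p_min = p_min)
}

#' Classify how much of a spheroid is analyzable
#'
#' Compares the analyzable depth with the spheroid's vertical diameter
#' `2c`: `"full"` when the whole spheroid is visible (`depth >= 2c`),
#' `"half"` when at least the center is reached (`c <= depth < 2c`, the
#' upper hemisphere can be analyzed and the counts extrapolated to the
#' lower half), `"not_analyzable"` otherwise. Equality cases join the
#' more permissive class.
#'
#' @param ellipsoid An `ellipsoid3d` (or a single numeric `c` semi-axis).
#' @param depth Analyzable depth in um (from [analyzable_depth()]).
#' @return List: `class` (one of `"full"`, `"half"`, `"not_analyzable"`)
#'   and `analyzable_depth`.
#' @examples
#' classify_visibility(30, 80)$class  # full
#' classify_visibility(30, 40)$class  # half
#' classify_visibility(30, 20)$class  # not_analyzable
#' @export
classify_visibility <- function(ellipsoid, depth) {
  cc <- if (inherits(ellipsoid, "ellipsoid3d")) ellipsoid$c else ellipsoid
  stopifnot(cc > 0, depth >= 0)
  eps <- 1e-9 * max(1, cc)  # equality joins the more permissive class
  cls <- if (depth >= 2 * cc - eps) "full" else if (depth >= cc - eps)
    "half" else "not_analyzable"
  list(class = cls, analyzable_depth = depth)
}

#' Visibility class levels
#' @return Character vector of the three attenuation classes.
#' @export
visibility_classes <- function() c("full", "half", "not_analyzable")
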