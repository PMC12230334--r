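#' Forward/backward difference image
#'
#' Pixelwise backward-minus-forward heights of one measurement. For compact
#' objects, non-zero values concentrate where the lateral position of the
#' object's edge differs between the two scan directions. Missing pixels in
#' either scan propagate as missing.
#'
#' @param pair a [ScanPair].
#' @return a [DifferenceImage] (positive = backward higher).
#' @export
differenceImage <- function(pair) {
  stopifnot(is(pair, "ScanPair"))
  new("DifferenceImage",
      delta = pair@backward@heights - pair@forward@heights,
      pitchX = pair@forward@pitchX, pitchY = pair@forward@pitchY)
}

#' Total edge volume (TEV)
#'
#' \eqn{TEV = \Delta x \, \Delta y \sum_i |z_i^{bwd} - z_i^{fwd}|} over all
#' non-missing pixels of the full preprocessed frame. TEV integrates the
#' forward/backward disagreement of one measurement; for compact objects it
#' is concentrated at edges and quantifies the morphodynamic response of
#' the specimen to the scan (the edge memory effect). Hysteresis-type
#' instrumental contributions are time-independent, so a time trend in TEV
#' reflects specimen activity.
#'
#' @param pair a [ScanPair].
#' @return TEV in nm^3 (non-negative; 0 iff the scans agree on all
#'   non-missing pixels).
#' @export
totalEdgeVolume <- function(pair) {
  stopifnot(is(pair, "ScanPair"))
  d <- pair@backward@heights - pair@forward@heights
  pair@forward@pitchX * pair@forward@pitchY * sum(abs(d), na.rm = TRUE)
}

#' Group objects by equivalent-sphere diameter
#'
#' The measured size distribution is bimodal; objects whose
#' equivalent-sphere diameter falls below the cutoff are labelled
#' submitochondrial particles, all others mitochondria (half-open
#' convention: the cutoff itself is a mitochondrion).
#'
#' @param dSphereEquiv numeric vector of equivalent-sphere diameters, nm.
#' @param cutoffNm group cutoff, default 1000 nm (between the printed
#'   modes below 1.0 um and above 1.5 um).
#' @return character vector, `"submito_particle"` or `"mitochondrion"`.
#' @export
splitByEquivalentDiameter <- function(dSphereEquiv, cutoffNm = 1000) {
  ifelse(dSphereEquiv < cutoffNm, "submito_particle", "mitochondrion")
}

#' Build the TEV-vs-time table for a set of measurements
#'
#' @param records list of [MeasurementRecord].
#' @param reports optional data.frame of [shapeReport()] rows (one per
#'   record, same order) used to derive the diameter group; without it all
#'   records are labelled `"mitochondrion"`.
#' @param cutoffNm diameter cutoff passed to [splitByEquivalentDiameter()].
#' @return data.frame with columns `id`, `t_prep_h`, `tev_nm3`, `group`,
#'   `complete`.
#' @export
tevPoints <- function(records, reports = NULL, cutoffNm = 1000) {
  records <- Filter(Negate(is.null), records)
  tev <- vapply(records, function(r) totalEdgeVolume(r@pair), numeric(1))
  grp <- if (!is.null(reports))
    splitByEquivalentDiameter(reports$d_sphere_equiv_nm, cutoffNm)
  else rep("mitochondrion", length(records))
  data.frame(
    id = vapply(records, function(r) r@id, character(1)),
    t_prep_h = vapply(records, function(r) r@tPrep, numeric(1)),
    tev_nm3 = tev, group = grp,
    complete = vapply(records, function(r) r@complete, logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Linear TEV-vs-time trend with zero crossing
#'
#' Ordinary least-squares fit of TEV against the time since preparation.
#' Partial captures (which nominally underestimate TEV) and the
#' submitochondrial-particle group (whose TEV is instrumental, not
#' morphodynamic) are excluded by default. When the fitted slope is
#' negative, the zero-crossing time `tZero = -intercept/slope` estimates
#' when morphodynamic activity ceases.
#'
#' @param points data.frame as returned by [tevPoints()] (columns
#'   `tev_nm3`, `t_prep_h`, and optionally `group`, `complete`).
#' @param excludePartial drop rows with `complete == FALSE`.
#' @param excludeSubmito drop rows with `group == "submito_particle"`.
#' @return a [TrendFit].
#' @examples
#' pts <- data.frame(t_prep_h = c(1, 5, 9),
#'                   tev_nm3 = 1e9 * (1 - c(1, 5, 9) / 18.8))
#' tevTrend(pts)
#' @export
tevTrend <- function(points, excludePartial = TRUE, excludeSubmito = TRUE) {
  p <- points
  if (excludePartial && "complete" %in% names(p)) p <- p[p$complete, ]
  if (excludeSubmito && "group" %in% names(p))
    p <- p[p$group != "submito_particle", ]
  if (nrow(p) < 3L || length(unique(p$t_prep_h)) < 3L)
    stop("trend fit needs at least 3 points with distinct t_prep")
  fit <- stats::lm(tev_nm3 ~ t_prep_h, data = p)
  co <- stats::coef(fit)
  slope <- unname(co["t_prep_h"]); intercept <- unname(co["(Intercept)"])
  tZero <- if (is.finite(slope) && slope < 0) -intercept / slope
           else NA_real_
  sm <- suppressWarnings(summary(fit))   # exact fits trip summary.lm
  # one-sided test against a decaying trend (slope < 0)
  slopeP <- stats::pt(sm$coefficients["t_prep_h", "t value"],
                      df = nrow(p) - 2L)
  new("TrendFit", slope = slope, intercept = intercept, tZero = tZero,
      rSquared = sm$r.squared, slopePValue = slopeP,
      nPoints = nrow(p))
}

#' One-sided test for a decrease of MCI* between first and last scans
#'
#' One-sample t-test on the paired differences (last - first) against zero
#' with alternative "less", at the 90% confidence level by default: a
#' significant result indicates that repeatedly measured objects become
#' more spherical over time.
#'
#' @param first,last numeric vectors of MCI* values of the first and last
#'   measurement of each repeatedly measured object (same length, n >= 2).
#' @param alpha significance level (default 0.10).
#' @return list with `statistic`, `df`, `p.value` (one-sided), `reject`.
#' @export
mciDecreaseTest <- function(first, last, alpha = 0.10) {
  if (length(first) != length(last))
    stop("first and last must have the same length")
  if (length(first) < 2L) stop("need at least 2 pairs")
  d <- last - first
  if (stats::sd(d) == 0 && all(d == 0)) {
    return(list(statistic = 0, df = length(d) - 1L, p.value = 0.5,
                reject = FALSE))
  }
  ht <- stats::t.test(d, mu = 0, alternative = "less")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, reject = ht$p.value < alpha)
}
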