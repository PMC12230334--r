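#' Scanline and background corrections for SICM height maps
#'
#' The standard chain applied to hopping-mode topographies before any
#' metric is computed:
#'
#' 1. `alignRowsMedian()` subtracts each scanline's median, removing
#'    line-to-line feedback offsets. When the object dominates its rows
#'    (so row medians are not substrate), `alignRowsMedianDiff()` instead
#'    removes the cumulative medians of consecutive row differences, which
#'    is insensitive to within-row structure shared by neighbouring rows.
#' 2. `subtractMeanPlane()` removes the least-squares background plane
#'    (sample tilt).
#' 3. `zeroFloor()` shifts heights so the minimum is the substrate zero.
#'
#' Missing pixels are excluded from medians and the plane fit and propagate
#' unchanged. All operations preserve grid dimensions and pitches.
#'
#' @param t a [Topography].
#' @return the corrected [Topography].
#' @examples
#' t <- Topography(matrix(rnorm(64), 8), pitchX = 10)
#' zeroFloor(subtractMeanPlane(alignRowsMedian(t)))
#' @export
alignRowsMedian <- function(t) {
  stopifnot(is(t, "Topography"))
  h <- t@heights
  med <- apply(h, 1L, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0   # all-missing row: leave untouched
  t@heights <- h - med
  t
}

#' @rdname alignRowsMedian
#' @export
alignRowsMedianDiff <- function(t) {
  stopifnot(is(t, "Topography"))
  h <- t@heights
  if (nrow(h) < 2L)
    stop("alignRowsMedianDiff needs at least 2 rows")
  d <- apply(h[-1L, , drop = FALSE] - h[-nrow(h), , drop = FALSE],
             1L, stats::median, na.rm = TRUE)
  d[is.na(d)] <- 0
  off <- c(0, cumsum(d))
  t@heights <- h - off
  # the global offset is undefined by the row differences; anchor at zero
  zeroFloor(t)
}

#' @rdname alignRowsMedian
#' @export
subtractMeanPlane <- function(t) {
  stopifnot(is(t, "Topography"))
  h <- t@heights
  x <- pixelCenters(ncol(h), t@pitchX)
  y <- pixelCenters(nrow(h), t@pitchY)
  X <- rep(x, each = nrow(h))
  Y <- rep(y, times = ncol(h))
  z <- as.vector(h)
  ok <- !is.na(z)
  if (sum(ok) < 3L)
    stop("mean-plane fit needs at least 3 non-missing pixels")
  A <- cbind(1, X[ok], Y[ok])
  if (qr(A)$rank < 3L)
    stop("mean-plane fit is degenerate (collinear pixels)")
  beta <- qr.coef(qr(A), z[ok])
  t@heights <- h - matrix(beta[1] + beta[2] * X + beta[3] * Y,
                          nrow(h), ncol(h))
  t
}

#' @rdname alignRowsMedian
#' @export
zeroFloor <- function(t) {
  stopifnot(is(t, "Topography"))
  t@heights <- t@heights - min(t@heights, na.rm = TRUE)
  t
}

#' Apply the full preprocessing chain
#'
#' @param t a [Topography].
#' @param steps character vector of step names executed in order; any of
#'   `"align_rows_median"`, `"align_rows_median_diff"`,
#'   `"subtract_mean_plane"`, `"zero_floor"`.
#' @return the corrected [Topography].
#' @export
preprocessTopography <- function(t,
    steps = c("align_rows_median", "subtract_mean_plane", "zero_floor")) {
  fns <- list(align_rows_median = alignRowsMedian,
              align_rows_median_diff = alignRowsMedianDiff,
              subtract_mean_plane = subtractMeanPlane,
              zero_floor = zeroFloor)
  bad <- setdiff(steps, names(fns))
  if (length(bad)) stop("unknown preprocessing step: ",
                        paste(bad, collapse = ", "))
  for (s in steps) t <- fns[[s]](t)
  t
}

#' Segment the dominant object of a zero-floored topography
#'
#' Thresholds at a fraction of the maximum height, keeps the largest
#' connected component and fills its holes. This replaces manual outlining:
#' substrate roughness (a few nm) is far below object heights (hundreds of
#' nm), so the result is insensitive to the exact threshold.
#'
#' @param t a zero-floored [Topography].
#' @param relThreshold threshold as a fraction of the maximum height
#'   (0 < relThreshold < 1).
#' @param minPixels minimum component size in pixels.
#' @param connectivity 4 or 8 (default 8).
#' @return an [ObjectMask].
#' @examples
#' h <- matrix(0, 32, 32); h[10:20, 10:20] <- 1000
#' segmentObject(Topography(h, pitchX = 10))
#' @export
segmentObject <- function(t, relThreshold = 0.10, minPixels = 16L,
                          connectivity = 8L) {
  stopifnot(is(t, "Topography"))
  if (relThreshold <= 0 || relThreshold >= 1)
    stop("relThreshold must be strictly between 0 and 1")
  h <- t@heights
  zmax <- max(h, na.rm = TRUE)
  if (!is.finite(zmax) || zmax <= 0)
    stop("segmentation error: no object above the substrate")
  m <- !is.na(h) & h >= relThreshold * zmax
  lab <- .labelComponents(m, as.integer(connectivity))
  if (max(lab) == 0L)
    stop("segmentation error: no connected component found")
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  if (sizes[best] < minPixels)
    stop(sprintf(
      "segmentation error: largest component has %d px (< %d required)",
      sizes[best], as.integer(minPixels)))
  keep <- lab == best
  filled <- EBImage::fillHull(matrix(as.numeric(keep), nrow(keep))) > 0
  ObjectMask(matrix(as.logical(filled), nrow(keep)),
             connectivity = connectivity)
}
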