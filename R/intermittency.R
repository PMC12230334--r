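#' Extract a line profile along the fast scan axis
#'
#' @param t a [Topography].
#' @param row slow-axis row index (1-based).
#' @return list with `row`, `x` (pixel-center positions, nm), `z` (heights,
#'   nm) and `direction`.
#' @export
lineProfile <- function(t, row) {
  stopifnot(is(t, "Topography"))
  if (row < 1L || row > nrow(t@heights)) stop("row out of range")
  list(row = as.integer(row),
       x = pixelCenters(ncol(t@heights), t@pitchX),
       z = t@heights[row, ],
       direction = t@direction)
}

#' Detect height-intermittency dropout events in a line profile
#'
#' At steep object edges the measured height can drop abruptly to nearly
#' substrate level and recover — the object transiently escapes the probe
#' ("tilting" of weakly immobilized, cap-shaped specimens). An event is a
#' maximal run of columns inside the search window whose height falls below
#' `fLow * zMax`, flanked on both sides (within the window) by columns at
#' or above `fHigh * zMax`. Both thresholds are relative, so detection is
#' invariant under uniform height rescaling.
#'
#' @param z numeric vector of profile heights (nm), or a profile list from
#'   [lineProfile()].
#' @param objectCols integer vector (or range) of columns to search.
#' @param zMax reference maximum height of the object, nm.
#' @param fLow fraction of `zMax` below which a column counts as dropped.
#' @param fHigh fraction of `zMax` a flanking column must reach.
#' @return data.frame with zero or more rows: `start_col`, `end_col`,
#'   `min_z_nm`, `flank_z_nm` (lower of the two flanks), `depth_fraction`
#'   (`(flank - min)/zMax`), ordered left to right.
#' @examples
#' detectDropouts(c(0, 800, 900, 50, 850, 0), objectCols = 2:5, zMax = 900)
#' @export
detectDropouts <- function(z, objectCols, zMax, fLow = 0.2, fHigh = 0.5) {
  if (is.list(z)) z <- z$z
  if (!(fLow > 0 && fLow < fHigh && fHigh < 1))
    stop("need 0 < fLow < fHigh < 1")
  objectCols <- sort(unique(as.integer(objectCols)))
  if (!length(objectCols)) stop("objectCols must be non-empty")
  lo <- objectCols[1]; hi <- objectCols[length(objectCols)]
  zw <- z[lo:hi]
  low <- !is.na(zw) & zw < fLow * zMax
  high <- !is.na(zw) & zw >= fHigh * zMax
  runs <- trueRuns(low)
  out <- list()
  if (nrow(runs)) for (k in seq_len(nrow(runs))) {
    s <- runs[k, 1]; e <- runs[k, 2]
    leftFlank  <- if (s > 1) { w <- which(high[seq_len(s - 1L)])
                               if (length(w)) max(w) else NA_integer_
                             } else NA_integer_
    rightFlank <- if (e < length(zw)) { w <- which(high); w <- w[w > e]
                                        if (length(w)) min(w) else NA_integer_
                                      } else NA_integer_
    if (is.na(leftFlank) || is.na(rightFlank)) next
    flankZ <- min(zw[leftFlank], zw[rightFlank])
    minZ <- min(zw[s:e])
    out[[length(out) + 1L]] <- data.frame(
      start_col = lo + s - 1L, end_col = lo + e - 1L,
      min_z_nm = minZ, flank_z_nm = flankZ,
      depth_fraction = (flankZ - minZ) / zMax)
  }
  if (!length(out))
    return(data.frame(start_col = integer(0), end_col = integer(0),
                      min_z_nm = numeric(0), flank_z_nm = numeric(0),
                      depth_fraction = numeric(0)))
  do.call(rbind, out)
}

#' Summarize height intermittency over a scan pair
#'
#' Runs the dropout detector over every mask-intersecting row of both scan
#' directions. The per-row search window is the mask's column span extended
#' by `marginNm` on each side, because dropout events also occur several
#' hundred nanometers away from the object's edge. Events are counted
#' independently per direction.
#'
#' @param pair a [ScanPair].
#' @param mask the [ObjectMask] of the object.
#' @param marginNm window extension beyond the mask span, nm (default 500).
#' @param fLow,fHigh relative thresholds, see [detectDropouts()].
#' @return list with `events` (data.frame: `direction`, `row`, `start_col`,
#'   `end_col`, `min_z_nm`, `depth_fraction`), `counts` (named vector per
#'   direction), `affectedFraction` (flagged pixels / mask pixels) and
#'   `alternations` (total high-low-high transitions over all rows and
#'   directions).
#' @export
intermittencySummary <- function(pair, mask, marginNm = 500,
                                 fLow = 0.2, fHigh = 0.5) {
  stopifnot(is(pair, "ScanPair"), is(mask, "ObjectMask"))
  m <- mask@mask
  if (!identical(dim(m), dim(pair@forward@heights)))
    stop("mask and pair dimensions differ")
  marginPx <- ceiling(marginNm / pair@forward@pitchX)
  rows <- which(rowSums(m) > 0)
  evs <- list()
  for (dir in c("forward", "backward")) {
    t <- slot(pair, dir)
    zMax <- max(t@heights[m], na.rm = TRUE)
    for (r in rows) {
      span <- range(which(m[r, ]))
      cols <- max(1L, span[1] - marginPx):min(ncol(m), span[2] + marginPx)
      ev <- detectDropouts(t@heights[r, ], cols, zMax, fLow, fHigh)
      if (nrow(ev))
        evs[[length(evs) + 1L]] <-
          cbind(direction = dir, row = r, ev, row.names = NULL)
    }
  }
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(direction = character(0), row = integer(0),
               start_col = integer(0), end_col = integer(0),
               min_z_nm = numeric(0), flank_z_nm = numeric(0),
               depth_fraction = numeric(0))
  counts <- c(forward = sum(events$direction == "forward"),
              backward = sum(events$direction == "backward"))
  flagged <- if (nrow(events))
    sum(events$end_col - events$start_col + 1L) else 0L
  list(events = events, counts = counts,
       affectedFraction = flagged / (2 * sum(m)),
       alternations = nrow(events))
}
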