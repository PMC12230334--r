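#' @import methods
NULL

.SPECIMENS  <- c("active_mito", "fixed_mito", "microsphere", "synthetic")
.ISOLATIONS <- c("cavitation", "mechanochemical", "none")
.DIRECTIONS <- c("forward", "backward")
.SHAPES     <- c("spherical_cap", "ellipsoidal_cap", "irregular")

#' Topography: a single-direction SICM height map
#'
#' A `Topography` holds the apparent heights (nm) recorded during one scan
#' direction of a hopping-mode SICM measurement, on a regular pixel grid.
#' Rows are the slow scan axis (y), columns the fast scan axis (x); heights
#' are samples at pixel centers. Missing pixels are `NA`.
#'
#' @slot heights numeric matrix of apparent heights in nm.
#' @slot pitchX,pitchY pixel edge lengths \eqn{\Delta x}, \eqn{\Delta y} in nm.
#' @slot direction `"forward"` or `"backward"` (fast-axis scan direction).
#'
#' @examples
#' topo <- Topography(matrix(0, 4, 4), pitchX = 10)
#' pitchX(topo)
#' @export
setClass("Topography",
  representation(heights = "matrix", pitchX = "numeric",
                 pitchY = "numeric", direction = "character"),
  prototype(pitchX = 1, pitchY = 1, direction = "forward"))

setValidity("Topography", function(object) {
  h <- object@heights
  if (!is.numeric(h) || length(h) == 0L)
    return("heights must be a non-empty numeric matrix")
  if (any(!is.finite(h) & !is.na(h)))
    return("all non-missing heights must be finite")
  for (s in c("pitchX", "pitchY")) {
    p <- slot(object, s)
    if (length(p) != 1L || !is.finite(p) || p <= 0)
      return(sprintf("%s must be a single positive finite number", s))
  }
  if (length(object@direction) != 1L ||
      !object@direction %in% .DIRECTIONS)
    return("direction must be 'forward' or 'backward'")
  TRUE
})

#' @param heights numeric matrix of heights in nm.
#' @param pitchX,pitchY pixel pitch in nm (`pitchY` defaults to `pitchX`).
#' @param direction scan direction, `"forward"` or `"backward"`.
#' @rdname Topography-class
#' @export
Topography <- function(heights, pitchX, pitchY = pitchX,
                       direction = "forward") {
  new("Topography", heights = as.matrix(heights), pitchX = pitchX,
      pitchY = pitchY, direction = direction)
}

#' ScanPair: matched forward and backward scans of one measurement
#'
#' @slot forward,backward [Topography] objects with identical grid
#'   dimensions and pitches, and directions `"forward"` / `"backward"`.
#' @export
setClass("ScanPair",
  representation(forward = "Topography", backward = "Topography"))

setValidity("ScanPair", function(object) {
  f <- object@forward; b <- object@backward
  if (!identical(dim(f@heights), dim(b@heights)))
    return("forward and backward grids must have identical dimensions")
  if (f@pitchX != b@pitchX || f@pitchY != b@pitchY)
    return("forward and backward pitches must be identical")
  if (f@direction != "forward" || b@direction != "backward")
    return("scan directions must be 'forward' and 'backward' respectively")
  TRUE
})

#' @param forward,backward [Topography] objects.
#' @rdname ScanPair-class
#' @export
ScanPair <- function(forward, backward) {
  new("ScanPair", forward = forward, backward = backward)
}

#' MeasurementRecord: a scan pair with its experimental metadata
#'
#' @slot id measurement label.
#' @slot pair the [ScanPair].
#' @slot tPrep hours elapsed since sample preparation (thawing), \eqn{t_P \ge 0}.
#' @slot specimen one of `"active_mito"`, `"fixed_mito"`, `"microsphere"`,
#'   `"synthetic"`.
#' @slot isolation one of `"cavitation"`, `"mechanochemical"`, `"none"`.
#' @slot complete `FALSE` when the scan captured more than 90% but less than
#'   100% of the object (drift/self-motion); such records nominally
#'   underestimate edge statistics.
#' @export
setClass("MeasurementRecord",
  representation(id = "character", pair = "ScanPair", tPrep = "numeric",
                 specimen = "character", isolation = "character",
                 complete = "logical"),
  prototype(specimen = "synthetic", isolation = "none", complete = TRUE))

setValidity("MeasurementRecord", function(object) {
  if (length(object@tPrep) != 1L || !is.finite(object@tPrep) ||
      object@tPrep < 0)
    return("tPrep must be a single finite non-negative number (hours)")
  if (!object@specimen %in% .SPECIMENS)
    return(paste("specimen must be one of:",
                 paste(.SPECIMENS, collapse = ", ")))
  if (!object@isolation %in% .ISOLATIONS)
    return(paste("isolation must be one of:",
                 paste(.ISOLATIONS, collapse = ", ")))
  if (length(object@complete) != 1L || is.na(object@complete))
    return("complete must be TRUE or FALSE")
  TRUE
})

#' @param id measurement label.
#' @param pair a [ScanPair].
#' @param tPrep hours since preparation.
#' @param specimen,isolation,complete see slots.
#' @rdname MeasurementRecord-class
#' @export
MeasurementRecord <- function(id, pair, tPrep, specimen = "synthetic",
                              isolation = "none", complete = TRUE) {
  new("MeasurementRecord", id = as.character(id), pair = pair,
      tPrep = tPrep, specimen = specimen, isolation = isolation,
      complete = complete)
}

#' ObjectMask: a segmented object footprint
#'
#' A logical grid congruent with a [Topography], containing a single
#' connected component under the recorded connectivity.
#'
#' @slot mask logical matrix.
#' @slot connectivity 4 or 8 (neighbourhood used for connectedness).
#' @export
setClass("ObjectMask",
  representation(mask = "matrix", connectivity = "integer"),
  prototype(connectivity = 8L))

setValidity("ObjectMask", function(object) {
  m <- object@mask
  if (!is.logical(m) || length(m) == 0L)
    return("mask must be a non-empty logical matrix")
  if (any(is.na(m))) return("mask must not contain NA")
  if (!any(m)) return("mask must contain at least one TRUE pixel")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  lab <- .labelComponents(m, object@connectivity)
  if (max(lab) > 1L)
    return("mask must be a single connected component")
  TRUE
})

#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @rdname ObjectMask-class
#' @export
ObjectMask <- function(mask, connectivity = 8L) {
  new("ObjectMask", mask = mask, connectivity = as.integer(connectivity))
}

#' DifferenceImage: pixelwise backward-minus-forward heights
#'
#' Positive values mean the backward scan recorded a greater apparent
#' height than the forward scan at that pixel.
#'
#' @slot delta numeric matrix of height differences (nm).
#' @slot pitchX,pitchY pixel pitch in nm, inherited from the pair.
#' @export
setClass("DifferenceImage",
  representation(delta = "matrix", pitchX = "numeric", pitchY = "numeric"))

#' TrendFit: linear TEV-vs-time trend
#'
#' Ordinary least-squares fit TEV = intercept + slope * t_P with the
#' extrapolated zero-crossing time.
#'
#' @slot slope nm^3 per hour.
#' @slot intercept nm^3.
#' @slot tZero hours at which the fitted line crosses zero
#'   (`-intercept/slope`); `NA` unless the slope is negative.
#' @slot rSquared coefficient of determination.
#' @slot slopePValue one-sided p-value of the regression t-test against
#'   the alternative slope < 0 (a decaying trend).
#' @slot nPoints number of points used in the fit.
#' @export
setClass("TrendFit",
  representation(slope = "numeric", intercept = "numeric", tZero = "numeric",
                 rSquared = "numeric", slopePValue = "numeric",
                 nPoints = "integer"))

#' SynthConfig: full parameterization of the synthetic scan-pair generator
#'
#' Defaults emulate the measured study conditions: cap-shaped objects a few
#' hundred nm to a few um across on a flat substrate, shallow undulations of
#' about 100 nm amplitude and lateral scale, a forward/backward edge
#' displacement whose magnitude decays linearly with time since preparation,
#' edge-localized stochastic height dropouts, and about 1 nm Gaussian
#' z-noise.
#'
#' @slot nrow,ncol grid dimensions in pixels.
#' @slot pitch pixel pitch, nm.
#' @slot shape `"spherical_cap"`, `"ellipsoidal_cap"` or `"irregular"`.
#' @slot capRadius sphere radius r of the cap, nm.
#' @slot capHeight cap height h (apparent height at the apex), nm; h <= 2r.
#' @slot ellipticity x semi-axis scale factor for the ellipsoidal variant.
#' @slot lobes number of lobes for the irregular variant (>= 2).
#' @slot lobeAmplitude lobe center displacement as a fraction of capRadius.
#' @slot undAmplitude undulation amplitude, nm, read as peak-to-peak
#'   (the band-limited field is scaled to RMS = undAmplitude/2).
#' @slot undLength undulation correlation length, nm.
#' @slot delta0 edge-memory displacement magnitude at t_P = 0, nm.
#' @slot tZero time at which the edge-memory displacement reaches zero, h.
#' @slot anisotropy relative amplitude (0..1) of the one-sided modulation of
#'   the edge displacement; 0 gives an isotropic edge shift.
#' @slot anisotropyPhase angle (rad) of the most-displaced side.
#' @slot dropoutProb probability q that an eligible steep-edge pixel starts
#'   a dropout run.
#' @slot slopeThreshold fast-axis slope magnitude (dimensionless, nm/nm)
#'   above which a pixel is dropout-eligible.
#' @slot maxRun maximum dropout run length, pixels.
#' @slot noiseSd Gaussian z-noise standard deviation, nm.
#' @slot tPrep time since preparation for the generated record, h.
#' @slot seed integer seed fixing all randomness of one record.
#' @export
setClass("SynthConfig",
  representation(nrow = "integer", ncol = "integer", pitch = "numeric",
    shape = "character", capRadius = "numeric", capHeight = "numeric",
    ellipticity = "numeric", lobes = "integer", lobeAmplitude = "numeric",
    undAmplitude = "numeric", undLength = "numeric",
    delta0 = "numeric", tZero = "numeric", anisotropy = "numeric",
    anisotropyPhase = "numeric", dropoutProb = "numeric",
    slopeThreshold = "numeric", maxRun = "integer", noiseSd = "numeric",
    tPrep = "numeric", seed = "integer"),
  prototype(nrow = 128L, ncol = 128L, pitch = 30, shape = "spherical_cap",
    capRadius = 1000, capHeight = 1000, ellipticity = 0.7, lobes = 3L,
    lobeAmplitude = 0.8, undAmplitude = 100, undLength = 100,
    delta0 = 100, tZero = 18.8, anisotropy = 0.5, anisotropyPhase = 0,
    dropoutProb = 0.1, slopeThreshold = 1, maxRun = 3L, noiseSd = 1,
    tPrep = 0, seed = 1L))

setValidity("SynthConfig", function(object) {
  pos <- c("pitch", "capRadius", "capHeight", "ellipticity", "undLength",
           "tZero")
  for (s in pos)
    if (!is.finite(slot(object, s)) || slot(object, s) <= 0)
      return(sprintf("%s must be positive", s))
  nn <- c("undAmplitude", "delta0", "noiseSd", "tPrep", "anisotropy")
  for (s in nn)
    if (!is.finite(slot(object, s)) || slot(object, s) < 0)
      return(sprintf("%s must be non-negative", s))
  if (object@nrow < 2L || object@ncol < 2L)
    return("grid must be at least 2x2")
  if (!object@shape %in% .SHAPES)
    return(paste("shape must be one of:", paste(.SHAPES, collapse = ", ")))
  if (object@capHeight > 2 * object@capRadius)
    return("capHeight must not exceed the cap diameter (h <= 2r)")
  if (object@dropoutProb < 0 || object@dropoutProb > 1)
    return("dropoutProb must be in [0, 1]")
  if (object@maxRun < 1L) return("maxRun must be >= 1")
  if (object@anisotropy > 1) return("anisotropy must be in [0, 1]")
  TRUE
})

#' @param ... slot values overriding the defaults (see slots).
#' @rdname SynthConfig-class
#' @export
synthConfig <- function(...) {
  args <- list(...)
  for (s in c("nrow", "ncol", "lobes", "maxRun", "seed"))
    if (!is.null(args[[s]])) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list(Class = "SynthConfig"), args))
}
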