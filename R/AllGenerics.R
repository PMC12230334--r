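#' Accessors for topography objects
#'
#' `heights()` returns the height matrix (nm), `pitchX()`/`pitchY()` the
#' pixel pitch (nm), `scanDirection()` the fast-axis direction,
#' `forwardScan()`/`backwardScan()` the two members of a [ScanPair], and
#' `maskMatrix()` the logical matrix of an [ObjectMask].
#'
#' @param x a [Topography], [ScanPair], [DifferenceImage] or [ObjectMask].
#' @return see details per accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("heights", function(x) standardGeneric("heights"))
#' @rdname accessors
#' @export
setGeneric("pitchX", function(x) standardGeneric("pitchX"))
#' @rdname accessors
#' @export
setGeneric("pitchY", function(x) standardGeneric("pitchY"))
#' @rdname accessors
#' @export
setGeneric("scanDirection", function(x) standardGeneric("scanDirection"))
#' @rdname accessors
#' @export
setGeneric("forwardScan", function(x) standardGeneric("forwardScan"))
#' @rdname accessors
#' @export
setGeneric("backwardScan", function(x) standardGeneric("backwardScan"))
#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setMethod("heights", "Topography", function(x) x@heights)
#' @rdname accessors
#' @export
setMethod("heights", "DifferenceImage", function(x) x@delta)
#' @rdname accessors
#' @export
setMethod("pitchX", "Topography", function(x) x@pitchX)
#' @rdname accessors
#' @export
setMethod("pitchY", "Topography", function(x) x@pitchY)
#' @rdname accessors
#' @export
setMethod("pitchX", "DifferenceImage", function(x) x@pitchX)
#' @rdname accessors
#' @export
setMethod("pitchY", "DifferenceImage", function(x) x@pitchY)
#' @rdname accessors
#' @export
setMethod("pitchX", "ScanPair", function(x) x@forward@pitchX)
#' @rdname accessors
#' @export
setMethod("pitchY", "ScanPair", function(x) x@forward@pitchY)
#' @rdname accessors
#' @export
setMethod("scanDirection", "Topography", function(x) x@direction)
#' @rdname accessors
#' @export
setMethod("forwardScan", "ScanPair", function(x) x@forward)
#' @rdname accessors
#' @export
setMethod("backwardScan", "ScanPair", function(x) x@backward)
#' @rdname accessors
#' @export
setMethod("maskMatrix", "ObjectMask", function(x) x@mask)

setMethod("show", "Topography", function(object) {
  d <- dim(object@heights)
  rng <- range(object@heights, na.rm = TRUE)
  cat(sprintf(
    "Topography (%s): %d x %d px, pitch %.3g x %.3g nm, z in [%.3g, %.3g] nm",
    object@direction, d[1], d[2], object@pitchY, object@pitchX,
    rng[1], rng[2]))
  nmiss <- sum(is.na(object@heights))
  if (nmiss > 0) cat(sprintf(", %d missing px", nmiss))
  cat("\n")
})

setMethod("show", "ScanPair", function(object) {
  d <- dim(object@forward@heights)
  cat(sprintf("ScanPair: %d x %d px, pitch %.3g x %.3g nm\n",
              d[1], d[2], object@forward@pitchY, object@forward@pitchX))
})

setMethod("show", "MeasurementRecord", function(object) {
  d <- dim(object@pair@forward@heights)
  cat(sprintf(
    "MeasurementRecord '%s': %s (%s isolation), t_P = %.2f h, %d x %d px%s\n",
    object@id, object@specimen, object@isolation, object@tPrep, d[1], d[2],
    if (object@complete) "" else " [partial capture]"))
})

setMethod("show", "ObjectMask", function(object) {
  cat(sprintf("ObjectMask: %d px, %d-connectivity, %d x %d grid\n",
              sum(object@mask), object@connectivity,
              nrow(object@mask), ncol(object@mask)))
})

setMethod("show", "TrendFit", function(object) {
  cat(sprintf(
    "TrendFit: TEV = %.4g %+.4g * t_P (nm^3, t_P in h), R^2 = %.3f, n = %d\n",
    object@intercept, object@slope, object@rSquared, object@nPoints))
  if (!is.na(object@tZero))
    cat(sprintf("  zero crossing at t_P = %.3g h\n", object@tZero))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %d x %d px @ %.3g nm, %s (r = %.3g, h = %.3g nm)\n",
    object@nrow, object@ncol, object@pitch, object@shape,
    object@capRadius, object@capHeight))
  cat(sprintf(
    "  undulation %.3g nm / %.3g nm, delta0 = %.3g nm, tZero = %.3g h, q = %.3g, sigma_z = %.3g nm, t_P = %.3g h, seed = %d\n",
    object@undAmplitude, object@undLength, object@delta0, object@tZero,
    object@dropoutProb, object@noiseSd, object@tPrep, object@seed))
})
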