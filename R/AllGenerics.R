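#' @include AllClasses.R
NULL

#' Accessors for lidwiper S4 objects
#'
#' Small accessor generics: `magnitude()` and `angleDegrees()` read a
#' [PolarVector-class]; `zoneRadius()`, `fitRMSE()` and `nSamples()` read a
#' [ZernikeCoefficients-class]; `coefMatrix()` extracts the terms x eyes
#' coefficient assay of a [CohortCoefficients-class]; `tiltLWA()` /
#' `comaLWA()` / `tiltCircSD()` / `comaCircSD()` read a
#' [LidWiperAxes-class]; `isDegenerate()` reports zero-vector or
#' degenerate-test flags.
#'
#' @param x The object to access.
#' @return The corresponding slot value (numeric, matrix or logical).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("magnitude", function(x) standardGeneric("magnitude"))

#' @rdname accessors
#' @export
setGeneric("angleDegrees", function(x) standardGeneric("angleDegrees"))

#' @rdname accessors
#' @export
setGeneric("zoneRadius", function(x) standardGeneric("zoneRadius"))

#' @rdname accessors
#' @export
setGeneric("fitRMSE", function(x) standardGeneric("fitRMSE"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))

#' @rdname accessors
#' @export
setGeneric("tiltLWA", function(x) standardGeneric("tiltLWA"))

#' @rdname accessors
#' @export
setGeneric("comaLWA", function(x) standardGeneric("comaLWA"))

#' @rdname accessors
#' @export
setGeneric("tiltCircSD", function(x) standardGeneric("tiltCircSD"))

#' @rdname accessors
#' @export
setGeneric("comaCircSD", function(x) standardGeneric("comaCircSD"))

#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname mirrorToRightFrame
#' @export
setGeneric("mirrorToRightFrame", function(x) standardGeneric("mirrorToRightFrame"))

#' @rdname cropZone
#' @export
setGeneric("cropZone", function(x, diameter = 5) standardGeneric("cropZone"))

#' @rdname fitMap
#' @export
setGeneric("fitMap", function(x, zoneRadius = 2.5, maxOrder = 5)
  standardGeneric("fitMap"))
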