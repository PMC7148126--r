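#' @rdname DecayFit-class
#' @param object a fitted object
#' @export
setGeneric("halfLife", function(object) standardGeneric("halfLife"))

#' @rdname DecayFit-class
#' @export
setGeneric("decaySlope", function(object) standardGeneric("decaySlope"))

#' @rdname BiphasicFit-class
#' @param object a [BiphasicFit-class]
#' @export
setGeneric("fastFraction", function(object) standardGeneric("fastFraction"))

#' @rdname BiphasicFit-class
#' @export
setGeneric("isBiphasic", function(object) standardGeneric("isBiphasic"))

#' @rdname BiphasicFit-class
#' @export
setGeneric("fastPhase", function(object) standardGeneric("fastPhase"))

#' @rdname BiphasicFit-class
#' @export
setGeneric("slowPhase", function(object) standardGeneric("slowPhase"))

#' @rdname SteadyState-class
#' @param object a [SteadyState-class]
#' @export
setGeneric("poolAbundances", function(object) standardGeneric("poolAbundances"))

#' @rdname ChaseCurve-class
#' @param object a [ChaseCurve-class]
#' @export
setGeneric("ctTable", function(object) standardGeneric("ctTable"))
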