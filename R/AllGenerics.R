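#' @include AllClasses.R
NULL

#' Accessors for StereoEnergy objects
#'
#' Small accessor generics in place of direct slot access.
#'
#' @param x an object of the documented classes.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("leftImage", function(x) standardGeneric("leftImage"))
#' @rdname accessors
#' @export
setGeneric("rightImage", function(x) standardGeneric("rightImage"))
#' @rdname accessors
#' @export
setGeneric("truthMap", function(x) standardGeneric("truthMap"))
#' @rdname accessors
#' @export
setGeneric("disparity", function(x) standardGeneric("disparity"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("responseMap", function(x) standardGeneric("responseMap"))
#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname accessors
#' @export
setGeneric("filterFamily", function(x) standardGeneric("filterFamily"))
#' @rdname accessors
#' @export
setGeneric("evenWeights", function(x) standardGeneric("evenWeights"))
#' @rdname accessors
#' @export
setGeneric("oddWeights", function(x) standardGeneric("oddWeights"))
#' @rdname accessors
#' @export
setGeneric("hypotheses", function(x) standardGeneric("hypotheses"))
#' @rdname accessors
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))
#' @rdname accessors
#' @export
setGeneric("channelSpecOf", function(x) standardGeneric("channelSpecOf"))

#' @rdname accessors
setMethod("leftImage", "StereoPair", function(x) x@left)
#' @rdname accessors
setMethod("rightImage", "StereoPair", function(x) x@right)
#' @rdname accessors
setMethod("truthMap", "GroundTruthStereogram", function(x) x@truth)
#' @rdname accessors
setMethod("disparity", "DisparityMap", function(x) x@disparity)
#' @rdname accessors
setMethod("disparity", "ChannelDisparityMap", function(x) x@disparity)
#' @rdname accessors
setMethod("validMask", "DisparityMap", function(x) x@validMask)
#' @rdname accessors
setMethod("responseMap", "ChannelDisparityMap", function(x) x@response)
#' @rdname accessors
setMethod("channels", "FilterBank", function(x) x@channels)
#' @rdname accessors
setMethod("filterFamily", "FilterBank", function(x) x@family)
#' @rdname accessors
setMethod("filterFamily", "ChannelSpec", function(x) x@family)
#' @rdname accessors
setMethod("filterFamily", "QuadratureFilter", function(x) x@spec@family)
#' @rdname accessors
setMethod("hypotheses", "DisparityHypothesisSet", function(x) x@values)
#' @rdname accessors
setMethod("hypotheses", "EnergyStack", function(x) x@hypotheses@values)
#' @rdname accessors
setMethod("energies", "EnergyStack", function(x) x@energies)
#' @rdname accessors
setMethod("channelSpecOf", "QuadratureFilter", function(x) x@spec)
#' @rdname accessors
setMethod("channelSpecOf", "EnergyStack", function(x) x@spec)
#' @rdname accessors
setMethod("channelSpecOf", "ChannelDisparityMap", function(x) x@spec)
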