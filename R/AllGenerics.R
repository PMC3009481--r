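#' @rdname MassSpecSet
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname MassSpecSet
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))

#' @rdname MassSpecSet
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname MassSpecSet
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @rdname NPCAModel-class
#' @export
setGeneric("metaSamples", function(object) standardGeneric("metaSamples"))

#' @rdname NPCAModel-class
#' @export
setGeneric("loadings", function(object) standardGeneric("loadings"))

#' @rdname NPCAModel-class
#' @export
setGeneric("varianceWeights", function(object) standardGeneric("varianceWeights"))
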