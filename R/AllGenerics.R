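#' @rdname AbundanceTable-class
#' @param x,object an object.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("taxonIDs", function(x) standardGeneric("taxonIDs"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))

#' Accessors for CooccurrenceNetwork
#'
#' @param x a [CooccurrenceNetwork-class].
#' @name network-accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname network-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname network-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
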