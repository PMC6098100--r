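#' @rdname EcoNetwork-accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname EcoNetwork-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname EcoNetwork-accessors
#' @export
setGeneric("isWeighted", function(x) standardGeneric("isWeighted"))

#' @rdname EcoNetwork-accessors
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))

#' @rdname EcoNetwork-accessors
#' @export
setGeneric("partition", function(x) standardGeneric("partition"))

#' @rdname EcoNetwork-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname EcoNetwork-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname AnnTopology-accessors
#' @export
setGeneric("layerSizes", function(x) standardGeneric("layerSizes"))

#' @rdname AnnTopology-accessors
#' @export
setGeneric("descriptors", function(x) standardGeneric("descriptors"))

#' @rdname AnnTopology-accessors
#' @export
setGeneric("printedDescriptors",
           function(x) standardGeneric("printedDescriptors"))

#' @rdname ConfusionStats-accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname ConfusionStats-accessors
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

#' @rdname ConfusionStats-accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname LinearNetNetModel-accessors
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))

#' @rdname LinearNetNetModel-accessors
#' @export
setGeneric("fittedStats", function(x) standardGeneric("fittedStats"))
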