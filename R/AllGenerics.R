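#' @rdname OtuTable-accessors
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @rdname OtuTable-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname OtuTable-accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname OtuTable-accessors
#' @export
setGeneric("isRelative", function(x) standardGeneric("isRelative"))

#' @rdname OtuTable-accessors
#' @export
setGeneric("nOtus", function(x) standardGeneric("nOtus"))

#' @rdname OtuTable-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname buildNetwork
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname buildNetwork
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname networkMetrics
#' @export
setGeneric("networkMetrics", function(x) standardGeneric("networkMetrics"))

#' @rdname hubScores
#' @export
setGeneric("hubScores", function(x, k = 20L) standardGeneric("hubScores"))
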