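#' Number of time points
#' @param x a [TimeSeriesSet-class]
#' @return integer(1)
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Node identifiers
#' @param x a [TimeSeriesSet-class] or [NodeTable-class]
#' @return character vector
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Sampling period (seconds)
#' @param x a [TimeSeriesSet-class]
#' @return numeric(1)
#' @export
setGeneric("samplingPeriod", function(x) standardGeneric("samplingPeriod"))

#' Subject identifier
#' @param x a [TimeSeriesSet-class]
#' @return character(1)
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Signal matrix (time points x nodes)
#' @param x a [TimeSeriesSet-class]
#' @return numeric matrix
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' Node metadata data.frame
#' @param x a [NodeTable-class]
#' @return data.frame
#' @export
setGeneric("nodeData", function(x) standardGeneric("nodeData"))

#' Node positions (mm)
#' @param x a [NodeTable-class]
#' @return numeric matrix n x 3 with rownames = node ids
#' @export
setGeneric("nodePositions", function(x) standardGeneric("nodePositions"))

#' Diagram / curve values
#' @param x a [CorrelationDiagram-class], [PValueDiagram-class] or
#'   [EfficiencyCurve-class]
#' @return numeric matrix or vector
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Window widths (seconds)
#' @param x a grid, diagram or efficiency curve
#' @return numeric vector
#' @export
setGeneric("widths", function(x) standardGeneric("widths"))

#' Window centers (seconds)
#' @param x a grid or diagram
#' @return numeric vector
#' @export
setGeneric("centers", function(x) standardGeneric("centers"))

#' Link records as a data.frame
#' @param x a [LinkTable-class]
#' @return data.frame
#' @export
setGeneric("linkData", function(x) standardGeneric("linkData"))
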