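## Accessors and show methods

#' @rdname nSamples
#' @export
setMethod("nSamples", "TimeSeriesSet", function(x) nrow(x@samples))

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "TimeSeriesSet", function(x) colnames(x@samples))

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "NodeTable", function(x) x@nodes$node_id)

#' @rdname samplingPeriod
#' @export
setMethod("samplingPeriod", "TimeSeriesSet", function(x) x@samplingPeriod)

#' @rdname subjectId
#' @export
setMethod("subjectId", "TimeSeriesSet", function(x) x@subjectId)

#' @rdname signalMatrix
#' @export
setMethod("signalMatrix", "TimeSeriesSet", function(x) x@samples)

#' @rdname nodeData
#' @export
setMethod("nodeData", "NodeTable", function(x) x@nodes)

#' @rdname nodePositions
#' @export
setMethod("nodePositions", "NodeTable", function(x) {
  p <- as.matrix(x@nodes[, c("x", "y", "z")])
  rownames(p) <- x@nodes$node_id
  p
})

#' @rdname values
#' @export
setMethod("values", "CorrelationDiagram", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "PValueDiagram", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "EfficiencyCurve", function(x) x@eta)

#' @rdname widths
#' @export
setMethod("widths", "WindowGrid", function(x) x@widths)

#' @rdname widths
#' @export
setMethod("widths", "CorrelationDiagram", function(x) x@widths)

#' @rdname widths
#' @export
setMethod("widths", "PValueDiagram", function(x) x@widths)

#' @rdname widths
#' @export
setMethod("widths", "EfficiencyCurve", function(x) x@widths)

#' @rdname centers
#' @export
setMethod("centers", "WindowGrid", function(x) x@centers)

#' @rdname centers
#' @export
setMethod("centers", "CorrelationDiagram", function(x) x@centers)

#' @rdname centers
#' @export
setMethod("centers", "PValueDiagram", function(x) x@centers)

#' @rdname linkData
#' @export
setMethod("linkData", "LinkTable", function(x) x@links)

#' Coerce a LinkTable to data.frame
#' @param x a [LinkTable-class]
#' @param row.names,optional,... passed on for compatibility
#' @return data.frame
#' @export
as.data.frame.LinkTable <- function(x, row.names = NULL, optional = FALSE, ...)
  x@links

setMethod("show", "TimeSeriesSet", function(object) {
  cat(sprintf("TimeSeriesSet '%s': %d samples x %d nodes, T = %g s (%.1f s)\n",
              object@subjectId, nrow(object@samples), ncol(object@samples),
              object@samplingPeriod,
              nrow(object@samples) * object@samplingPeriod))
})

setMethod("show", "NodeTable", function(object) {
  h <- table(object@nodes$hemisphere)
  cat(sprintf("NodeTable: %d nodes (%d left, %d right)\n",
              nrow(object@nodes),
              if ("left" %in% names(h)) h[["left"]] else 0L,
              if ("right" %in% names(h)) h[["right"]] else 0L))
})

setMethod("show", "WindowGrid", function(object) {
  cat(sprintf(
    "WindowGrid: w0 = %g s, M = %d (widths %g-%g s), %d centers from %g to %g s\n",
    object@w0, object@M, object@widths[1], object@widths[object@M],
    length(object@centers), object@centers[1],
    object@centers[length(object@centers)]))
})

setMethod("show", "CorrelationDiagram", function(object) {
  cat(sprintf("CorrelationDiagram: %d centers x %d widths\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "PValueDiagram", function(object) {
  cat(sprintf(
    "PValueDiagram: %d centers x %d widths, %d '%s' surrogates (min p = %.4g)\n",
    nrow(object@values), ncol(object@values), object@nSurrogates,
    object@surrogateMethod, 1 / (object@nSurrogates + 1)))
})

setMethod("show", "EfficiencyCurve", function(object) {
  cat(sprintf("EfficiencyCurve: %d widths (%g-%g s), alpha = %g, max eta = %.3f\n",
              length(object@widths), object@widths[1],
              object@widths[length(object@widths)], object@alpha,
              max(object@eta)))
})

setMethod("show", "LinkTable", function(object) {
  lk <- object@links
  cat(sprintf("LinkTable: %d pairs, %d observable links (R = %.3f)\n",
              nrow(lk), sum(is.finite(lk$W_s)),
              if (nrow(lk)) mean(is.finite(lk$W_s)) else NA_real_))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: slopes (%.2f, %.2f, %.2f) s, breaks (%.1f, %.1f) mm,\n  W(%g mm) = %g s, unlinked fraction %.2f, W band [%g, %g] s\n",
    object@slopes[1], object@slopes[2], object@slopes[3],
    object@breakpoints[1], object@breakpoints[2], object@breakpoints[1],
    object@intercept, object@unlinkedFraction, object@wRange[1],
    object@wRange[2]))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d nodes, %d subjects, %g s at %g Hz, band %g-%g Hz\n  grid w0 = %g s, M = %d, %d '%s' surrogates, alpha = %g, eta > %g\n",
    object@nNodes, object@nSubjects, object@duration,
    1 / object@samplingPeriod, object@noiseBand[1], object@noiseBand[2],
    object@w0, object@M, object@nSurrogates, object@surrogate,
    object@alpha, object@etaThreshold))
})

setMethod("show", "CalibrationCurve", function(object) {
  ok <- is.finite(object@WofRho)
  cat(sprintf(
    "CalibrationCurve: %d rho points in [%.3g, %.3g], W in [%.3g, %.3g] s (%d reps)\n",
    length(object@rhoGrid), min(object@rhoGrid), max(object@rhoGrid),
    if (any(ok)) min(object@WofRho[ok]) else NA,
    if (any(ok)) max(object@WofRho[ok]) else NA, object@nReps))
})

setMethod("show", "JointDistribution", function(object) {
  cat(sprintf("JointDistribution: %d x %d bins over %d links%s\n",
              nrow(object@f), ncol(object@f), sum(object@counts),
              if (object@binning@logD) " (log-d axis)" else ""))
})

setMethod("show", "ConditionalCurve", function(object) {
  tb <- object@table
  ok <- tb$n > 0
  cat(sprintf(
    "ConditionalCurve: %d distance bins (%d nonempty), Wbar in [%.3g, %.3g] s\n",
    nrow(tb), sum(ok), min(tb$wbar[ok]), max(tb$wbar[ok])))
})

setMethod("show", "PiecewiseFit", function(object) {
  cat("Three-regime piecewise-linear fit of Wbar vs ln d\n")
  for (i in 1:3)
    cat(sprintf("  m%d = %6.3f +/- %.3f s\n", i, object@slopes[i],
                object@slopeSE[i]))
  cat(sprintf("  d12 = %.2f +/- %.2f mm, d23 = %.2f +/- %.2f mm\n",
              object@breakpoints[1], object@breakpointSE[1],
              object@breakpoints[2], object@breakpointSE[2]))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("Power-law fit: W = W0 (d/%g)^gamma, gamma = %.3f +/- %.3f, W0 = %.3f +/- %.3f s\n",
              object@d0, object@gamma, object@gammaSE, object@W0, object@W0SE))
})

setMethod("show", "KS2DResult", function(object) {
  cat(sprintf("2-D KS test (%s): D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              object@method, object@D, object@p, object@n1, object@n2))
})
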