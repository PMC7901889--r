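#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib netobs, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## Time series container
## ---------------------------------------------------------------------------

#' Multichannel time-series set
#'
#' Holds the sampled signals of all nodes of one subject: a numeric matrix
#' with one row per time point and one column per node, together with the
#' sampling period (seconds) and a subject identifier.  Column names are the
#' node identifiers.
#'
#' @slot subjectId character(1), subject label.
#' @slot samplingPeriod numeric(1), sampling period in seconds (> 0).
#' @slot samples numeric matrix, time points x nodes, all values finite.
#'
#' @seealso [timeSeriesSet()], [readSeriesMatrix()]
#' @export
setClass("TimeSeriesSet",
  representation(subjectId = "character",
                 samplingPeriod = "numeric",
                 samples = "matrix"))

setValidity("TimeSeriesSet", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "'subjectId' must be a single string")
  if (length(object@samplingPeriod) != 1L || !is.finite(object@samplingPeriod) ||
      object@samplingPeriod <= 0)
    msg <- c(msg, "'samplingPeriod' must be a single positive number")
  if (!is.numeric(object@samples))
    msg <- c(msg, "'samples' must be a numeric matrix")
  else {
    if (nrow(object@samples) < 2L)
      msg <- c(msg, "'samples' must contain at least 2 time points")
    if (!all(is.finite(object@samples)))
      msg <- c(msg, "'samples' must be finite everywhere")
    ids <- colnames(object@samples)
    if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
      msg <- c(msg, "'samples' must have unique, non-empty column names (node ids)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TimeSeriesSet
#'
#' @param samples numeric matrix, one row per time point, one column per node.
#' @param samplingPeriod sampling period in seconds.
#' @param subjectId subject label.
#' @param nodeIds optional node identifiers; defaults to the column names of
#'   `samples` or `"n1" ... "nK"` when absent.
#' @return A [TimeSeriesSet-class] object.
#' @examples
#' ts <- timeSeriesSet(matrix(rnorm(20), ncol = 2), samplingPeriod = 0.004)
#' nSamples(ts)
#' @export
timeSeriesSet <- function(samples, samplingPeriod, subjectId = "subject",
                          nodeIds = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.null(nodeIds)) {
    stopifnot(length(nodeIds) == ncol(samples))
    colnames(samples) <- as.character(nodeIds)
  } else if (is.null(colnames(samples))) {
    colnames(samples) <- paste0("n", seq_len(ncol(samples)))
  }
  new("TimeSeriesSet", subjectId = as.character(subjectId),
      samplingPeriod = as.numeric(samplingPeriod), samples = samples)
}

## ---------------------------------------------------------------------------
## Node table
## ---------------------------------------------------------------------------

#' Node table: labels, hemispheres and 3-D positions
#'
#' One row per node with an identifier, an atlas-area label, the hemisphere
#' ("left" or "right") and a 3-D position in millimetres (MNI-style frame).
#'
#' @slot nodes data.frame with columns `node_id`, `label`, `hemisphere`,
#'   `x`, `y`, `z`.
#' @seealso [nodeTable()], [readNodeTable()], [placeNodes()]
#' @export
setClass("NodeTable", representation(nodes = "data.frame"))

setValidity("NodeTable", function(object) {
  nd <- object@nodes
  need <- c("node_id", "label", "hemisphere", "x", "y", "z")
  if (!all(need %in% names(nd)))
    return(paste("node table must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(nd$node_id))
    msg <- c(msg, "duplicate node_id values")
  if (!all(nd$hemisphere %in% c("left", "right")))
    msg <- c(msg, "hemisphere must be 'left' or 'right'")
  if (!all(is.finite(as.matrix(nd[, c("x", "y", "z")]))))
    msg <- c(msg, "node positions must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a NodeTable
#'
#' @param node_id node identifiers (unique).
#' @param label atlas-area labels.
#' @param hemisphere `"left"` or `"right"` per node (common abbreviations
#'   `l`, `r`, `L`, `R`, `lh`, `rh` are normalised).
#' @param x,y,z coordinates in mm.
#' @return A [NodeTable-class] object.
#' @export
nodeTable <- function(node_id, label, hemisphere, x, y, z) {
  hemisphere <- normalizeHemisphere(hemisphere)
  nd <- data.frame(node_id = as.character(node_id), label = as.character(label),
                   hemisphere = hemisphere, x = as.numeric(x), y = as.numeric(y),
                   z = as.numeric(z), stringsAsFactors = FALSE)
  new("NodeTable", nodes = nd)
}

normalizeHemisphere <- function(h) {
  h0 <- tolower(trimws(as.character(h)))
  map <- c(left = "left", l = "left", lh = "left",
           right = "right", r = "right", rh = "right")
  out <- unname(map[h0])
  if (anyNA(out))
    stop("unknown hemisphere token(s): ",
         paste(unique(h0[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

## ---------------------------------------------------------------------------
## Window grid
## ---------------------------------------------------------------------------

#' Multiscale moving-window grid
#'
#' Window widths are `m * w0`, `m = 1 ... M`.  All widths share the same
#' center points: the first is at `M*w0/2`, successive centers step by `w0`,
#' and the last one is at most `N*T - M*w0/2`, so every window of every width
#' fits inside the recording.  Windows are half-open sample-index intervals;
#' the window of width `m*w0` holds exactly `m*w0/T` samples.
#'
#' @slot w0 numeric(1), minimum window width (s).
#' @slot M integer(1), number of widths.
#' @slot samplingPeriod numeric(1), sampling period (s).
#' @slot nSamples integer(1), length of the series the grid was built for.
#' @slot widths numeric(M), window widths (s).
#' @slot centers numeric(K), window center times (s).
#' @slot starts integer matrix K x M of 0-based window start samples.
#' @slot lens integer(M), window lengths in samples.
#' @seealso [buildWindowGrid()]
#' @export
setClass("WindowGrid",
  representation(w0 = "numeric", M = "integer", samplingPeriod = "numeric",
                 nSamples = "integer", widths = "numeric", centers = "numeric",
                 starts = "matrix", lens = "integer"))

## ---------------------------------------------------------------------------
## Diagrams and efficiency
## ---------------------------------------------------------------------------

#' Windowed correlation diagram
#'
#' Sample Pearson coefficients `r(k, w)` on a [WindowGrid-class]: rows are
#' window centers, columns window widths.  Cells where either window is
#' constant are `NA` (the coefficient is undefined there).
#'
#' @slot values numeric matrix K x M in `[-1, 1]` (or `NA`).
#' @slot centers,widths grid coordinates (s).
#' @export
setClass("CorrelationDiagram",
  representation(values = "matrix", centers = "numeric", widths = "numeric"))

#' Surrogate-based p-value diagram
#'
#' For each grid cell, `p(k, w) = (g + 1) / (nSurrogates + 1)` where `g`
#' counts surrogate replicates whose `|r|` reaches the observed `|r|`; the
#' smallest attainable value is `1/(nSurrogates + 1)`.
#'
#' @slot values numeric matrix of p values (`NA` where `r` was undefined).
#' @slot centers,widths grid coordinates (s).
#' @slot nSurrogates integer(1), surrogate replicates used.
#' @slot surrogateMethod character(1), one of `"ft"`, `"aaft"`, `"iaaft"`.
#' @export
setClass("PValueDiagram",
  representation(values = "matrix", centers = "numeric", widths = "numeric",
                 nSurrogates = "integer", surrogateMethod = "character"))

#' Efficiency curve
#'
#' Fraction of windows of each width whose correlation is significant at the
#' `alpha` threshold; undefined cells count as non-significant.
#'
#' @slot eta numeric(M) in `[0, 1]`.
#' @slot widths numeric(M), window widths (s).
#' @slot alpha numeric(1), p-value threshold.
#' @export
setClass("EfficiencyCurve",
  representation(eta = "numeric", widths = "numeric", alpha = "numeric"))

setValidity("EfficiencyCurve", function(object) {
  if (length(object@eta) != length(object@widths))
    return("eta and widths must have equal length")
  if (any(object@eta < 0 | object@eta > 1, na.rm = TRUE))
    return("eta must lie in [0, 1]")
  TRUE
})

## ---------------------------------------------------------------------------
## Link table
## ---------------------------------------------------------------------------

#' Link table
#'
#' One row per unordered node pair and subject: node identifiers, hemisphere
#' pair (`LL`, `LR`, `RR`), Euclidean distance `d_mm` and time scale of
#' observability `W_s` (`NA` when no link was detected).
#'
#' @slot links data.frame with columns `subject_id`, `node_a`, `node_b`,
#'   `hemisphere_pair`, `d_mm`, `W_s`.
#' @seealso [assessLinks()], [writeLinkTable()], [readLinkTable()]
#' @export
setClass("LinkTable", representation(links = "data.frame"))

setValidity("LinkTable", function(object) {
  lk <- object@links
  need <- c("subject_id", "node_a", "node_b", "hemisphere_pair", "d_mm", "W_s")
  if (!all(need %in% names(lk)))
    return(paste("link table must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(lk)) {
    if (!all(lk$hemisphere_pair %in% c("LL", "LR", "RR")))
      msg <- c(msg, "hemisphere_pair must be LL, LR or RR")
    if (any(!is.finite(lk$d_mm)) || any(lk$d_mm <= 0))
      msg <- c(msg, "d_mm must be finite and positive")
    if (any(is.finite(lk$W_s) & lk$W_s <= 0))
      msg <- c(msg, "finite W_s must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LinkTable from a data.frame
#' @param links data.frame with columns `subject_id`, `node_a`, `node_b`,
#'   `hemisphere_pair`, `d_mm`, `W_s`.
#' @return A [LinkTable-class] object.
#' @export
linkTable <- function(links) {
  links$subject_id <- as.character(links$subject_id)
  links$node_a <- as.character(links$node_a)
  links$node_b <- as.character(links$node_b)
  links$hemisphere_pair <- as.character(links$hemisphere_pair)
  links$d_mm <- as.numeric(links$d_mm)
  links$W_s <- as.numeric(links$W_s)
  new("LinkTable", links = links)
}

## ---------------------------------------------------------------------------
## Synthetic-data classes
## ---------------------------------------------------------------------------

#' Ground truth for the synthetic generator
#'
#' Defines the piecewise-linear dependence of the target time scale `W` on
#' `ln d` (d in mm): three slopes (s per unit `ln d`), two breakpoints (mm),
#' and the intercept, parameterised as `W` at the first breakpoint.  Targets
#' are clipped to `wRange`.  A fraction of node pairs carries no shared
#' signal at all.
#'
#' @slot slopes numeric(3), s per unit ln(d/mm).
#' @slot breakpoints numeric(2), mm, increasing.
#' @slot intercept numeric(1), W at `d = breakpoints[1]` (s).
#' @slot unlinkedFraction numeric(1) in `[0, 1]`.
#' @slot wRange numeric(2), clip band for targets (s).
#' @seealso [groundTruth()], [targetW()]
#' @export
setClass("GroundTruth",
  representation(slopes = "numeric", breakpoints = "numeric",
                 intercept = "numeric", unlinkedFraction = "numeric",
                 wRange = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (length(object@slopes) != 3L) msg <- c(msg, "need exactly 3 slopes")
  if (length(object@breakpoints) != 2L || diff(object@breakpoints) <= 0 ||
      any(object@breakpoints <= 0))
    msg <- c(msg, "breakpoints must be two increasing positive values")
  if (object@unlinkedFraction < 0 || object@unlinkedFraction > 1)
    msg <- c(msg, "unlinkedFraction must lie in [0, 1]")
  if (length(object@wRange) != 2L || diff(object@wRange) <= 0 ||
      object@wRange[1] <= 0)
    msg <- c(msg, "wRange must be an increasing positive interval")
  if (length(msg)) msg else TRUE
})

#' Ground-truth constructor with study defaults
#'
#' Defaults reproduce the three-regime law reported for resting-state MEG
#' cohorts: slopes 7.0, 19.1 and 6.7 s per unit ln d, breakpoints 44 and
#' 68.3 mm.  The intercept (12.5 s at 44 mm) places all targets for
#' distances in 10-175 mm inside the probed band 0.2-30 s.
#'
#' @param slopes numeric(3), s per unit ln(d/mm).
#' @param breakpoints numeric(2), mm.
#' @param intercept W at the first breakpoint (s).
#' @param unlinkedFraction fraction of pairs with zero shared signal.
#' @param wRange clip band (s).
#' @return A [GroundTruth-class] object.
#' @export
groundTruth <- function(slopes = c(7.0, 19.1, 6.7), breakpoints = c(44, 68.3),
                        intercept = 12.5, unlinkedFraction = 0.6,
                        wRange = c(0.2, 30)) {
  new("GroundTruth", slopes = as.numeric(slopes),
      breakpoints = as.numeric(breakpoints), intercept = as.numeric(intercept),
      unlinkedFraction = as.numeric(unlinkedFraction),
      wRange = as.numeric(wRange))
}

#' Synthetic cohort configuration
#'
#' Geometry, signal and link-assessment settings for [generateCohort()] and
#' [calibrateRhoToW()].  Defaults mirror the study conditions: 72 nodes,
#' 250 Hz sampling, 180 s recordings, 0.5-45 Hz band-limited signals, window
#' grid w0 = 0.2 s with M = 150 widths.  The recording duration must be at
#' least 5 times the maximum probed width `M*w0`.
#'
#' @slot nNodes,nSubjects integers.
#' @slot samplingPeriod numeric(1), s.
#' @slot duration numeric(1), s.
#' @slot noiseBand numeric(2), band edges in Hz (a lower edge of 0 and an
#'   upper edge at or above Nyquist yield white noise).
#' @slot seed integer(1), master seed.
#' @slot groundTruth a [GroundTruth-class].
#' @slot w0,M,alpha,etaThreshold,nSurrogates,surrogate link-assessment
#'   parameters (see [assessLinks()]).
#' @slot positionJitterSd per-subject node-position jitter, mm.
#' @seealso [syntheticConfig()]
#' @export
setClass("SyntheticConfig",
  representation(nNodes = "integer", nSubjects = "integer",
                 samplingPeriod = "numeric", duration = "numeric",
                 noiseBand = "numeric", seed = "integer",
                 groundTruth = "GroundTruth",
                 w0 = "numeric", M = "integer", alpha = "numeric",
                 etaThreshold = "numeric", nSurrogates = "integer",
                 surrogate = "character", positionJitterSd = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nNodes < 2L) msg <- c(msg, "nNodes must be >= 2")
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@samplingPeriod <= 0) msg <- c(msg, "samplingPeriod must be > 0")
  wmax <- object@M * object@w0
  if (object@duration < 5 * wmax)
    msg <- c(msg, sprintf("duration (%g s) must be at least 5 x M*w0 (%g s)",
                          object@duration, 5 * wmax))
  if (!object@surrogate %in% c("ft", "aaft", "iaaft"))
    msg <- c(msg, "surrogate must be ft, aaft or iaaft")
  if (length(object@noiseBand) != 2L || diff(object@noiseBand) <= 0)
    msg <- c(msg, "noiseBand must be an increasing pair of Hz values")
  if (length(msg)) msg else TRUE
})

#' Synthetic-configuration constructor
#'
#' @param nNodes,nSubjects cohort geometry.
#' @param samplingPeriod,duration sampling period and recording length (s).
#' @param noiseBand band edges (Hz) of the band-limited Gaussian signals.
#' @param seed master seed.
#' @param groundTruth a [GroundTruth-class]; defaults to [groundTruth()].
#' @param w0,M,alpha,etaThreshold,nSurrogates,surrogate link-assessment
#'   parameters used for calibration and downstream assessment.
#' @param positionJitterSd per-subject anatomical jitter of node positions (mm).
#' @return A [SyntheticConfig-class] object.
#' @export
syntheticConfig <- function(nNodes = 72, nSubjects = 10,
                            samplingPeriod = 0.004, duration = 180,
                            noiseBand = c(0.5, 45), seed = 1,
                            groundTruth = netobs::groundTruth(),
                            w0 = 0.2, M = 150, alpha = 0.05,
                            etaThreshold = 0.5, nSurrogates = 200,
                            surrogate = "iaaft", positionJitterSd = 2) {
  new("SyntheticConfig", nNodes = as.integer(nNodes),
      nSubjects = as.integer(nSubjects),
      samplingPeriod = as.numeric(samplingPeriod),
      duration = as.numeric(duration), noiseBand = as.numeric(noiseBand),
      seed = as.integer(seed), groundTruth = groundTruth,
      w0 = as.numeric(w0), M = as.integer(M), alpha = as.numeric(alpha),
      etaThreshold = as.numeric(etaThreshold),
      nSurrogates = as.integer(nSurrogates),
      surrogate = as.character(surrogate),
      positionJitterSd = as.numeric(positionJitterSd))
}

#' Calibration curve between pair correlation and time scale
#'
#' Monotone (non-increasing) empirical mapping from the zero-lag correlation
#' rho of a pair of band-limited signals to the median time scale of
#' observability W returned by the estimator.
#'
#' @slot rhoGrid correlation values in (0, 1), increasing.
#' @slot WofRho median W per rho (s), non-increasing; `NA` where the
#'   estimator found no link in most replicates.
#' @slot nReps integer(1), Monte-Carlo replicates per grid point.
#' @slot seed integer(1).
#' @seealso [calibrateRhoToW()], [rhoForTargetW()]
#' @export
setClass("CalibrationCurve",
  representation(rhoGrid = "numeric", WofRho = "numeric",
                 nReps = "integer", seed = "integer"))

setValidity("CalibrationCurve", function(object) {
  if (length(object@rhoGrid) != length(object@WofRho))
    return("rhoGrid and WofRho must have equal length")
  if (any(object@rhoGrid <= 0 | object@rhoGrid >= 1))
    return("rhoGrid must lie in (0, 1)")
  if (is.unsorted(object@rhoGrid, strictly = TRUE))
    return("rhoGrid must be strictly increasing")
  w <- object@WofRho[is.finite(object@WofRho)]
  if (length(w) > 1 && any(diff(w) > 1e-9))
    return("WofRho must be non-increasing in rho")
  TRUE
})

## ---------------------------------------------------------------------------
## Distribution classes
## ---------------------------------------------------------------------------

#' Two-dimensional binning of (d, W)
#'
#' Bin edges for the distance axis (mm, or ln mm when `logD`) and the W axis
#' (s).  Edges of length 0 mean "span the data when first used".  Bins are
#' right-open except the last, which is closed.
#'
#' @slot dEdges,wEdges numeric, strictly increasing (possibly empty).
#' @slot nBinsD,nBinsW integers, used when edges are auto-spanned.
#' @slot logD logical(1): bin distance uniformly in ln d.
#' @seealso [binning2d()]
#' @export
setClass("Binning2D",
  representation(dEdges = "numeric", wEdges = "numeric",
                 nBinsD = "integer", nBinsW = "integer", logD = "logical"))

setValidity("Binning2D", function(object) {
  msg <- character()
  if (length(object@dEdges) && is.unsorted(object@dEdges, strictly = TRUE))
    msg <- c(msg, "dEdges must be strictly increasing")
  if (length(object@wEdges) && is.unsorted(object@wEdges, strictly = TRUE))
    msg <- c(msg, "wEdges must be strictly increasing")
  if (object@nBinsD < 1L || object@nBinsW < 1L)
    msg <- c(msg, "bin counts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Binning constructor
#' @param nBinsD,nBinsW number of bins per axis (study analyses use 25 or 50).
#' @param logD bin the distance axis uniformly in ln d.
#' @param dEdges,wEdges explicit edges; default auto-span from the data.
#' @return A [Binning2D-class] object.
#' @export
binning2d <- function(nBinsD = 25, nBinsW = 25, logD = FALSE,
                      dEdges = numeric(), wEdges = numeric()) {
  new("Binning2D", dEdges = as.numeric(dEdges), wEdges = as.numeric(wEdges),
      nBinsD = as.integer(nBinsD), nBinsW = as.integer(nBinsW),
      logD = as.logical(logD))
}

#' Joint sample distribution f(d, W)
#'
#' Normalised 2-D histogram of (distance, time scale) over observable links;
#' rows are distance bins, columns W bins.
#'
#' @slot f numeric matrix of bin probabilities (sums to 1).
#' @slot counts integer matrix of the same shape.
#' @slot binning the realised [Binning2D-class] (edges filled in).
#' @seealso [jointDistribution()], [marginals()], [conditionalCurve()]
#' @export
setClass("JointDistribution",
  representation(f = "matrix", counts = "matrix", binning = "Binning2D"))

setValidity("JointDistribution", function(object) {
  if (any(object@f < 0)) return("probabilities must be non-negative")
  if (abs(sum(object@f) - 1) > 1e-12) return("f must sum to 1")
  if (!all(dim(object@f) == dim(object@counts)))
    return("f and counts must have the same shape")
  TRUE
})

#' Conditional distribution and mean curve of W given distance
#'
#' Column-normalised conditional `f(W | d)` (rows W bins, columns d bins)
#' plus, per distance bin, the probability-weighted mean `Wbar`, the weighted
#' standard deviation, and the bin count.  `x` holds the distance-bin centers
#' on the binning's axis scale (mm, or ln mm when `logD`).
#'
#' @slot conditional numeric matrix W x d; nonempty columns sum to 1.
#' @slot table data.frame with columns `x`, `wbar`, `sd`, `n`.
#' @slot binning the [Binning2D-class] used.
#' @export
setClass("ConditionalCurve",
  representation(conditional = "matrix", table = "data.frame",
                 binning = "Binning2D"))

## ---------------------------------------------------------------------------
## Fit classes
## ---------------------------------------------------------------------------

#' Three-regime piecewise-linear fit of Wbar versus ln d
#'
#' Result of the two-step breakpoint procedure: three independent weighted
#' line fits of `Wbar` on `ln d`, with the regime boundaries given by the
#' abscissae of intersection of consecutive lines.  Continuity at the
#' breakpoints is not enforced.
#'
#' @slot slopes,slopeSE numeric(3), s per unit ln(d/mm).
#' @slot intercepts,interceptSE numeric(3), s (at ln d = 0).
#' @slot breakpoints,breakpointSE numeric(2), mm.
#' @slot segments data.frame with per-segment point counts and residual
#'   summaries.
#' @slot step1 list with the first-step slopes, intercepts and breakpoints.
#' @seealso [twoStepPiecewiseFit()]
#' @export
setClass("PiecewiseFit",
  representation(slopes = "numeric", slopeSE = "numeric",
                 intercepts = "numeric", interceptSE = "numeric",
                 breakpoints = "numeric", breakpointSE = "numeric",
                 segments = "data.frame", step1 = "list"))

#' Power-law fit of W versus distance
#'
#' `W = W0 * (d / d0)^gamma`, fitted linearly in log-log coordinates.
#'
#' @slot gamma,gammaSE exponent and its standard error.
#' @slot W0,W0SE amplitude at the reference distance (s).
#' @slot d0 reference distance (mm).
#' @seealso [fitPowerLaw()]
#' @export
setClass("PowerLawFit",
  representation(gamma = "numeric", gammaSE = "numeric",
                 W0 = "numeric", W0SE = "numeric", d0 = "numeric"))

## ---------------------------------------------------------------------------
## KS2D result
## ---------------------------------------------------------------------------

#' Two-sample 2-D Kolmogorov-Smirnov result
#'
#' @slot D statistic in `[0, 1]`.
#' @slot p probability in `(0, 1]`.
#' @slot n1,n2 sample sizes.
#' @slot method `"asymptotic"` or `"permutation"`.
#' @seealso [ks2dTest()]
#' @export
setClass("KS2DResult",
  representation(D = "numeric", p = "numeric", n1 = "integer",
                 n2 = "integer", method = "character"))

setValidity("KS2DResult", function(object) {
  if (object@D < 0 || object@D > 1) return("D must lie in [0, 1]")
  if (object@p <= 0 || object@p > 1) return("p must lie in (0, 1]")
  TRUE
})
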