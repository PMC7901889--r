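## Core link-assessment chain: window grid -> r(k,w) -> p(k,w) -> eta(w) -> W.

#' Build the multiscale window grid
#'
#' Widths are `m*w0` for `m = 1 ... M`; every width shares the same centers,
#' starting at `M*w0/2` and stepping by `w0` up to `N*T - M*w0/2`.  Windows
#' are half-open sample intervals, so the window of width `m*w0` holds
#' exactly `m*w0/T` samples.
#'
#' @param nSamples series length `N`.
#' @param samplingPeriod sampling period `T` (s); `w0` must be a positive
#'   multiple of it.
#' @param w0 minimum window width (s).
#' @param M number of widths.
#' @return A [WindowGrid-class].
#' @examples
#' g <- buildWindowGrid(60000, 0.004, w0 = 0.2, M = 150)
#' length(centers(g))   # 1051
#' @export
buildWindowGrid <- function(nSamples, samplingPeriod, w0 = 0.2, M = 150) {
  nSamples <- as.integer(nSamples); M <- as.integer(M)
  L0r <- w0 / samplingPeriod
  if (abs(L0r - round(L0r)) > 1e-8 || round(L0r) < 1)
    stop("w0 must be a positive whole multiple of the sampling period",
         call. = FALSE)
  L0 <- as.integer(round(L0r))
  if (nSamples < M * L0)
    stop(sprintf("sequence too short: N*T = %g s < M*w0 = %g s",
                 nSamples * samplingPeriod, M * w0), call. = FALSE)
  K <- nSamples %/% L0 - M + 1L               # number of centers
  lens <- L0 * seq_len(M)
  # centers in half-samples to keep exact integer arithmetic
  centers2 <- M * L0 + 2L * L0 * (seq_len(K) - 1L)
  centers <- centers2 / 2 * samplingPeriod
  starts <- matrix(0L, K, M)
  for (m in seq_len(M))
    starts[, m] <- as.integer((centers2 - lens[m]) %/% 2L)
  new("WindowGrid", w0 = w0, M = M, samplingPeriod = samplingPeriod,
      nSamples = nSamples, widths = w0 * seq_len(M), centers = centers,
      starts = starts, lens = as.integer(lens))
}

checkGridInput <- function(x, y, grid) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) != grid@nSamples)
    stop("series length does not match the window grid", call. = FALSE)
}

#' Windowed Pearson correlation diagram
#'
#' Sample Pearson coefficient of `x` and `y` over every window of the grid.
#' Cells where either window is constant are `NA` (undefined correlation);
#' downstream they count as non-significant.
#'
#' @param x,y numeric series of equal length, matching `grid`.
#' @param grid a [WindowGrid-class].
#' @return A [CorrelationDiagram-class] (centers x widths).
#' @export
windowedPearson <- function(x, y, grid) {
  checkGridInput(x, y, grid)
  r <- .xcorrDiagramCpp(as.numeric(x), as.numeric(y), grid@starts, grid@lens)
  new("CorrelationDiagram", values = r, centers = grid@centers,
      widths = grid@widths)
}

pairSeed <- function(seed, a, b) {
  # deterministic, order-independent per-pair sub-seed
  h <- function(s) {
    v <- utf8ToInt(as.character(s))
    sum(v * (31 ^ (seq_along(v) %% 7))) %% 1000003
  }
  ids <- sort(c(as.character(a), as.character(b)))
  (as.numeric(seed) * 7919 + h(ids[1]) * 104729 + h(ids[2]) * 1299709) %%
    2147483629
}

#' Surrogate-based p-value diagram
#'
#' For each of `nSurrogates` replicates both full-length series are
#' independently surrogated and the whole correlation diagram is recomputed
#' on the same grid; the two-sided p value of each cell is
#' `(g + 1)/(nSurrogates + 1)` with `g` the number of replicates whose
#' `|r|` reaches the observed `|r|`.  The smallest attainable p is therefore
#' `1/(nSurrogates + 1)`.
#'
#' @param x,y numeric series matching `grid`.
#' @param grid a [WindowGrid-class].
#' @param nSurrogates number of surrogate replicates (>= 19).
#' @param method surrogate type, see [makeSurrogate()].
#' @param seed integer seed.
#' @param surrogatesX,surrogatesY optional pre-generated surrogate matrices
#'   (`length(x)` x `nSurrogates`), e.g. a per-node pool shared across pairs.
#' @return A [PValueDiagram-class].
#' @export
pvalueDiagram <- function(x, y, grid, nSurrogates = 200,
                          method = c("iaaft", "aaft", "ft"), seed = 1,
                          surrogatesX = NULL, surrogatesY = NULL) {
  method <- match.arg(method)
  checkGridInput(x, y, grid)
  if (nSurrogates < 19) stop("nSurrogates must be at least 19", call. = FALSE)
  if (is.null(surrogatesX))
    surrogatesX <- surrogateMatrix(x, nSurrogates, method, seed)
  if (is.null(surrogatesY))
    surrogatesY <- surrogateMatrix(y, nSurrogates, method, seed + 1)
  res <- .pairExceedCpp(as.numeric(x), as.numeric(y), surrogatesX, surrogatesY,
                        grid@starts, grid@lens)
  p <- (res$g + 1) / (nSurrogates + 1)
  p[is.na(res$r)] <- NA_real_
  new("PValueDiagram", values = p, centers = grid@centers,
      widths = grid@widths, nSurrogates = as.integer(nSurrogates),
      surrogateMethod = method)
}

#' Efficiency function
#'
#' Fraction of windows of each width whose correlation is significant at
#' `alpha`; undefined cells (`NA` p values) count as non-significant.
#'
#' @param p a [PValueDiagram-class].
#' @param alpha p-value threshold (default 0.05).
#' @return An [EfficiencyCurve-class].
#' @export
efficiency <- function(p, alpha = 0.05) {
  sig <- p@values < alpha
  sig[is.na(sig)] <- FALSE
  new("EfficiencyCurve", eta = colMeans(sig), widths = p@widths,
      alpha = alpha)
}

#' Time scale of observability
#'
#' The smallest window width at which the efficiency curve overcomes the
#' threshold (strictly, by default; ties at exactly the threshold do not
#' qualify).  `NA` when no width qualifies: no link is deemed to exist.
#'
#' @param eta an [EfficiencyCurve-class].
#' @param threshold efficiency threshold (default 0.5).
#' @param strict require `eta > threshold` (default) rather than `>=`.
#' @return numeric(1): the width in seconds, or `NA`.
#' @export
observabilityTimescale <- function(eta, threshold = 0.5, strict = TRUE) {
  hit <- if (strict) eta@eta > threshold else eta@eta >= threshold
  i <- which(hit)
  if (!length(i)) NA_real_ else eta@widths[min(i)]
}

hemispherePair <- function(h1, h2) {
  n <- sum(c(h1, h2) == "right")
  c("LL", "LR", "RR")[n + 1L]
}

#' Assess links for every node pair of a subject
#'
#' Runs the full chain (windowed Pearson diagram, surrogate p values,
#' efficiency, time scale of observability) on each of the `N(N-1)/2`
#' unordered node pairs and returns one record per pair with the Euclidean
#' distance of the node positions and the detected `W` (`NA` when no link).
#' Reproducible given `seed`: per-pair sub-seeds are derived
#' deterministically from the sorted node identifiers.
#'
#' @param ts a [TimeSeriesSet-class]; its node ids must appear in `nodes`.
#' @param nodes a [NodeTable-class] with positions in mm.
#' @param w0,M window-grid parameters (see [buildWindowGrid()]).
#' @param alpha p-value threshold.
#' @param etaThreshold efficiency threshold.
#' @param nSurrogates surrogate replicates per pair.
#' @param surrogate surrogate type, see [makeSurrogate()].
#' @param seed master seed.
#' @param shareSurrogates generate one surrogate pool per node (seeded from
#'   the node id) and reuse it across all pairs involving that node, instead
#'   of drawing a fresh pool per pair.  Replicates remain mutually
#'   independent; this cuts the dominant FFT cost by ~`N` for cohort-scale
#'   runs.
#' @return A [LinkTable-class] with `N(N-1)/2` rows, ordered by node id.
#' @export
assessLinks <- function(ts, nodes, w0 = 0.2, M = 150, alpha = 0.05,
                        etaThreshold = 0.5, nSurrogates = 200,
                        surrogate = c("iaaft", "aaft", "ft"), seed = 1,
                        shareSurrogates = FALSE) {
  surrogate <- match.arg(surrogate)
  ids <- sort(nodeIds(ts))
  nd <- nodeData(nodes)
  miss <- setdiff(ids, nd$node_id)
  if (length(miss))
    stop("node ids missing from the node table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  nd <- nd[match(ids, nd$node_id), ]
  pos <- as.matrix(nd[, c("x", "y", "z")])
  X <- signalMatrix(ts)[, ids, drop = FALSE]
  grid <- buildWindowGrid(nrow(X), samplingPeriod(ts), w0 = w0, M = M)

  pool <- NULL
  if (shareSurrogates) {
    pool <- lapply(seq_along(ids), function(i)
      surrogateMatrix(X[, i], nSurrogates, surrogate,
                      pairSeed(seed, ids[i], "@pool")))
    names(pool) <- ids
  }

  n <- length(ids)
  nPairs <- (n * (n - 1L)) %/% 2L
  out <- data.frame(subject_id = rep(subjectId(ts), nPairs),
                    node_a = character(nPairs), node_b = character(nPairs),
                    hemisphere_pair = character(nPairs),
                    d_mm = numeric(nPairs), W_s = numeric(nPairs))
  row <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      row <- row + 1L
      if (shareSurrogates) {
        p <- pvalueDiagram(X[, i], X[, j], grid, nSurrogates, surrogate,
                           seed = pairSeed(seed, ids[i], ids[j]),
                           surrogatesX = pool[[i]], surrogatesY = pool[[j]])
      } else {
        p <- pvalueDiagram(X[, i], X[, j], grid, nSurrogates, surrogate,
                           seed = pairSeed(seed, ids[i], ids[j]))
      }
      W <- observabilityTimescale(efficiency(p, alpha), etaThreshold)
      out$node_a[row] <- ids[i]
      out$node_b[row] <- ids[j]
      out$hemisphere_pair[row] <- hemispherePair(nd$hemisphere[i],
                                                 nd$hemisphere[j])
      out$d_mm[row] <- euclideanDistance(pos[i, ], pos[j, ])
      out$W_s[row] <- W
    }
  }
  linkTable(out)
}
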