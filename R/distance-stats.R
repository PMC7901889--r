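## Joint, marginal and conditional sample distributions of (d, W).

#' Euclidean distance between two 3-D positions
#' @param a,b numeric 3-vectors (mm).
#' @return distance in mm.
#' @examples euclideanDistance(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
euclideanDistance <- function(a, b) {
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

## bin index per value: right-open bins, last bin closed
binIndex <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE)
  i[v < edges[1] | v > edges[length(edges)]] <- NA_integer_
  i
}

autoEdges <- function(v, nBins) {
  r <- range(v)
  if (diff(r) <= 0) r <- r + c(-0.5, 0.5)      # degenerate: single value
  seq(r[1], r[2], length.out = nBins + 1L)
}

observableLinks <- function(links) {
  lk <- if (is(links, "LinkTable")) linkData(links) else links
  lk[is.finite(lk$W_s), , drop = FALSE]
}

#' Joint sample distribution f(d, W)
#'
#' Normalised 2-D histogram of link length and time scale over observable
#' links (finite `W` only).  With `logD` bins are uniform in `ln d` (d in
#' mm).  Bin edges default to the span of the data.
#'
#' @param links a [LinkTable-class] or its data.frame.
#' @param binning a [Binning2D-class]; see [binning2d()].
#' @return A [JointDistribution-class].
#' @export
jointDistribution <- function(links, binning = binning2d()) {
  lk <- observableLinks(links)
  if (!nrow(lk)) stop("no observable links: cannot build a distribution",
                      call. = FALSE)
  d <- if (binning@logD) log(lk$d_mm) else lk$d_mm
  w <- lk$W_s
  dE <- if (length(binning@dEdges)) binning@dEdges else autoEdges(d, binning@nBinsD)
  wE <- if (length(binning@wEdges)) binning@wEdges else autoEdges(w, binning@nBinsW)
  di <- binIndex(d, dE); wi <- binIndex(w, wE)
  keep <- !is.na(di) & !is.na(wi)
  counts <- matrix(0L, length(dE) - 1L, length(wE) - 1L)
  tab <- table(factor(di[keep], levels = seq_len(nrow(counts))),
               factor(wi[keep], levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  f <- counts / sum(counts)
  used <- binning2d(nBinsD = nrow(counts), nBinsW = ncol(counts),
                    logD = binning@logD, dEdges = dE, wEdges = wE)
  new("JointDistribution", f = f, counts = counts, binning = used)
}

#' Marginal distributions of d and W
#'
#' Row and column sums of the joint distribution; each sums to 1.
#'
#' @param joint a [JointDistribution-class].
#' @return list with `gD` and `gW` (named numeric vectors of bin centers).
#' @export
marginals <- function(joint) {
  dE <- joint@binning@dEdges; wE <- joint@binning@wEdges
  gD <- rowSums(joint@f); gW <- colSums(joint@f)
  names(gD) <- format((dE[-1] + dE[-length(dE)]) / 2, digits = 6)
  names(gW) <- format((wE[-1] + wE[-length(wE)]) / 2, digits = 6)
  list(gD = gD, gW = gW)
}

#' Conditional distribution f(W | d) and the mean curve Wbar
#'
#' Column-normalises the joint distribution into `f(W | d)` (rows W bins,
#' columns d bins) and evaluates, per distance bin, the probability-weighted
#' mean of the W bin centers, `Wbar = sum_W W f(W | d)`, together with the
#' weighted standard deviation and the bin count.  Empty distance bins are
#' reported with `n = 0` and `NA` mean.  The 68% band used in plots is
#' `Wbar +/- sd`.
#'
#' @param joint a [JointDistribution-class].
#' @return A [ConditionalCurve-class]; its `table` has distance-bin centers
#'   `x` on the binning's axis scale (mm, or ln mm when `logD`).
#' @export
conditionalCurve <- function(joint) {
  dE <- joint@binning@dEdges; wE <- joint@binning@wEdges
  dC <- (dE[-1] + dE[-length(dE)]) / 2
  wC <- (wE[-1] + wE[-length(wE)]) / 2
  gD <- rowSums(joint@f)
  cond <- t(joint@f)                                # W x d
  n <- colSums(t(joint@counts))
  wbar <- sdv <- rep(NA_real_, length(dC))
  for (j in seq_along(dC)) {
    if (gD[j] > 0) {
      pj <- cond[, j] / gD[j]
      cond[, j] <- pj
      wbar[j] <- sum(wC * pj)
      sdv[j] <- sqrt(max(0, sum(wC^2 * pj) - wbar[j]^2))
    }
  }
  tab <- data.frame(x = dC, wbar = wbar, sd = sdv, n = as.integer(n))
  new("ConditionalCurve", conditional = cond, table = tab,
      binning = joint@binning)
}

#' Raw-sample conditional mean of W per distance bin
#'
#' Cross-check variant of [conditionalCurve()]: the per-bin mean and
#' standard deviation of the raw `W` samples rather than of the binned
#' distribution.
#'
#' @param links a [LinkTable-class] or data.frame.
#' @param binning a [Binning2D-class].
#' @return data.frame with columns `x`, `wbar`, `sd`, `n`.
#' @export
conditionalCurveRaw <- function(links, binning = binning2d()) {
  lk <- observableLinks(links)
  if (!nrow(lk)) stop("no observable links", call. = FALSE)
  d <- if (binning@logD) log(lk$d_mm) else lk$d_mm
  dE <- if (length(binning@dEdges)) binning@dEdges else autoEdges(d, binning@nBinsD)
  di <- binIndex(d, dE)
  dC <- (dE[-1] + dE[-length(dE)]) / 2
  out <- data.frame(x = dC, wbar = NA_real_, sd = NA_real_, n = 0L)
  for (j in seq_along(dC)) {
    w <- lk$W_s[which(di == j)]
    out$n[j] <- length(w)
    if (length(w)) {
      out$wbar[j] <- mean(w)
      out$sd[j] <- if (length(w) > 1) stats::sd(w) else 0
    }
  }
  out
}
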