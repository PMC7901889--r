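## Two-sample two-dimensional Kolmogorov-Smirnov test (Fasano-Franceschini
## statistic, Peacock-style asymptotic probability after Press et al., plus
## a permutation mode that serves as the ground-truth oracle).

asPointMatrix <- function(s) {
  if (is(s, "LinkTable")) {
    lk <- observableLinks(s)
    s <- cbind(lk$d_mm, lk$W_s)
  }
  m <- as.matrix(s)
  if (ncol(m) != 2) stop("samples must be 2-column point sets", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Fasano-Franceschini 2-D KS statistic
#'
#' For every data point of each sample taken as origin, the four open
#' quadrants around it are compared between the two samples' point
#' fractions; `D` is the mean of the two per-sample maximal absolute
#' differences.  Points lying on a dividing line are excluded from all four
#' quadrant counts (tie convention).
#'
#' @param s1,s2 two-column matrices (or [LinkTable-class]s, using the
#'   `(d, W)` points of observable links); at least 3 points each.
#' @return `D` in `[0, 1]`.
#' @export
ks2dStatistic <- function(s1, s2) {
  a <- asPointMatrix(s1); b <- asPointMatrix(s2)
  if (nrow(a) < 3 || nrow(b) < 3)
    stop("both samples need at least 3 points", call. = FALSE)
  .ks2dStatCpp(a, b)
}

## Kolmogorov Q function
qKS <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- 1:101
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' P value for the 2-D KS statistic
#'
#' Asymptotic form: with effective size `n = n1 n2 / (n1 + n2)` and the
#' coordinate-correlation correction `rr = sqrt(1 - (r1^2 + r2^2)/2)`,
#' `p = Q_KS( D sqrt(n) / (1 + rr (0.25 - 0.75/sqrt(n))) )`.
#'
#' @param D statistic from [ks2dStatistic()].
#' @param n1,n2 sample sizes (>= 3).
#' @param r1,r2 Pearson correlations between the two coordinates within each
#'   sample.
#' @return probability in `(0, 1]`.
#' @export
ks2dPValue <- function(D, n1, n2, r1 = 0, r2 = 0) {
  if (D < 0 || D > 1) stop("D must lie in [0, 1]", call. = FALSE)
  n <- n1 * n2 / (n1 + n2)
  rr <- sqrt(max(1 - (r1^2 + r2^2) / 2, 0))
  lam <- sqrt(n) * D / (1 + rr * (0.25 - 0.75 / sqrt(n)))
  max(qKS(lam), .Machine$double.xmin)
}

safeCor <- function(m) {
  if (stats::sd(m[, 1]) == 0 || stats::sd(m[, 2]) == 0) return(0)
  stats::cor(m[, 1], m[, 2])
}

#' Two-sample 2-D Kolmogorov-Smirnov test
#'
#' Compares two bivariate samples, typically `(d, W)` point sets from two
#' node sets.  `method = "asymptotic"` uses the Press et al. probability;
#' `method = "permutation"` pools the points, reshuffles the labels `B`
#' times and reports `p = (g + 1) / (B + 1)` with `g` the permutations whose
#' `D` reaches the observed one.
#'
#' @param s1,s2 two-column point sets (or [LinkTable-class]s).
#' @param method `"asymptotic"` or `"permutation"`.
#' @param B permutation replicates.
#' @param seed integer seed for the permutation mode.
#' @return A [KS2DResult-class].
#' @export
ks2dTest <- function(s1, s2, method = c("asymptotic", "permutation"),
                     B = 999, seed = 1) {
  method <- match.arg(method)
  a <- asPointMatrix(s1); b <- asPointMatrix(s2)
  if (nrow(a) < 3 || nrow(b) < 3)
    stop("both samples need at least 3 points", call. = FALSE)
  D <- .ks2dStatCpp(a, b)
  if (method == "asymptotic") {
    p <- ks2dPValue(D, nrow(a), nrow(b), safeCor(a), safeCor(b))
  } else {
    pool <- rbind(a, b)
    Db <- withSeed(seed, .ks2dPermCpp(pool, nrow(a), as.integer(B)))
    p <- (sum(Db >= D) + 1) / (B + 1)
  }
  new("KS2DResult", D = D, p = p, n1 = nrow(a), n2 = nrow(b), method = method)
}

#' Bonferroni gate over a family of p values
#'
#' @param pValues non-empty numeric vector.
#' @param alpha family-wise level (default 0.05).
#' @return list with `correctedLevel = alpha / length(pValues)` and logical
#'   `reject` flags (`p < correctedLevel`).
#' @examples
#' bonferroniGate(rep(0.02, 7))$reject   # none: 0.02 > 0.05/7
#' @export
bonferroniGate <- function(pValues, alpha = 0.05) {
  if (!length(pValues)) stop("pValues must be non-empty", call. = FALSE)
  lvl <- alpha / length(pValues)
  list(correctedLevel = lvl, reject = pValues < lvl)
}
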