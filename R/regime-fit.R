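## Three-regime piecewise-linear fit of Wbar versus ln d, and the
## third-regime power-law comparison fit.

#' Weighted straight-line fit
#'
#' Weighted least squares of `y` on `x` with parameter covariance.  Default
#' curve weights downstream are `n / sd^2` per distance bin.
#'
#' @param x,y numeric vectors (>= 2 distinct x).
#' @param weights optional non-negative weights.
#' @return list with `slope`, `intercept`, `cov` (2 x 2, intercept first),
#'   `sigma` (residual standard deviation) and `n`.
#' @export
fitLine <- function(x, y, weights = NULL) {
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(weights)) keep <- keep & is.finite(weights)
  x <- x[keep]; y <- y[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(unique(x)) < 2)
    stop("degenerate fit: need at least 2 distinct x values", call. = FALSE)
  fit <- if (is.null(weights)) stats::lm(y ~ x) else
    stats::lm(y ~ x, weights = weights)
  cf <- stats::coef(fit)
  ## summary.lm warns on exact fits; zero covariance is the right answer there
  V <- suppressWarnings(stats::vcov(fit))
  ## exact fits have zero residual variance; vcov is then 0, which is fine
  if (any(!is.finite(V))) V[!is.finite(V)] <- 0
  list(slope = unname(cf[2]), intercept = unname(cf[1]), cov = V,
       sigma = suppressWarnings(stats::sigma(fit)), n = length(x))
}

#' Abscissa of intersection of two straight lines
#'
#' `x* = (b2 - b1) / (m1 - m2)`, with first-order uncertainty propagated
#' from both lines' parameter covariances (lines fitted on disjoint data are
#' treated as independent).
#'
#' @param l1,l2 line fits from [fitLine()].
#' @return list with `x` and `se`.
#' @export
intersectLines <- function(l1, l2) {
  dm <- l1$slope - l2$slope
  if (abs(dm) < 1e-12 * max(abs(l1$slope), abs(l2$slope), 1))
    stop("lines are parallel: no intersection", call. = FALSE)
  xs <- (l2$intercept - l1$intercept) / dm
  ## gradient of x* wrt (b1, m1) and (b2, m2)
  g1 <- c(-1 / dm, -xs / dm)
  g2 <- c(1 / dm, xs / dm)
  v <- as.numeric(t(g1) %*% l1$cov %*% g1 + t(g2) %*% l2$cov %*% g2)
  list(x = xs, se = sqrt(max(v, 0)))
}

curveForFit <- function(curve) {
  if (is(curve, "ConditionalCurve")) {
    tab <- curve@table
    x <- if (curve@binning@logD) tab$x else log(tab$x)
    data.frame(x = x, y = tab$wbar, sd = tab$sd, n = tab$n)
  } else {
    stopifnot(all(c("x", "wbar", "n") %in% names(curve)))
    data.frame(x = curve$x, y = curve$wbar,
               sd = if ("sd" %in% names(curve)) curve$sd else NA_real_,
               n = curve$n)
  }
}

segmentWeights <- function(seg) {
  ## n/sd^2 when the dispersions are informative; otherwise unweighted
  if (all(is.finite(seg$sd)) && all(seg$sd > 1e-9)) seg$n / seg$sd^2 else NULL
}

fitSegments <- function(df, lb1, lb2, minPoints) {
  segIdx <- list(which(df$x <= lb1),
                 which(df$x > lb1 & df$x <= lb2),
                 which(df$x > lb2))
  fits <- vector("list", 3)
  for (s in 1:3) {
    idx <- segIdx[[s]]
    if (length(idx) < minPoints)
      stop(sprintf("segment %d has %d bins; need at least %d (breaks at d = %.3g, %.3g mm)",
                   s, length(idx), minPoints, exp(lb1), exp(lb2)),
           call. = FALSE)
    seg <- df[idx, ]
    fits[[s]] <- fitLine(seg$x, seg$y, segmentWeights(seg))
  }
  fits
}

#' Two-step three-regime piecewise-linear fit
#'
#' Step 1: with the ln-d axis cut at the initial breakpoints, three straight
#' lines are fitted independently on the three ranges; the two abscissae of
#' intersection of consecutive lines replace the initial breakpoints.
#' Step 2: the three lines are refitted on the updated ranges; the reported
#' slopes and intercepts are the step-2 fits and the reported breakpoints the
#' step-2 intersections, with first-order-propagated uncertainties.  Exactly
#' two steps are performed unless `iterate` is set.  Continuity at the
#' breakpoints is not enforced.
#'
#' @param curve a [ConditionalCurve-class] (or a data.frame with columns
#'   `x` = ln d, `wbar`, `sd`, `n`); bins with `n < 2` are dropped.
#' @param initD12,initD23 initial breakpoints (mm).
#' @param minPointsPerSegment minimum bins per segment (default 3).
#' @param iterate if `TRUE`, repeat the refit step until the breakpoints move
#'   by less than `tol` (off by default; the canonical procedure is two
#'   steps).
#' @param maxIter,tol iteration controls when `iterate` is set.
#' @return A [PiecewiseFit-class].
#' @export
twoStepPiecewiseFit <- function(curve, initD12 = 44, initD23 = 68,
                                minPointsPerSegment = 3, iterate = FALSE,
                                maxIter = 20, tol = 1e-6) {
  if (initD12 >= initD23) stop("initial breakpoints must be ordered",
                               call. = FALSE)
  df <- curveForFit(curve)
  df <- df[is.finite(df$y) & df$n >= 2, ]
  if (nrow(df) < 3 * minPointsPerSegment)
    stop("too few usable bins for a three-segment fit", call. = FALSE)
  rng <- range(df$x)

  oneStep <- function(lb1, lb2) {
    fits <- fitSegments(df, lb1, lb2, minPointsPerSegment)
    i12 <- intersectLines(fits[[1]], fits[[2]])
    i23 <- intersectLines(fits[[2]], fits[[3]])
    list(fits = fits, i12 = i12, i23 = i23)
  }
  checkBreaks <- function(st, stage) {
    if (!(st$i12$x < st$i23$x))
      stop(sprintf("%s breakpoints are not ordered (d12 = %.3g, d23 = %.3g mm)",
                   stage, exp(st$i12$x), exp(st$i23$x)), call. = FALSE)
    if (st$i12$x < rng[1] || st$i23$x > rng[2])
      stop(sprintf("%s breakpoints fall outside the data range (d12 = %.3g, d23 = %.3g mm)",
                   stage, exp(st$i12$x), exp(st$i23$x)), call. = FALSE)
  }

  s1 <- oneStep(log(initD12), log(initD23))
  checkBreaks(s1, "step-1")
  s2 <- oneStep(s1$i12$x, s1$i23$x)
  checkBreaks(s2, "step-2")
  if (iterate) {
    prev <- c(s1$i12$x, s1$i23$x)
    for (it in seq_len(maxIter)) {
      cur <- c(s2$i12$x, s2$i23$x)
      if (max(abs(cur - prev)) < tol) break
      prev <- cur
      s2 <- oneStep(cur[1], cur[2])
      checkBreaks(s2, "iterated")
    }
  }

  fits <- s2$fits
  segTab <- do.call(rbind, lapply(1:3, function(s)
    data.frame(segment = s, n = fits[[s]]$n, sigma = fits[[s]]$sigma)))
  bx <- c(s2$i12$x, s2$i23$x)
  bse <- c(s2$i12$se, s2$i23$se)
  new("PiecewiseFit",
      slopes = vapply(fits, `[[`, numeric(1), "slope"),
      slopeSE = vapply(fits, function(f) sqrt(f$cov[2, 2]), numeric(1)),
      intercepts = vapply(fits, `[[`, numeric(1), "intercept"),
      interceptSE = vapply(fits, function(f) sqrt(f$cov[1, 1]), numeric(1)),
      breakpoints = exp(bx),
      breakpointSE = exp(bx) * bse,     # delta method: d = exp(x*)
      segments = segTab,
      step1 = list(slopes = vapply(s1$fits, `[[`, numeric(1), "slope"),
                   intercepts = vapply(s1$fits, `[[`, numeric(1), "intercept"),
                   breakpoints = exp(c(s1$i12$x, s1$i23$x))))
}

#' Bootstrap cross-check of breakpoint uncertainties
#'
#' Resamples the curve's bins with replacement and repeats the two-step fit;
#' returns the standard deviations of the bootstrap breakpoints.
#'
#' @param curve as in [twoStepPiecewiseFit()].
#' @param initD12,initD23 initial breakpoints (mm).
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return numeric(2): bootstrap SE of d12 and d23 (mm); failed replicates
#'   are dropped.
#' @export
bootstrapBreakpointSE <- function(curve, initD12 = 44, initD23 = 68, B = 100,
                                  seed = 1) {
  df <- curveForFit(curve)
  df <- df[is.finite(df$y) & df$n >= 2, ]
  withSeed(seed, {
    bs <- matrix(NA_real_, B, 2)
    for (b in seq_len(B)) {
      idx <- sort(sample.int(nrow(df), replace = TRUE))
      rs <- df[idx, ]
      rs <- rs[!duplicated(rs$x), ]
      rs <- data.frame(x = rs$x, wbar = rs$y, sd = rs$sd, n = rs$n)
      ft <- tryCatch(twoStepPiecewiseFit(rs, initD12, initD23),
                     error = function(e) NULL)
      if (!is.null(ft)) bs[b, ] <- ft@breakpoints
    }
    apply(bs, 2, stats::sd, na.rm = TRUE)
  })
}

#' Power-law fit of W versus distance
#'
#' Fits `W = W0 (d / d0)^gamma` by linear regression of `ln W` on
#' `ln(d / d0)`; `gamma` is the slope and `W0 = exp(intercept)`.  Intended
#' for the third distance regime (`d > d23`).
#'
#' @param d distances (mm, > 0).
#' @param W time scales (s, > 0).
#' @param d0 reference distance (mm, default 75).
#' @param weights optional weights for the log-space fit.
#' @return A [PowerLawFit-class].
#' @export
fitPowerLaw <- function(d, W, d0 = 75, weights = NULL) {
  keep <- is.finite(d) & is.finite(W) & d > 0 & W > 0
  d <- d[keep]; W <- W[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(d) < 3) stop("need at least 3 points for a power-law fit",
                          call. = FALSE)
  if (d0 <= 0) stop("d0 must be positive", call. = FALSE)
  ln <- fitLine(log(d / d0), log(W), weights)
  W0 <- exp(ln$intercept)
  new("PowerLawFit", gamma = ln$slope, gammaSE = sqrt(ln$cov[2, 2]),
      W0 = W0, W0SE = W0 * sqrt(ln$cov[1, 1]), d0 = d0)
}
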