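## Synthetic cohorts with a known W(ln d) ground truth: node geometries,
## band-limited Gaussian signals with a distance-decaying shared component,
## and the empirical rho -> W calibration that keeps the ground truth honest
## against the actual estimator.

#' Place nodes inside two mirrored half-ellipsoid hemispheres
#'
#' Rejection-samples `nNodes` positions uniformly inside two half-ellipsoids
#' of head-like scale (default semi-axes 70, 85, 65 mm, mirrored about the
#' mid-sagittal plane), enforcing a minimum pairwise distance.  The first
#' half of the nodes is assigned to the left hemisphere (x < 0), the rest to
#' the right.  Deterministic given `seed`.
#'
#' @param nNodes number of nodes (>= 2).
#' @param seed integer seed.
#' @param minDist minimum pairwise distance (mm, default 10).
#' @param semiAxes ellipsoid semi-axes (mm).
#' @param midlineGap half-width of the inter-hemispheric gap (mm).
#' @param maxTries rejection attempts per node before giving up.
#' @return A [NodeTable-class] with labels `"area01" ...`.
#' @export
placeNodes <- function(nNodes, seed = 1, minDist = 10,
                       semiAxes = c(70, 85, 65), midlineGap = 3,
                       maxTries = 20000) {
  stopifnot(nNodes >= 2)
  nLeft <- nNodes %/% 2L
  withSeed(seed, {
    pos <- matrix(NA_real_, nNodes, 3)
    for (i in seq_len(nNodes)) {
      side <- if (i <= nLeft) -1 else 1
      ok <- FALSE
      for (t in seq_len(maxTries)) {
        v <- stats::rnorm(3)
        u <- v / sqrt(sum(v^2)) * stats::runif(1)^(1 / 3)
        p <- u * semiAxes
        p[1] <- side * (midlineGap + abs(p[1]))
        if (i == 1L || min(sqrt(colSums((t(pos[seq_len(i - 1), , drop = FALSE]) - p)^2))) > minDist) {
          pos[i, ] <- p; ok <- TRUE; break
        }
      }
      if (!ok)
        stop(sprintf("could not place node %d with pairwise distance > %g mm",
                     i, minDist), call. = FALSE)
    }
    nodeTable(node_id = sprintf("n%02d", seq_len(nNodes)),
              label = sprintf("area%02d", seq_len(nNodes)),
              hemisphere = c(rep("left", nLeft), rep("right", nNodes - nLeft)),
              x = pos[, 1], y = pos[, 2], z = pos[, 3])
  })
}

#' Ground-truth time scale as a function of distance
#'
#' Continuous piecewise-linear function of `ln d` with three slopes meeting
#' at the two breakpoints, clipped to the `wRange` band.
#'
#' @param d distances in mm (> 0); vectorised.
#' @param gt a [GroundTruth-class].
#' @return target W in seconds.
#' @examples
#' gt <- groundTruth(slopes = c(7, 19, 7), breakpoints = c(44, 68.3),
#'                   intercept = 10)
#' targetW(68.3, gt)   # 10 + 19 * log(68.3 / 44)
#' @export
targetW <- function(d, gt) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("distances must be finite and positive", call. = FALSE)
  ld <- log(d)
  b <- log(gt@breakpoints)
  m <- gt@slopes
  w <- ifelse(ld <= b[1], gt@intercept + m[1] * (ld - b[1]),
       ifelse(ld <= b[2], gt@intercept + m[2] * (ld - b[1]),
              gt@intercept + m[2] * (b[2] - b[1]) + m[3] * (ld - b[2])))
  pmin(pmax(w, gt@wRange[1]), gt@wRange[2])
}

## band-limited standardized Gaussian noise, one column per channel
bandNoise <- function(n, k, samplingPeriod, band) {
  w <- matrix(stats::rnorm(n * k), n, k)
  nyq <- 1 / (2 * samplingPeriod)
  lo <- band[1] / nyq
  hi <- band[2] / nyq
  if (lo > 1e-9 || hi < 1 - 1e-9) {
    lo <- max(lo, 1e-4)
    if (hi >= 1) {
      bf <- signal::butter(4, lo, type = "high")
    } else {
      bf <- signal::butter(4, c(lo, hi), type = "pass")
    }
    for (j in seq_len(k)) w[, j] <- signal::filtfilt(bf, w[, j])
  }
  scale(w)[, , drop = FALSE]
}

## Fisher-z power heuristic: samples needed to detect rho at two-sided 5%
## with ~50% power, used only to place the calibration grid.
fisherSamples <- function(rho) (stats::qnorm(0.975) / atanh(rho))^2 + 3

#' Calibrate the correlation-to-time-scale mapping
#'
#' For each correlation `rho` of a grid, simulates pairs
#' `x = sqrt(rho) z + sqrt(1-rho) e1`, `y = sqrt(rho) z + sqrt(1-rho) e2`
#' (with `z`, `e1`, `e2` independent band-limited Gaussian noises drawn per
#' the configuration) and runs the full W estimator with the configuration's
#' grid and surrogate settings; returns, per rho, the mean W over replicates
#' that detected a link (the same detected-only mean that the downstream
#' conditional curve estimates, so skew and censoring of the estimator enter
#' the curve consistently; `stat = "median"` gives the median instead),
#' forced non-increasing by isotonic regression.  The Fisher-z power
#' approximation
#' `W ~ ((z_0.975/atanh rho)^2 + 3) * T` seeds the grid placement; the
#' Monte-Carlo estimates refine it (band-limited signals carry fewer
#' effective samples per window, so their W exceeds the white-noise
#' heuristic by roughly the oversampling factor).
#'
#' @param config a [SyntheticConfig-class].
#' @param nReps Monte-Carlo replicates per grid point (>= 20).
#' @param rhoGrid optional explicit grid in (0, 1); default log-spaced around
#'   the Fisher-z bracket of the probed W band.
#' @param nGrid grid size when auto-placed.
#' @param stat summary over replicates: `"meanDetected"` (default) or
#'   `"median"` (undetected replicates counted as infinite).
#' @return A [CalibrationCurve-class].
#' @export
calibrateRhoToW <- function(config, nReps = 20, rhoGrid = NULL, nGrid = 14,
                            stat = c("meanDetected", "median")) {
  stat <- match.arg(stat)
  if (nReps < 20) stop("nReps must be at least 20", call. = FALSE)
  T <- config@samplingPeriod
  if (is.null(rhoGrid)) {
    ## Fisher-z bracket of the probed W band, corrected for the reduced
    ## effective sample count of band-limited noise (kappa = 1 + 2 sum acf)
    kap <- withSeed(config@seed + 17, {
      w <- bandNoise(8192L, 1L, T, config@noiseBand)[, 1]
      a <- stats::acf(w, lag.max = 50, plot = FALSE)$acf[-1]
      a <- a[seq_len(max(which(a > 0.05), 1))]
      max(1, 1 + 2 * sum(a))
    })
    z <- stats::qnorm(0.975)
    wmax <- config@M * config@w0
    wmin <- config@w0
    lo <- 0.85 * tanh(z / sqrt(wmax / (T * kap)))
    hi <- min(0.95, 1.2 * tanh(z / sqrt(max(3 * wmin / (T * kap), 6))))
    rhoGrid <- exp(seq(log(lo), log(hi), length.out = nGrid))
  }
  if (any(rhoGrid <= 0 | rhoGrid >= 1))
    stop("rho grid must lie in (0, 1)", call. = FALSE)
  rhoGrid <- sort(rhoGrid)
  N <- as.integer(round(config@duration / T))
  grid <- buildWindowGrid(N, T, w0 = config@w0, M = config@M)
  Ws <- matrix(NA_real_, length(rhoGrid), nReps)
  for (g in seq_along(rhoGrid)) {
    rho <- rhoGrid[g]
    for (rep in seq_len(nReps)) {
      sd0 <- config@seed + 7643 * g + 131 * rep
      sig <- withSeed(sd0, bandNoise(N, 3L, T, config@noiseBand))
      x <- sqrt(rho) * sig[, 1] + sqrt(1 - rho) * sig[, 2]
      y <- sqrt(rho) * sig[, 1] + sqrt(1 - rho) * sig[, 3]
      p <- pvalueDiagram(x, y, grid, config@nSurrogates, config@surrogate,
                         seed = sd0 + 1)
      Ws[g, rep] <- observabilityTimescale(efficiency(p, config@alpha),
                                           config@etaThreshold)
    }
  }
  med <- apply(Ws, 1, function(w) {
    if (stat == "median") {
      w[is.na(w)] <- Inf
      m <- stats::median(w)
      if (is.finite(m)) m else NA_real_
    } else {
      # detected-only mean; too few detections -> unreliable, drop the point
      if (sum(is.finite(w)) < max(3, length(w) %/% 4)) NA_real_
      else mean(w[is.finite(w)])
    }
  })
  ## average Monte-Carlo noise locally: detection-weighted geometric mean
  ## over each point and its grid neighbours (global parametric fits distort
  ## the censoring-induced curvature near the top of the band)
  ok <- which(is.finite(med))
  if (length(ok) >= 5) {
    nd <- apply(Ws, 1, function(w) sum(is.finite(w)))
    sm <- med
    for (i in ok) {
      nb <- intersect(c(i - 1L, i, i + 1L), ok)
      wgt <- pmax(nd[nb], 1)
      sm[i] <- exp(sum(wgt * log(med[nb])) / sum(wgt))
    }
    med <- sm
  }
  ## isotonic post-processing: W non-increasing in rho
  ok <- is.finite(med)
  if (sum(ok) >= 2) {
    iso <- stats::isoreg(rhoGrid[ok], -med[ok])
    med[ok] <- -iso$yf
  }
  new("CalibrationCurve", rhoGrid = rhoGrid, WofRho = med,
      nReps = as.integer(nReps), seed = config@seed)
}

#' Invert the calibration: correlation needed for a target time scale
#'
#' Linear interpolation of the monotone calibration curve inside its finite
#' range.  Beyond the largest finite median W (where the estimator censors
#' more than half of the replicates) the inverse follows the Fisher-type
#' power law `atanh(rho) ~ W^(-1/2)` fitted to the finite part of the curve,
#' so large targets still map to distinct, decreasing correlations instead
#' of being clamped.
#'
#' @param W target time scales (s).
#' @param calibration a [CalibrationCurve-class].
#' @return correlations in (0, 1).
#' @export
rhoForTargetW <- function(W, calibration) {
  ok <- is.finite(calibration@WofRho) & calibration@WofRho > 0
  if (sum(ok) < 2) stop("calibration curve has fewer than 2 finite points",
                        call. = FALSE)
  wf <- calibration@WofRho[ok]
  rf <- calibration@rhoGrid[ok]
  o <- order(wf)
  wf <- wf[o]; rf <- rf[o]
  ## de-duplicate flat isotonic steps for interpolation
  keep <- !duplicated(wf)
  out <- stats::approx(wf[keep], rf[keep], xout = W, rule = 2, ties = mean)$y
  hi <- W > max(wf)
  lo <- W < min(wf)
  if (any(hi | lo)) {
    pw <- stats::lm(log(atanh(rf)) ~ log(wf))
    pred <- function(w) tanh(exp(stats::coef(pw)[1] + stats::coef(pw)[2] * log(w)))
    ## anchor the tail to the curve endpoint so the inverse stays continuous
    if (any(hi))
      out[hi] <- pmin(out[hi], pred(W[hi]) * (rf[length(rf)] / pred(max(wf))))
    if (any(lo))
      out[lo] <- pmax(out[lo], pred(W[lo]) * (rf[1] / pred(min(wf))))
  }
  pmin(pmax(out, 1e-4), 0.999)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Per subject, node positions are jittered (anatomical variability), the
#' pairwise target correlation matrix is assembled from
#' `rho_ij = rhoForTargetW(targetW(d_ij))` with a fixed random subset of
#' pairs (the unlinked fraction) set to zero, repaired to the nearest
#' correlation matrix, and its Cholesky factor applied to independent
#' band-limited Gaussian noise.  Deterministic given the configuration seed.
#'
#' @param config a [SyntheticConfig-class].
#' @param calibration optional pre-computed [CalibrationCurve-class];
#'   computed from `config` when missing.
#' @param calibrationReps replicates for the on-the-fly calibration.
#' @return list with elements `nodes` (base geometry), `subjectNodes` (list
#'   of per-subject jittered [NodeTable-class]s), `series` (list of
#'   [TimeSeriesSet-class]s), `groundTruth`, `calibration`, `ages` (uniform
#'   over 18-88), `unlinked` (logical matrix of pairs with zero shared
#'   signal) and `rhoTarget` (list of per-subject target correlation
#'   matrices, after the nearest-correlation repair).
#' @export
generateCohort <- function(config, calibration = NULL, calibrationReps = 48) {
  gt <- config@groundTruth
  if (is.null(calibration))
    calibration <- calibrateRhoToW(config, nReps = calibrationReps)
  nodes <- placeNodes(config@nNodes, seed = config@seed)
  ids <- nodeIds(nodes)
  n <- config@nNodes
  N <- as.integer(round(config@duration / config@samplingPeriod))

  unlinked <- withSeed(config@seed + 211, {
    u <- matrix(FALSE, n, n)
    pairs <- which(upper.tri(u))
    off <- pairs[sample.int(length(pairs),
                            size = round(gt@unlinkedFraction * length(pairs)))]
    u[off] <- TRUE
    u | t(u)
  })

  subjectNodes <- vector("list", config@nSubjects)
  series <- vector("list", config@nSubjects)
  rhoTarget <- vector("list", config@nSubjects)
  basePos <- nodePositions(nodes)
  nd <- nodeData(nodes)
  for (s in seq_len(config@nSubjects)) {
    out <- withSeed(config@seed + 7000 + s, {
      pos <- basePos + matrix(stats::rnorm(3 * n, sd = config@positionJitterSd),
                              n, 3)
      D <- as.matrix(stats::dist(pos))
      R <- matrix(0, n, n)
      up <- upper.tri(R)
      R[up] <- rhoForTargetW(targetW(D[up], gt), calibration)
      R[unlinked & up] <- 0
      R <- R + t(R); diag(R) <- 1
      ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-8) {
        rep <- Matrix::nearPD(R, corr = TRUE, maxit = 200)
        if (!rep$converged)
          stop("nearest-correlation-matrix repair did not converge",
               call. = FALSE)
        R <- as.matrix(rep$mat)
      }
      E <- bandNoise(N, n, config@samplingPeriod, config@noiseBand)
      X <- E %*% chol(R)
      list(pos = pos, R = R, X = X)
    })
    ndS <- nd; ndS$x <- out$pos[, 1]; ndS$y <- out$pos[, 2]; ndS$z <- out$pos[, 3]
    subjectNodes[[s]] <- new("NodeTable", nodes = ndS)
    series[[s]] <- timeSeriesSet(out$X, config@samplingPeriod,
                                 subjectId = sprintf("S%03d", s),
                                 nodeIds = ids)
    rhoTarget[[s]] <- out$R
  }
  ages <- withSeed(config@seed + 499,
                   sample(18:88, config@nSubjects, replace = TRUE))
  list(nodes = nodes, subjectNodes = subjectNodes, series = series,
       groundTruth = gt, calibration = calibration, ages = ages,
       unlinked = unlinked, rhoTarget = rhoTarget)
}
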