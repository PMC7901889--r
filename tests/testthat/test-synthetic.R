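test_that("node placement respects spacing, span and determinism", {
  nt <- placeNodes(72, seed = 1)
  nd <- nodeData(nt)
  expect_equal(nrow(nd), 72L)
  expect_equal(sum(nd$hemisphere == "left"), 36L)
  D <- as.matrix(dist(nodePositions(nt)))
  dd <- D[upper.tri(D)]
  expect_gt(min(dd), 10)
  expect_lt(max(dd), 180)
  # generated geometries span a broad distance range
  expect_lt(min(dd), 15)
  expect_gt(max(dd), 150)
  # left nodes have negative x
  expect_true(all(sign(nd$x) == ifelse(nd$hemisphere == "left", -1, 1)))

  expect_identical(nodeData(placeNodes(72, seed = 1)), nd)
  expect_equal(nrow(nodeData(placeNodes(2, seed = 3))), 2L)
})

test_that("targetW is continuous, piecewise linear in ln d, and clipped", {
  gt <- groundTruth(slopes = c(7, 19, 7), breakpoints = c(44, 68.3),
                    intercept = 10, wRange = c(0.05, 100))
  # continuity at both breakpoints
  eps <- 1e-9
  expect_equal(targetW(44 - eps, gt), targetW(44 + eps, gt), tolerance = 1e-6)
  expect_equal(targetW(68.3 - eps, gt), targetW(68.3 + eps, gt),
               tolerance = 1e-6)
  # closed form: W(d23) = W(d12) + m2 ln(d23/d12)
  expect_equal(targetW(68.3, gt), 10 + 19 * log(68.3 / 44), tolerance = 1e-12)
  # slopes in ln d
  expect_equal((targetW(30, gt) - targetW(20, gt)) / log(30 / 20), 7,
               tolerance = 1e-9)
  expect_equal((targetW(150, gt) - targetW(100, gt)) / log(1.5), 7,
               tolerance = 1e-9)
  # clipping at the band edges
  gtc <- groundTruth(intercept = 12.5, wRange = c(2.5, 20))
  expect_equal(targetW(5, gtc), 2.5)
  expect_equal(targetW(175, gtc), 20)
  expect_error(targetW(-1, gtc), "positive")
})

test_that("ground-truth validity catches malformed parameter sets", {
  expect_error(groundTruth(breakpoints = c(70, 44)), "increasing")
  expect_error(groundTruth(unlinkedFraction = 1.5), "unlinkedFraction")
  expect_error(syntheticConfig(duration = 10), "duration")
})

test_that("calibration is monotone and brackets the Fisher-z prediction", {
  # white-noise config so the Fisher-z heuristic applies directly
  cfg <- syntheticConfig(nNodes = 2, nSubjects = 1, duration = 6,
                         noiseBand = c(0, 125), w0 = 0.04, M = 20,
                         nSurrogates = 49, surrogate = "ft", seed = 21)
  cal <- calibrateRhoToW(cfg, nReps = 20, rhoGrid = c(0.15, 0.3, 0.6, 0.9))
  W <- cal@WofRho
  expect_true(all(diff(W[is.finite(W)]) <= 1e-9))
  # rho = 0.3: Fisher-z predicts ((1.96/atanh .3)^2 + 3) * 0.004 ~ 0.17 s
  Wf <- ((qnorm(0.975) / atanh(0.3))^2 + 3) * 0.004
  expect_gt(W[2], Wf / 2)
  expect_lt(W[2], Wf * 2)
  # rho = 0.9: W collapses towards the smallest width
  expect_lte(W[4], 2 * cfg@w0)
  expect_error(calibrateRhoToW(cfg, nReps = 20, rhoGrid = c(0.5, 1.2)),
               "\\(0, 1\\)")
})

test_that("the calibration inverse is monotone and respects the curve", {
  cal <- new("CalibrationCurve", rhoGrid = c(0.05, 0.1, 0.2, 0.4),
             WofRho = c(20, 8, 3, 1), nReps = 20L, seed = 1L)
  expect_equal(rhoForTargetW(8, cal), 0.1)
  expect_equal(rhoForTargetW(c(3, 20), cal), c(0.2, 0.05))
  r <- rhoForTargetW(c(0.5, 1, 5, 25, 40), cal)
  expect_true(all(diff(r) < 0))
  expect_lt(r[4], 0.05)     # extrapolated beyond the largest finite W
  expect_gt(r[1], 0.4)
})

test_that("generated pairs realise the requested correlations", {
  gt2 <- groundTruth(slopes = c(0, 0, 0), breakpoints = c(44, 68.3),
                     intercept = 1, unlinkedFraction = 0, wRange = c(0.2, 30))
  cfg <- syntheticConfig(nNodes = 2, nSubjects = 2, duration = 20,
                         w0 = 0.1, M = 10, nSurrogates = 49, surrogate = "ft",
                         seed = 31, groundTruth = gt2)
  cal <- new("CalibrationCurve", rhoGrid = c(0.1, 0.3, 0.5, 0.8),
             WofRho = c(4, 1, 0.5, 0.1), nReps = 20L, seed = 1L)
  co <- generateCohort(cfg, calibration = cal)
  # target W = 1 everywhere -> rho = 0.3 for every pair
  X <- signalMatrix(co$series[[1]])
  expect_equal(cor(X[, 1], X[, 2]), 0.3, tolerance = 0.1)
  # determinism: identical config -> bit-identical cohorts
  co2 <- generateCohort(cfg, calibration = cal)
  expect_identical(signalMatrix(co2$series[[1]]), X)
  expect_identical(nodeData(co2$nodes), nodeData(co$nodes))
})

test_that("a fully unlinked cohort has near-zero pair correlations", {
  gt0 <- groundTruth(unlinkedFraction = 1)
  cfg <- syntheticConfig(nNodes = 6, nSubjects = 1, duration = 20,
                         w0 = 0.1, M = 10, nSurrogates = 49, surrogate = "ft",
                         seed = 33, groundTruth = gt0)
  cal <- new("CalibrationCurve", rhoGrid = c(0.1, 0.5),
             WofRho = c(4, 0.5), nReps = 20L, seed = 1L)
  co <- generateCohort(cfg, calibration = cal)
  C <- cor(signalMatrix(co$series[[1]]))
  off <- abs(C[upper.tri(C)])
  # 3/sqrt(N) with N reduced by the band-limitation oversampling
  expect_lt(max(off), 3 / sqrt(nrow(signalMatrix(co$series[[1]])) / 4))
})

test_that("band-limited noise is standardized and within band", {
  set.seed(9)
  w <- netobs:::bandNoise(4096, 2, 0.004, c(0.5, 45))
  expect_equal(apply(w, 2, sd), c(1, 1), tolerance = 1e-9)
  s <- Mod(fft(w[, 1]))^2
  fr <- (seq_along(s) - 1) / (length(s) * 0.004)
  half <- fr > 0 & fr < 125
  expect_gt(sum(s[half & fr > 0.4 & fr < 46]) / sum(s[half]), 0.95)
})
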