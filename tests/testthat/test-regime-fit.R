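test_that("line fits are exact on exact data and match the normal equations", {
  f <- fitLine(1:10, 2 * (1:10) + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$sigma, 0, tolerance = 1e-10)

  f2 <- fitLine(c(0, 4), c(1, 9))
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 1)

  # heteroscedastic WLS against an explicit normal-equations solve
  set.seed(1)
  x <- runif(40, 0, 10)
  w <- runif(40, 0.2, 5)
  y <- 3 - 0.7 * x + rnorm(40, sd = 1 / sqrt(w))
  f3 <- fitLine(x, y, weights = w)
  A <- cbind(1, x)
  beta <- solve(t(A) %*% (w * A), t(A) %*% (w * y))
  expect_equal(unname(c(f3$intercept, f3$slope)), unname(beta[, 1]),
               tolerance = 1e-10)

  expect_error(fitLine(rep(2, 5), 1:5), "degenerate")
})

test_that("line intersections and their propagated uncertainty are correct", {
  l1 <- list(slope = 1, intercept = 0, cov = matrix(0, 2, 2))
  l2 <- list(slope = -1, intercept = 2, cov = matrix(0, 2, 2))
  i <- intersectLines(l1, l2)
  expect_equal(i$x, 1)
  expect_equal(i$se, 0)
  expect_error(intersectLines(l1, l1), "parallel")

  # uncertainty: var only on b2 -> se(x*) = se(b2) / |m1 - m2|
  l2b <- list(slope = -1, intercept = 2, cov = diag(c(0.04, 0)))
  expect_equal(intersectLines(l1, l2b)$se, 0.2 / 2)

  # lines through noiseless piecewise segments intersect at the breakpoint
  gt <- groundTruth(slopes = c(7, 19, 7), breakpoints = c(44, 68.3),
                    intercept = 10, wRange = c(1e-3, 1e3))
  d1 <- seq(20, 43, 2); d2 <- seq(45, 67, 2)
  f1 <- fitLine(log(d1), targetW(d1, gt))
  f2 <- fitLine(log(d2), targetW(d2, gt))
  expect_equal(intersectLines(f1, f2)$x, log(44), tolerance = 1e-10)
})

test_that("the two-step fit recovers a noiseless three-regime curve", {
  gt <- groundTruth(slopes = c(7, 19, 7), breakpoints = c(44, 68.3),
                    intercept = 12.5, wRange = c(0.01, 100))
  curve <- noiselessCurve(gt)
  # default init (44, 68): exact recovery
  f <- twoStepPiecewiseFit(curve, 44, 68)
  expect_equal(f@slopes, c(7, 19, 7), tolerance = 1e-9)
  expect_equal(f@breakpoints, c(44, 68.3), tolerance = 1e-9)
  # init at the true breaks: step 2 equals step 1 (fixed point)
  ft <- twoStepPiecewiseFit(curve, 44, 68.3)
  expect_equal(ft@step1$slopes, ft@slopes, tolerance = 1e-9)
  expect_equal(ft@step1$breakpoints, ft@breakpoints, tolerance = 1e-9)
  # a farther init contaminates the middle segment; recovery stays within
  # a few percent (exact two-step procedure, no iteration)
  f2 <- twoStepPiecewiseFit(curve, 40, 75)
  expect_lt(max(abs(f2@slopes - c(7, 19, 7)) / c(7, 19, 7)), 0.025)
  expect_lt(max(abs(f2@breakpoints - c(44, 68.3)) / c(44, 68.3)), 0.01)
  # iterate-to-convergence polishes that away
  f3 <- twoStepPiecewiseFit(curve, 40, 75, iterate = TRUE)
  expect_equal(f3@breakpoints, c(44, 68.3), tolerance = 1e-6)
})

test_that("refitting from the final breakpoints is a fixed point within noise", {
  set.seed(2)
  gt <- groundTruth(slopes = c(7, 19, 7), breakpoints = c(44, 68.3),
                    intercept = 12.5, wRange = c(0.01, 100))
  curve <- noiselessCurve(gt)
  curve$wbar <- curve$wbar + rnorm(nrow(curve), sd = 0.3)
  curve$sd <- 0.3 * sqrt(curve$n)
  f1 <- twoStepPiecewiseFit(curve, 44, 68)
  f2 <- twoStepPiecewiseFit(curve, f1@breakpoints[1], f1@breakpoints[2])
  expect_lt(max(abs(f2@slopes - f1@slopes) / pmax(f1@slopeSE, 1e-9)), 1)
})

test_that("degenerate single-slope input cannot produce ordered breakpoints", {
  d <- exp(seq(log(10), log(175), length.out = 40))
  curve <- data.frame(x = log(d), wbar = 2 + 5 * log(d), sd = 0, n = 10L)
  expect_error(twoStepPiecewiseFit(curve, 44, 68), "parallel|ordered|outside")
})

test_that("power-law fits recover exponent and amplitude", {
  d <- exp(seq(log(70), log(175), length.out = 25))
  W <- 20.9 * (d / 75)^0.44
  pl <- fitPowerLaw(d, W)
  expect_equal(pl@gamma, 0.44, tolerance = 1e-10)
  expect_equal(pl@W0, 20.9, tolerance = 1e-8)
  # constant W -> zero exponent
  expect_equal(fitPowerLaw(d, rep(5, 25))@gamma, 0, tolerance = 1e-12)
  # doubling d0 rescales W0 by 2^gamma and leaves gamma unchanged
  pl2 <- fitPowerLaw(d, W, d0 = 150)
  expect_equal(pl2@gamma, pl@gamma, tolerance = 1e-10)
  expect_equal(pl2@W0, pl@W0 * 2^0.44, tolerance = 1e-6)
  expect_error(fitPowerLaw(d[1:2], W[1:2]), "at least 3")
})

test_that("bootstrap breakpoint uncertainties are finite and modest on clean data", {
  set.seed(3)
  gt <- groundTruth(slopes = c(7, 19, 7), breakpoints = c(44, 68.3),
                    intercept = 12.5, wRange = c(0.01, 100))
  curve <- noiselessCurve(gt)
  curve$wbar <- curve$wbar + rnorm(nrow(curve), sd = 0.2)
  se <- bootstrapBreakpointSE(curve, 44, 68, B = 40, seed = 4)
  expect_true(all(is.finite(se)))
  expect_lt(se[1], 10)
})
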