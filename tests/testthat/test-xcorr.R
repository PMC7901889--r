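test_that("window grid follows the center/width rules", {
  # 240 s at 250 Hz, w0 = 0.2 s, M = 150: widths 0.2-30 s, centers 15-225 s
  g <- buildWindowGrid(60000, 0.004, w0 = 0.2, M = 150)
  expect_equal(widths(g), 0.2 * (1:150))
  expect_equal(g@lens[1], 50L)              # 50 samples in the 0.2 s window
  expect_equal(centers(g)[1], 15)
  expect_equal(centers(g)[length(centers(g))], 225)
  expect_length(centers(g), 1051L)
  # every window fits inside the recording
  expect_true(all(g@starts >= 0))
  expect_true(all(sweep(g@starts, 2, g@lens, "+") <= 60000))

  # M = 1: centers step w0 from w0/2
  g1 <- buildWindowGrid(1000, 0.004, w0 = 0.2, M = 1)
  expect_equal(centers(g1)[1:3], c(0.1, 0.3, 0.5))

  # N*T = M*w0 exactly: a single center at the midpoint
  g2 <- buildWindowGrid(500, 0.004, w0 = 0.2, M = 10)
  expect_length(centers(g2), 1L)
  expect_equal(centers(g2), 1)

  expect_error(buildWindowGrid(400, 0.004, w0 = 0.2, M = 10), "too short")
  expect_error(buildWindowGrid(1000, 0.004, w0 = 0.3141, M = 10), "multiple")
})

test_that("windowed Pearson agrees with a naive per-window loop", {
  set.seed(11)
  n <- 2500
  g <- buildWindowGrid(n, 0.004, w0 = 0.2, M = 10)
  for (i in 1:3) {
    x <- cumsum(rnorm(n)); y <- 0.3 * x + rnorm(n)
    r <- values(windowedPearson(x, y, g))
    expect_equal(r, naiveDiagram(x, y, g), tolerance = 1e-12)
  }
})

test_that("perfectly dependent and constant windows behave as documented", {
  set.seed(2)
  x <- rnorm(600)
  g <- buildWindowGrid(600, 0.004, w0 = 0.2, M = 4)
  expect_true(all(values(windowedPearson(x, x, g)) == 1))
  r <- values(windowedPearson(x, -2 * x + 3, g))
  expect_equal(max(abs(r + 1)), 0, tolerance = 1e-12)
  # a constant stretch makes the affected cells NA
  xc <- x; xc[1:200] <- 5
  rc <- values(windowedPearson(xc, x, g))
  expect_true(anyNA(rc[1, ]))
  expect_true(all(is.finite(rc[nrow(rc), ])))
  # hand-computed 4-point example
  g4 <- buildWindowGrid(4, 1, w0 = 4, M = 1)
  expect_equal(values(windowedPearson(c(1, 2, 3, 4), c(1, 3, 2, 4), g4))[1, 1],
               0.8)
})

test_that("surrogates preserve spectrum (ft) and amplitudes (iaaft)", {
  set.seed(3)
  x <- as.numeric(arima.sim(list(ar = 0.9), 512))
  s <- makeSurrogate(x, seed = 5, method = "ft")
  expect_equal(Mod(fft(s)), Mod(fft(x)), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(s, x)))

  si <- makeSurrogate(x, seed = 5, method = "iaaft")
  expect_equal(sort(si), sort(x))
  # iaaft keeps the spectrum to good approximation as well
  px <- Mod(fft(x))[2:40]; ps <- Mod(fft(si))[2:40]
  expect_gt(cor(px, ps), 0.95)

  sa <- makeSurrogate(x, seed = 5, method = "aaft")
  expect_equal(sort(sa), sort(x))

  # determinism
  expect_identical(makeSurrogate(x, seed = 9), makeSurrogate(x, seed = 9))
})

test_that("surrogates are uncorrelated with the original on average", {
  set.seed(4)
  x <- as.numeric(arima.sim(list(ar = 0.8), 512))
  r <- vapply(1:100, function(s) cor(x, makeSurrogate(x, seed = s,
                                                      method = "ft")),
              numeric(1))
  expect_lt(abs(mean(r)), 0.05)
})

test_that("p-value diagrams attain the discrete bound and flag dependence", {
  set.seed(5)
  # identical strongly autocorrelated series: no surrogate beats |r| = 1
  x <- as.numeric(arima.sim(list(ar = 0.95), 1200))
  g <- buildWindowGrid(1200, 0.004, w0 = 0.2, M = 5)
  p <- pvalueDiagram(x, x, g, nSurrogates = 200, method = "ft", seed = 1)
  expect_true(all(values(p) == 1 / 201))
  # n = 19 surrogates -> minimum achievable p is 0.05
  p19 <- pvalueDiagram(x, x, g, nSurrogates = 19, method = "ft", seed = 1)
  expect_equal(min(values(p19)), 0.05)
})

test_that("p values are near-uniform for independent noise", {
  # mean p ~ 0.5; averaged over pairs because cells within a pair share
  # the two underlying series
  mp <- vapply(1:4, function(s) {
    set.seed(s)
    x <- rnorm(6000); y <- rnorm(6000)
    g <- buildWindowGrid(6000, 0.004, w0 = 0.2, M = 12)
    mean(values(pvalueDiagram(x, y, g, nSurrogates = 99, method = "ft",
                              seed = 40 + s)), na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(mp) - 0.5), 0.05)
})

test_that("efficiency counts significant windows and W is the first crossing", {
  g <- buildWindowGrid(1000, 0.004, w0 = 0.2, M = 5)
  K <- length(centers(g))
  mk <- function(vals) new("PValueDiagram",
                           values = matrix(vals, K, 5, byrow = TRUE),
                           centers = centers(g), widths = widths(g),
                           nSurrogates = 200L, surrogateMethod = "ft")
  expect_equal(values(efficiency(mk(rep(1 / 201, 5)))), rep(1, 5))
  expect_equal(values(efficiency(mk(rep(1, 5)))), rep(0, 5))

  # counting: 526 of 1051 centers significant -> eta = 0.50047...
  p <- matrix(1, 1051, 1); p[1:526, 1] <- 0.01
  eta <- new("EfficiencyCurve", eta = colMeans(p < 0.05), widths = 15,
             alpha = 0.05)
  expect_equal(values(eta), 526 / 1051)

  # first strict crossing of 0.5; exact ties do not qualify
  eta2 <- new("EfficiencyCurve", eta = c(0.2, 0.5, 0.6, 0.9),
              widths = c(5, 10, 15, 20), alpha = 0.05)
  expect_equal(observabilityTimescale(eta2), 15)
  expect_equal(observabilityTimescale(eta2, strict = FALSE), 10)
  eta3 <- new("EfficiencyCurve", eta = rep(0.4, 4),
              widths = c(5, 10, 15, 20), alpha = 0.05)
  expect_true(is.na(observabilityTimescale(eta3)))
  eta4 <- new("EfficiencyCurve", eta = rep(1, 4), widths = c(5, 10, 15, 20),
              alpha = 0.05)
  expect_equal(observabilityTimescale(eta4), 5)
})

test_that("W is invariant under affine rescaling of either series", {
  set.seed(6)
  n <- 3000
  z <- as.numeric(arima.sim(list(ar = 0.7), n))
  x <- z + rnorm(n); y <- z + rnorm(n)
  g <- buildWindowGrid(n, 0.004, w0 = 0.2, M = 8)
  W1 <- observabilityTimescale(efficiency(
    pvalueDiagram(x, y, g, 49, "ft", seed = 3)))
  W2 <- observabilityTimescale(efficiency(
    pvalueDiagram(5 * x + 2, -0.3 * y + 1, g, 49, "ft", seed = 3)))
  expect_equal(W1, W2)
})

test_that("assessLinks is symmetric in node order and handles identical columns", {
  set.seed(7)
  n <- 600
  X <- matrix(rnorm(n * 3), n, 3)
  X[, 3] <- X[, 1]                       # identical pair -> W = w0
  nt <- nodeTable(c("a", "b", "c"), c("A", "B", "C"),
                  c("left", "left", "right"),
                  x = c(-30, -10, 25), y = c(0, 40, -20), z = c(0, 10, 5))
  ts1 <- timeSeriesSet(X, 0.004, "S1", nodeIds = c("a", "b", "c"))
  ts2 <- timeSeriesSet(X[, 3:1], 0.004, "S1", nodeIds = c("c", "b", "a"))
  # note: 19 surrogates give min p = 0.05, which never beats the strict
  # p < 0.05 rule; detection needs at least 20
  args <- list(nodes = nt, w0 = 0.2, M = 3, nSurrogates = 39,
               surrogate = "ft", seed = 5)
  l1 <- linkData(do.call(assessLinks, c(list(ts1), args)))
  l2 <- linkData(do.call(assessLinks, c(list(ts2), args)))
  expect_equal(l1, l2)
  expect_equal(nrow(l1), 3L)
  expect_equal(l1$W_s[l1$node_a == "a" & l1$node_b == "c"], 0.2)
  expect_equal(sort(unique(l1$hemisphere_pair)), c("LL", "LR"))
  expect_equal(l1$d_mm[l1$node_a == "a" & l1$node_b == "b"],
               sqrt(20^2 + 40^2 + 10^2))
})
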