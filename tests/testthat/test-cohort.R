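test_that("subject summaries compute the link ratio R", {
  df <- makeLinkDf(d = runif(2556, 10, 170),
                   W = c(runif(1022, 1, 25), rep(NA, 2556 - 1022)))
  s <- subjectSummary(linkTable(df), age = 30)
  expect_equal(s$R, 1022 / 2556)
  expect_equal(s$n_pairs, 2556L)
  expect_equal(s$n_links, 1022L)

  none <- makeLinkDf(d = runif(10, 10, 50), W = rep(NA_real_, 10))
  s0 <- subjectSummary(linkTable(none))
  expect_equal(s0$R, 0)
  expect_true(is.na(s0$mean_W))

  all <- makeLinkDf(d = runif(10, 10, 50), W = runif(10, 1, 5))
  expect_equal(subjectSummary(linkTable(all))$R, 1)
  expect_error(subjectSummary(linkTable(all[0, ])), "zero pairs")
})

test_that("decade summaries partition ages and build the grand-mean band", {
  sm <- data.frame(subject_id = paste0("S", 1:14),
                   age = c(20, 25, 30, 39, 45, 50, 60, 62, 70, 75, 80, 85, 18, 88),
                   R = 0.4)
  ds <- decadeSummaries(sm)
  expect_equal(nrow(ds$decades), 7L)
  expect_equal(sum(ds$decades$n), 14L)
  expect_true(all(ds$decades$meanR == 0.4))
  expect_equal(ds$grand$mean, 0.4)
  expect_equal(diff(ds$grand$band), 0)

  # one subject per decade: decade mean equals that subject's R
  sm2 <- data.frame(subject_id = paste0("S", 1:7),
                    age = c(20, 30, 40, 50, 60, 70, 80),
                    R = seq(0.1, 0.7, 0.1))
  ds2 <- decadeSummaries(sm2)
  expect_equal(ds2$decades$meanR, seq(0.1, 0.7, 0.1))
  expect_equal(ds2$decades$n, rep(1L, 7))

  # empty decades are reported absent, not an error
  sm3 <- data.frame(subject_id = "S1", age = 20, R = 0.5)
  ds3 <- decadeSummaries(sm3)
  expect_equal(ds3$decades$n[1], 1L)
  expect_true(all(ds3$decades$n[-1] == 0L))
  expect_error(decadeSummaries(data.frame(subject_id = "a", age = 10, R = 1)),
               "18, 88")
})

test_that("age-independent cohorts keep decade means inside the 2-sigma band", {
  set.seed(8)
  inside <- vapply(1:40, function(i) {
    sm <- data.frame(subject_id = paste0("S", 1:70),
                     age = rep(c(20, 30, 40, 50, 60, 70, 80), each = 10),
                     R = rnorm(70, 0.4, 0.05))
    ds <- decadeSummaries(sm)
    all(ds$decades$meanR >= ds$grand$band[1] &
        ds$decades$meanR <= ds$grand$band[2])
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("hemisphere partition is exhaustive and disjoint", {
  df <- makeLinkDf(d = c(10, 20, 30), W = c(1, 2, NA),
                   hemi = c("LL", "LR", "LL"))
  pt <- hemispherePartition(linkTable(df))
  expect_equal(nrow(linkData(pt$LL)), 2L)
  expect_equal(nrow(linkData(pt$LR)), 1L)
  expect_equal(nrow(linkData(pt$RR)), 0L)

  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    df <- makeLinkDf(runif(n, 10, 170), runif(n, 1, 25),
                     hemi = sample(c("LL", "LR", "RR"), n, replace = TRUE))
    pt <- hemispherePartition(linkTable(df))
    sizes <- vapply(pt, function(p) nrow(linkData(p)), integer(1))
    expect_equal(sum(sizes), n)        # exhaustive
    merged <- do.call(rbind, lapply(pt, linkData))
    expect_false(any(duplicated(merged[, c("node_a", "node_b")])))  # disjoint
    expect_setequal(paste(merged$node_a, merged$node_b),
                    paste(df$node_a, df$node_b))
  }
})

test_that("fully linked three-node example partitions as expected", {
  df <- data.frame(subject_id = "S1",
                   node_a = c("L1", "L1", "L2"),
                   node_b = c("L2", "R1", "R1"),
                   hemisphere_pair = c("LL", "LR", "LR"),
                   d_mm = c(10, 20, 30), W_s = c(1, 2, 3))
  pt <- hemispherePartition(linkTable(df))
  expect_equal(linkData(pt$LL)$node_b, "L2")
  expect_equal(nrow(linkData(pt$LR)), 2L)
  expect_equal(nrow(linkData(pt$RR)), 0L)
})

test_that("control-set comparison rejects overlapping node sets", {
  nt <- placeNodes(6, seed = 1)
  nd <- nodeData(nt)
  a <- new("NodeTable", nodes = nd[1:3, ])
  b <- new("NodeTable", nodes = nd[3:6, ])
  expect_error(controlSetComparison(list(), a, b), "overlap")
})

test_that("node sets generated under different laws are mostly rejected", {
  mkCohort <- function(gt, seed, prefix) {
    cfg <- syntheticConfig(nNodes = 12, nSubjects = 3, duration = 40,
                           w0 = 0.3, M = 25, nSurrogates = 50,
                           surrogate = "ft", seed = seed, groundTruth = gt)
    cal <- new("CalibrationCurve", rhoGrid = c(0.05, 0.1, 0.2, 0.4, 0.7),
               WofRho = c(6, 3, 1.4, 0.6, 0.2), nReps = 20L, seed = 1L)
    co <- generateCohort(cfg, calibration = cal)
    co$rename <- function(nt) {
      nd <- nodeData(nt); nd$node_id <- paste0(prefix, nd$node_id)
      new("NodeTable", nodes = nd)
    }
    co
  }
  # strongly linked short-time-scale law vs almost fully unlinked law
  coA <- mkCohort(groundTruth(slopes = c(0.5, 1.5, 0.5),
                              breakpoints = c(44, 68.3), intercept = 1,
                              unlinkedFraction = 0, wRange = c(0.2, 5)),
                  seed = 51, prefix = "A")
  coB <- mkCohort(groundTruth(slopes = c(0.5, 1.5, 0.5),
                              breakpoints = c(44, 68.3), intercept = 2.5,
                              unlinkedFraction = 0.3, wRange = c(0.2, 5)),
                  seed = 52, prefix = "B")
  ndA <- coA$rename(coA$nodes); ndB <- coB$rename(coB$nodes)
  series <- lapply(1:3, function(s) {
    XA <- signalMatrix(coA$series[[s]]); XB <- signalMatrix(coB$series[[s]])
    timeSeriesSet(cbind(XA, XB), 0.004, sprintf("S%d", s),
                  nodeIds = c(nodeIds(ndA), nodeIds(ndB)))
  })
  ctl <- controlSetComparison(series, ndA, ndB, ksMethod = "asymptotic",
                              alpha = 0.05, w0 = 0.3, M = 25,
                              nSurrogates = 50, surrogate = "ft", seed = 2)
  expect_gte(sum(ctl$reject), 2L)     # majority of subjects reject
})

test_that("the pipeline is deterministic and reports per-hemisphere fit blocks", {
  gt <- groundTruth(slopes = c(1, 2.5, 1), breakpoints = c(44, 68.3),
                    intercept = 2, unlinkedFraction = 0.3,
                    wRange = c(0.1, 5))
  cfg <- syntheticConfig(nNodes = 8, nSubjects = 2, duration = 30,
                         w0 = 0.1, M = 10, nSurrogates = 39,
                         surrogate = "ft", seed = 11, groundTruth = gt)
  cal <- new("CalibrationCurve", rhoGrid = c(0.05, 0.1, 0.2, 0.4, 0.7),
             WofRho = c(5, 2.5, 1.2, 0.5, 0.15), nReps = 20L, seed = 1L)
  res1 <- runPipeline(list(synthetic = cfg, calibration = cal, bins = 6))
  res2 <- runPipeline(list(synthetic = cfg, calibration = cal, bins = 6))
  expect_identical(linkData(res1$links), linkData(res2$links))
  expect_named(res1$fits, c("All", "LL", "LR", "RR"))
  expect_equal(nrow(res1$perSubject), 2L)
  expect_equal(nrow(linkData(res1$links)), 2 * choose(8, 2))

  # configuration errors surface before any computation
  expect_error(runPipeline(list(seriesFiles = "x.tsv",
                                samplingPeriod = 0.004)),
               "nodeFile|configuration|name")
})
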