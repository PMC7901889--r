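# shared fixtures, all generated in code

# small white-noise pair as a TimeSeriesSet
makeNoiseSet <- function(n = 1000, k = 2, T = 0.004, seed = 1,
                         subject = "S1") {
  set.seed(seed)
  timeSeriesSet(matrix(rnorm(n * k), n, k), samplingPeriod = T,
                subjectId = subject)
}

# naive per-window Pearson loop: the oracle for the prefix-sum diagram
naiveDiagram <- function(x, y, grid) {
  K <- length(grid@centers); M <- grid@M
  out <- matrix(NA_real_, K, M)
  for (m in seq_len(M)) for (k in seq_len(K)) {
    s0 <- grid@starts[k, m] + 1L
    xi <- x[s0:(s0 + grid@lens[m] - 1L)]
    yi <- y[s0:(s0 + grid@lens[m] - 1L)]
    if (stats::sd(xi) > 0 && stats::sd(yi) > 0)
      out[k, m] <- stats::cor(xi, yi)
  }
  out
}

# brute-force Fasano-Franceschini statistic: the oracle for the C++ scan
bruteKS2D <- function(a, b) {
  quad <- function(o, s) {
    dx <- s[, 1] - o[1]; dy <- s[, 2] - o[2]
    c(mean(dx > 0 & dy > 0), mean(dx < 0 & dy > 0),
      mean(dx < 0 & dy < 0), mean(dx > 0 & dy < 0))
  }
  maxOver <- function(origins) {
    mx <- 0
    for (i in seq_len(nrow(origins))) {
      d <- max(abs(quad(origins[i, ], a) - quad(origins[i, ], b)))
      if (d > mx) mx <- d
    }
    mx
  }
  (maxOver(a) + maxOver(b)) / 2
}

# synthetic link table with arbitrary columns filled in
makeLinkDf <- function(d, W, subject = "S1", hemi = NULL) {
  n <- length(d)
  if (is.null(hemi)) hemi <- rep("LL", n)
  data.frame(subject_id = rep(subject, n),
             node_a = sprintf("a%04d", seq_len(n)),
             node_b = sprintf("b%04d", seq_len(n)),
             hemisphere_pair = hemi, d_mm = d, W_s = W)
}

# noiseless three-regime conditional curve sampled on a log-distance grid
noiselessCurve <- function(gt, dMin = 10, dMax = 175, nBins = 50) {
  d <- exp(seq(log(dMin), log(dMax), length.out = nBins))
  data.frame(x = log(d), wbar = targetW(d, gt), sd = 0, n = 100L)
}
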