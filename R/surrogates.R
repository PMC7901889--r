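## Surrogate-data generation (Schreiber-Schmitz family).
## "ft" preserves the amplitude spectrum via phase randomization; "aaft"
## additionally matches the amplitude distribution through rank mapping of a
## phase-randomized gaussianized copy; "iaaft" iterates spectrum and
## amplitude adjustment until the rank ordering stabilises.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## random-phase spectra for n replicates; returns N x n real matrix
ftSurrogateMatrix <- function(x, n) {
  N <- length(x)
  Xf <- stats::fft(x)
  amp <- Mod(Xf)
  even <- N %% 2L == 0L
  nfree <- if (even) N %/% 2L - 1L else (N - 1L) %/% 2L
  S <- matrix(complex(real = 0, imaginary = 0), N, n)
  S[1, ] <- Xf[1]                                   # keep the mean
  if (nfree > 0) {
    free <- 2:(1 + nfree)
    phi <- matrix(stats::runif(nfree * n, 0, 2 * pi), nfree, n)
    S[free, ] <- amp[free] * exp(1i * phi)
    S[N + 2L - free, ] <- Conj(S[free, , drop = FALSE])
  }
  if (even) {
    nyq <- N %/% 2L + 1L
    sgn <- ifelse(stats::runif(n) < 0.5, -1, 1)
    S[nyq, ] <- amp[nyq] * sgn
  }
  Re(stats::mvfft(S, inverse = TRUE)) / N
}

aaftSurrogateMatrix <- function(x, n) {
  N <- length(x)
  sx <- sort(x)
  rx <- rank(x, ties.method = "first")
  out <- matrix(0, N, n)
  for (j in seq_len(n)) {
    g <- sort(stats::rnorm(N))[rx]                  # gaussianized copy of x
    gs <- ftSurrogateMatrix(g, 1L)[, 1]
    out[, j] <- sx[rank(gs, ties.method = "first")]
  }
  out
}

iaaftSurrogateMatrix <- function(x, n, maxit = 100L) {
  N <- length(x)
  amp <- Mod(stats::fft(x))
  sx <- sort(x)
  out <- matrix(0, N, n)
  for (j in seq_len(n)) {
    s <- sx[sample.int(N)]
    rprev <- integer(0)
    for (it in seq_len(maxit)) {
      sp <- stats::fft(s)
      s2 <- Re(stats::fft(amp * exp(1i * Arg(sp)), inverse = TRUE)) / N
      r <- rank(s2, ties.method = "first")
      s <- sx[r]
      if (identical(r, rprev)) break
      rprev <- r
    }
    out[, j] <- s
  }
  out
}

surrogateMatrix <- function(x, n, method = c("iaaft", "aaft", "ft"), seed) {
  method <- match.arg(method)
  withSeed(seed, switch(method,
    ft = ftSurrogateMatrix(x, n),
    aaft = aaftSurrogateMatrix(x, n),
    iaaft = iaaftSurrogateMatrix(x, n)))
}

#' Generate a surrogate series
#'
#' Builds one surrogate of `x` under the null hypothesis of a linear
#' stochastic process: `"ft"` (phase randomization) preserves the amplitude
#' spectrum; `"aaft"` and `"iaaft"` additionally preserve the marginal
#' amplitude distribution, with `"iaaft"` iterating both constraints.
#' Deterministic given `seed`.
#'
#' @param x numeric series (length >= 4).
#' @param seed integer seed.
#' @param method `"ft"`, `"aaft"` or `"iaaft"` (default).
#' @return numeric vector of `length(x)`.
#' @examples
#' s <- makeSurrogate(sin(1:100 / 5) + rnorm(100, sd = .1), seed = 1)
#' @export
makeSurrogate <- function(x, seed, method = c("iaaft", "aaft", "ft")) {
  if (length(x) < 4L) stop("series too short for surrogate generation",
                           call. = FALSE)
  method <- match.arg(method)
  surrogateMatrix(x, 1L, method, seed)[, 1]
}
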