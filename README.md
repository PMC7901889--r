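# netobs — time scales of cross-correlation observability in functional networks

`netobs` estimates functional links between node-level time series — e.g.
source-reconstructed MEG activity at selected cortical nodes — and
characterises how connectivity depends on the geometric distance between
nodes.  It is aimed at researchers analysing multichannel resting-state
recordings who want a connectivity measure that spans time scales from
fractions of a second to tens of seconds, together with the statistics to
relate it to network geometry.

## The method

For a pair of signals, the sample Pearson coefficient `r(k, w)` is evaluated
on a multiscale grid of moving windows (widths `w = m·w0`, `m = 1…M`, shared
centers stepping by `w0`).  Cell-wise significance comes from surrogate
data: both series are replaced by spectrum-preserving surrogates
(FT/AAFT/IAAFT), the diagram is recomputed, and
`p(k, w) = (g + 1)/(n_surr + 1)` counts the replicates whose `|r|` reaches
the observed one.  The *efficiency* `η(w)` is the fraction of windows of
width `w` with `p < 0.05`.  A link exists when `η(w)` exceeds 0.5 — the
majority of windows see the correlation — and the smallest such width is the
**time scale of observability** `W`; its reciprocal acts as a connectivity
strength.  Identical signals give `W = w0`; independent signals give no
link.

Per subject, all `N(N−1)/2` node pairs yield records `(d, W)` with `d` the
Euclidean inter-node distance (mm).  Pooled records are binned into the
joint distribution `f(d, W)`, its marginals, and the conditional
`f(W | log d)`; the conditional mean `W̄(log d) = Σ_W W·f(W | log d)` is
fitted by **three straight lines in `ln d`** via a two-step breakpoint
procedure (fit on initial ranges → replace breakpoints by the line
intersections → refit), giving slopes `m1, m2, m3` (s per unit `ln d`) and
breakpoints `d12, d23` (mm), overall and within hemisphere subsets (LL, LR,
RR).  A power law `W = W0 (d/d0)^γ` is fitted to the third regime for
comparison.  A two-sample two-dimensional Kolmogorov–Smirnov test
(Fasano–Franceschini) with Bonferroni correction across subjects checks
that results do not depend on the particular node set.

A synthetic-cohort generator produces band-limited Gaussian signals whose
pairwise correlations follow a known piecewise-linear `W(ln d)` ground
truth through an empirical `ρ → W` calibration of the estimator itself, so
the whole pipeline is testable without access to restricted recordings.

## A worked example

```r
library(netobs)
gt  <- groundTruth(intercept = 12.0)      # slopes 7.0/19.1/6.7 s, breaks 44/68.3 mm
cfg <- syntheticConfig(nNodes = 24, nSubjects = 2, duration = 180,
                       w0 = 0.72, M = 50, nSurrogates = 50,
                       surrogate = "ft", seed = 7, groundTruth = gt)
res <- runPipeline(list(synthetic = cfg, bins = 30,
                        initD12 = 44, initD23 = 68))
res$fits$All
res$perSubject[, c("subject_id", "R", "mean_W", "n_links", "n_pairs")]
```

```
Three-regime piecewise-linear fit of Wbar vs ln d
  m1 =  3.219 +/- 2.670 s
  m2 = 26.128 +/- 2.453 s
  m3 = 13.328 +/- 3.797 s
  d12 = 42.12 +/- 2.07 mm, d23 = 62.62 +/- 7.98 mm
  subject_id         R   mean_W n_links n_pairs
1       S001 0.3333333 19.87043      92     276
2       S002 0.3550725 20.62286      98     276
```

The breakpoints land near the generating 44 and 68.3 mm, and the
per-subject link ratio `R ≈ 0.34` reflects the generator's 60% unlinked
pairs with near-complete detection of the rest; with only 24 nodes and two
subjects the outer slopes carry large uncertainties (the generating law is
7.0, 19.1, 6.7 s).  The 72-node, 5-subject run performed by
`scripts/acceptance.R` (seed 1) recovers slopes 6.80, 22.63, 6.77 s and
breakpoints 43.8, 68.2 mm.

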