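## Cohort-level orchestration: per-subject link ratio, age-decade summaries,
## hemisphere partitioning, control-node-set comparison, pipeline driver.

#' Per-subject link summary
#'
#' `R` is the fraction of node pairs with a detected link out of all
#' `N(N-1)/2` pairs; `mean_W` the mean finite time scale.
#'
#' @param links a [LinkTable-class] (single subject).
#' @param age subject age in years.
#' @param subjectIdLabel optional override of the subject id.
#' @return data.frame with one row: `subject_id`, `age`, `R`, `mean_W`,
#'   `n_links`, `n_pairs`.
#' @export
subjectSummary <- function(links, age = NA_real_, subjectIdLabel = NULL) {
  lk <- linkData(links)
  if (!nrow(lk)) stop("link table has zero pairs", call. = FALSE)
  sid <- if (!is.null(subjectIdLabel)) subjectIdLabel else lk$subject_id[1]
  nL <- sum(is.finite(lk$W_s))
  data.frame(subject_id = sid, age = age, R = nL / nrow(lk),
             mean_W = if (nL) mean(lk$W_s[is.finite(lk$W_s)]) else NA_real_,
             n_links = nL, n_pairs = nrow(lk))
}

#' Age-decade summaries of the link ratio
#'
#' Subjects are grouped into decades 18-27, 28-37, ..., 78-88 and the mean
#' `R` with its standard error is reported per decade; the grand mean of the
#' per-decade means is returned with a 2-sigma band (sigma = standard
#' deviation of the decade means).
#'
#' @param summaries data.frame of [subjectSummary()] rows with finite ages
#'   in `[18, 88]`.
#' @return list with `decades` (data.frame: `decade`, `meanR`, `se`, `n`;
#'   empty decades have `n = 0` and `NA` mean) and `grand` (list `mean`,
#'   `sigma`, `band`).
#' @export
decadeSummaries <- function(summaries) {
  if (any(!is.finite(summaries$age) | summaries$age < 18 | summaries$age > 88))
    stop("ages must lie within [18, 88]", call. = FALSE)
  lower <- seq(18, 78, by = 10)
  upper <- pmin(lower + 9, 88)
  lab <- sprintf("%d-%d", lower, upper)
  idx <- findInterval(summaries$age, c(lower, 89))
  dec <- data.frame(decade = lab, meanR = NA_real_, se = NA_real_, n = 0L)
  for (g in seq_along(lower)) {
    r <- summaries$R[idx == g]
    dec$n[g] <- length(r)
    if (length(r)) {
      dec$meanR[g] <- mean(r)
      dec$se[g] <- if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_
    }
  }
  m <- dec$meanR[dec$n > 0]
  grand <- list(mean = mean(m),
                sigma = if (length(m) > 1) stats::sd(m) else 0)
  grand$band <- grand$mean + c(-2, 2) * grand$sigma
  list(decades = dec, grand = grand)
}

#' Partition a link table by hemisphere pair
#'
#' @param links a [LinkTable-class] with hemisphere information.
#' @return named list of three [LinkTable-class]s (`LL`, `LR`, `RR`);
#'   exhaustive and disjoint.
#' @export
hemispherePartition <- function(links) {
  lk <- linkData(links)
  if (any(!lk$hemisphere_pair %in% c("LL", "LR", "RR")))
    stop("missing or invalid hemisphere_pair", call. = FALSE)
  lapply(stats::setNames(nm = c("LL", "LR", "RR")), function(h)
    linkTable(lk[lk$hemisphere_pair == h, , drop = FALSE]))
}

#' Control-node-set comparison
#'
#' For each subject, links are assessed on two disjoint node sets and the
#' two `(d, W)` samples of observable links are compared with the 2-D KS
#' test; the per-subject p values are then gated at the Bonferroni-corrected
#' level `alpha / n_subjects`.
#'
#' @param series list of [TimeSeriesSet-class]s (one per subject), holding
#'   the signals of all nodes of both sets.
#' @param nodesA,nodesB two disjoint [NodeTable-class]s.
#' @param ksMethod,B,ksSeed see [ks2dTest()].
#' @param alpha family-wise level for the Bonferroni gate.
#' @param ... link-assessment parameters passed to [assessLinks()].
#' @return list with `perSubject` (data.frame: `subject_id`, `D`, `p`),
#'   `correctedLevel` and `reject` flags.
#' @export
controlSetComparison <- function(series, nodesA, nodesB,
                                 ksMethod = "asymptotic", B = 999,
                                 ksSeed = 1, alpha = 0.05, ...) {
  idsA <- nodeIds(nodesA); idsB <- nodeIds(nodesB)
  if (length(intersect(idsA, idsB)))
    stop("node sets overlap: ",
         paste(intersect(idsA, idsB), collapse = ", "), call. = FALSE)
  res <- data.frame(subject_id = character(), D = numeric(), p = numeric())
  for (ts in series) {
    sub <- function(ids) timeSeriesSet(
      signalMatrix(ts)[, ids, drop = FALSE], samplingPeriod(ts),
      subjectId = subjectId(ts), nodeIds = ids)
    lA <- assessLinks(sub(idsA), nodesA, ...)
    lB <- assessLinks(sub(idsB), nodesB, ...)
    kt <- ks2dTest(lA, lB, method = ksMethod, B = B, seed = ksSeed)
    res <- rbind(res, data.frame(subject_id = subjectId(ts), D = kt@D,
                                 p = kt@p))
  }
  gate <- bonferroniGate(res$p, alpha)
  list(perSubject = res, correctedLevel = gate$correctedLevel,
       reject = gate$reject)
}
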