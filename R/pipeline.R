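## End-to-end driver: inputs (real files or a synthetic cohort) -> link
## assessment -> distance distributions -> piecewise fits (all links plus
## the three hemisphere subsets) -> power law -> subject summaries.

#' Run the full analysis pipeline
#'
#' Either generates a synthetic cohort from `config$synthetic` (a
#' [SyntheticConfig-class]) or loads real inputs from `config$seriesFiles`
#' (character vector of series-matrix paths), `config$nodeFile` and
#' `config$samplingPeriod`.  Further recognised entries, with their
#' defaults: `w0` (0.2 s), `M` (150), `alpha` (0.05), `etaThreshold` (0.5),
#' `nSurrogates` (200), `surrogate` ("iaaft"), `shareSurrogates` (TRUE for
#' synthetic cohorts), `seed` (1), `bins` (50), `initD12`/`initD23`
#' (44/68 mm), `d0` (75 mm), `ages`, `epochs` (per-subject epoch tables
#' applied through [selectAndTrimEpochs()]), and `outputDir` (when set,
#' every artifact is written there as delimited text plus a JSON-like run
#' manifest).
#'
#' @param config a named list, see Details.
#' @return list with `links` (pooled [LinkTable-class]), `perSubject`
#'   summaries, `decades`, `joint`, `curve`, `fits` (named list of
#'   [PiecewiseFit-class] or failure messages for All/LL/LR/RR),
#'   `powerLaw`, `nodes`, and `params` (the fully-resolved parameter set).
#' @export
runPipeline <- function(config) {
  defaults <- list(w0 = 0.2, M = 150, alpha = 0.05, etaThreshold = 0.5,
                   nSurrogates = 200, surrogate = "iaaft", seed = 1,
                   bins = 50, initD12 = 44, initD23 = 68, d0 = 75,
                   shareSurrogates = NULL, outputDir = NULL, ages = NULL,
                   epochs = NULL)
  params <- utils::modifyList(defaults, config)

  ## ---- resolve inputs before any computation
  if (!is.null(params$synthetic)) {
    cfg <- params$synthetic
    stopifnot(is(cfg, "SyntheticConfig"))
    params$w0 <- cfg@w0; params$M <- cfg@M; params$alpha <- cfg@alpha
    params$etaThreshold <- cfg@etaThreshold
    params$nSurrogates <- cfg@nSurrogates; params$surrogate <- cfg@surrogate
    if (is.null(params$shareSurrogates)) params$shareSurrogates <- TRUE
    cohort <- generateCohort(cfg, calibration = params$calibration)
    series <- cohort$series
    subjectNodes <- cohort$subjectNodes
    nodes <- cohort$nodes
    ages <- cohort$ages
  } else {
    if (is.null(params$seriesFiles) || is.null(params$nodeFile) ||
        is.null(params$samplingPeriod))
      stop("configuration must name 'seriesFiles', 'nodeFile' and 'samplingPeriod' (or supply 'synthetic')",
           call. = FALSE)
    if (!file.exists(params$nodeFile))
      stop("node table not found: ", params$nodeFile, call. = FALSE)
    nodes <- readNodeTable(params$nodeFile)
    series <- lapply(params$seriesFiles, readSeriesMatrix,
                     samplingPeriod = params$samplingPeriod)
    subjectNodes <- rep(list(nodes), length(series))
    ages <- params$ages
    if (is.null(params$shareSurrogates)) params$shareSurrogates <- FALSE
    if (!is.null(params$epochs)) {
      series <- mapply(function(ts, ep) {
        tr <- selectAndTrimEpochs(ep, samplingPeriod(ts))
        keep <- unlist(mapply(seq, tr$start + 1L, tr$end, SIMPLIFY = FALSE))
        timeSeriesSet(signalMatrix(ts)[keep, , drop = FALSE],
                      samplingPeriod(ts), subjectId(ts))
      }, series, params$epochs, SIMPLIFY = FALSE)
    }
  }

  ## ---- link assessment
  linkDfs <- vector("list", length(series))
  for (s in seq_along(series)) {
    lt <- assessLinks(series[[s]], subjectNodes[[s]], w0 = params$w0,
                      M = params$M, alpha = params$alpha,
                      etaThreshold = params$etaThreshold,
                      nSurrogates = params$nSurrogates,
                      surrogate = params$surrogate,
                      seed = params$seed + s,
                      shareSurrogates = isTRUE(params$shareSurrogates))
    linkDfs[[s]] <- linkData(lt)
  }
  links <- linkTable(do.call(rbind, linkDfs))

  ## ---- per-subject and decade summaries
  perSubject <- do.call(rbind, lapply(seq_along(linkDfs), function(s)
    subjectSummary(linkTable(linkDfs[[s]]),
                   age = if (!is.null(ages)) ages[s] else NA_real_)))
  decades <- if (!is.null(ages) && all(is.finite(perSubject$age)))
    decadeSummaries(perSubject) else NULL

  ## ---- distributions and fits (all links + hemisphere subsets)
  bins <- params$bins
  joint <- jointDistribution(links, binning2d(bins, bins, logD = TRUE))
  curve <- conditionalCurve(joint)
  parts <- hemispherePartition(links)
  fitOne <- function(lt) {
    tryCatch({
      j <- jointDistribution(lt, binning2d(bins, bins, logD = TRUE))
      twoStepPiecewiseFit(conditionalCurve(j), params$initD12, params$initD23)
    }, error = function(e) conditionMessage(e))
  }
  fits <- c(list(All = fitOne(links)), lapply(parts, fitOne))

  ## ---- third-regime power law on the pooled observable links
  d23 <- if (is(fits$All, "PiecewiseFit")) fits$All@breakpoints[2] else
    params$initD23
  obs <- observableLinks(links)
  third <- obs[obs$d_mm > d23, ]
  powerLaw <- tryCatch(fitPowerLaw(third$d_mm, third$W_s, d0 = params$d0),
                       error = function(e) conditionMessage(e))

  out <- list(links = links, perSubject = perSubject, decades = decades,
              joint = joint, curve = curve, fits = fits, powerLaw = powerLaw,
              nodes = nodes, params = params[setdiff(names(params),
                                                     c("synthetic", "calibration"))])
  if (!is.null(params$outputDir)) writePipelineArtifacts(out, params$outputDir)
  out
}

writePipelineArtifacts <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLinkTable(res$links, file.path(dir, "links.tsv"))
  writeNodeTable(res$nodes, file.path(dir, "nodes.tsv"))
  utils::write.table(res$perSubject, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$curve@table, file.path(dir, "conditional_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$joint@f, file.path(dir, "joint.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fitRows <- do.call(rbind, lapply(names(res$fits), function(nm) {
    f <- res$fits[[nm]]
    if (!is(f, "PiecewiseFit"))
      return(data.frame(set = nm, m1 = NA, m2 = NA, m3 = NA, d12 = NA,
                        d23 = NA, note = as.character(f)))
    data.frame(set = nm, m1 = f@slopes[1], m2 = f@slopes[2], m3 = f@slopes[3],
               d12 = f@breakpoints[1], d23 = f@breakpoints[2], note = "")
  }))
  utils::write.table(fitRows, file.path(dir, "piecewise_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pp <- res$params[!vapply(res$params, is.null, logical(1))]
  manifest <- c("{",
    paste0('  "', names(pp), '": "',
           vapply(pp, function(v) paste(format(v), collapse = ","),
                  character(1)),
           '"', c(rep(",", length(pp) - 1), "")),
    "}")
  writeLines(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}
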