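## On-disk artifacts: series matrices, node tables, link tables, epoch rules.
## All formats are header-first delimited text; comma and tab (and general
## whitespace) are accepted on read, tab is emitted on write.

splitDelimited <- function(lines) {
  lines <- sub("[\r\n]+$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  delim <- if (any(grepl(",", lines))) "," else "[ \t]+"
  lapply(lines, function(l) trimws(strsplit(trimws(l), delim)[[1]]))
}

#' Read a delimited series matrix
#'
#' Parses a plain-text numeric matrix with one column per node and an
#' optional single header row of node identifiers.  Comma- and
#' whitespace-delimited files are accepted; trailing blank lines are
#' ignored.
#'
#' @param path file path.
#' @param samplingPeriod sampling period in seconds.
#' @param subjectId subject label attached to the result.
#' @return A [TimeSeriesSet-class].
#' @examples
#' f <- tempfile(); writeLines(c("n1,n2", "1,2", "3,4", "5,6"), f)
#' readSeriesMatrix(f, samplingPeriod = 0.004)
#' @export
readSeriesMatrix <- function(path, samplingPeriod, subjectId = basename(path)) {
  cells <- splitDelimited(readLines(path, warn = FALSE))
  if (!length(cells)) stop("empty series file: ", path, call. = FALSE)
  first <- suppressWarnings(as.numeric(cells[[1]]))
  hasHeader <- anyNA(first)
  ids <- if (hasHeader) cells[[1]] else paste0("n", seq_along(cells[[1]]))
  rows <- if (hasHeader) cells[-1] else cells
  if (!length(rows)) stop("series file has a header but no data rows: ", path,
                          call. = FALSE)
  p <- length(ids)
  nf <- lengths(rows)
  if (any(nf != p)) {
    bad <- which(nf != p)[1]
    stop(sprintf("ragged row %d in '%s': %d fields, expected %d",
                 bad + hasHeader, path, nf[bad], p), call. = FALSE)
  }
  m <- matrix(NA_real_, nrow = length(rows), ncol = p)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric value '%s' at row %d, column %d of '%s'",
                   rows[[i]][j], i + hasHeader, j, path), call. = FALSE)
    }
    m[i, ] <- v
  }
  timeSeriesSet(m, samplingPeriod = samplingPeriod, subjectId = subjectId,
                nodeIds = ids)
}

#' Write a series matrix
#'
#' @param ts a [TimeSeriesSet-class].
#' @param path output file path; a header row of node ids is written first.
#' @return `path`, invisibly.
#' @export
writeSeriesMatrix <- function(ts, path) {
  utils::write.table(signalMatrix(ts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = nodeIds(ts))
  invisible(path)
}

#' Read a node table
#'
#' Expects a delimited table with columns `node_id`, `label`, `hemisphere`,
#' `x`, `y`, `z` (mm), with or without a header row.  Hemisphere tokens are
#' normalised to `left`/`right`.
#'
#' @param path file path.
#' @return A [NodeTable-class].
#' @export
readNodeTable <- function(path) {
  cells <- splitDelimited(readLines(path, warn = FALSE))
  if (!length(cells)) stop("empty node table: ", path, call. = FALSE)
  if (any(lengths(cells) != 6L))
    stop("node table rows must have 6 fields (node_id, label, hemisphere, x, y, z): ",
         path, call. = FALSE)
  xyz <- suppressWarnings(as.numeric(cells[[1]][4:6]))
  if (anyNA(xyz)) cells <- cells[-1]               # header row
  if (!length(cells)) stop("node table has no data rows: ", path, call. = FALSE)
  m <- do.call(rbind, cells)
  coords <- suppressWarnings(apply(m[, 4:6, drop = FALSE], 2, as.numeric))
  coords <- matrix(coords, ncol = 3)
  if (anyNA(coords))
    stop("non-numeric coordinate in node table: ", path, call. = FALSE)
  if (anyDuplicated(m[, 1]))
    stop("duplicate node_id in node table: ",
         paste(unique(m[duplicated(m[, 1]), 1]), collapse = ", "),
         call. = FALSE)
  nodeTable(node_id = m[, 1], label = m[, 2], hemisphere = m[, 3],
            x = coords[, 1], y = coords[, 2], z = coords[, 3])
}

#' Write a node table
#' @param nodes a [NodeTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNodeTable <- function(nodes, path) {
  utils::write.table(nodeData(nodes), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Epoch selection and trimming
## ---------------------------------------------------------------------------

#' Construct an epoch list
#'
#' Epochs are 0-based half-open sample intervals `[start, end)`.
#'
#' @param start,end integer vectors of equal length, `end > start`.
#' @return data.frame with columns `start`, `end`.
#' @export
epochs <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == length(end))
  if (any(end <= start)) stop("epoch end must exceed start", call. = FALSE)
  data.frame(start = start, end = end)
}

trimEpochTo <- function(start, end, targetSamples) {
  excess <- (end - start) - targetSamples
  stopifnot(excess >= 0)
  # symmetric trim; the odd leftover sample is removed from the end
  front <- excess %/% 2L
  c(start = start + front, end = end - (excess - front))
}

#' Select and trim epochs to the analysis duration
#'
#' Implements the epoch-selection rules used for resting-state recordings:
#' with `T1` the duration of the longest artifact-free epoch, if
#' `T1 >= 240 s` that epoch is trimmed symmetrically to 240 s; if
#' `180 <= T1 < 240 s`, to 180 s; if `T1 < 180 s` the two longest epochs are
#' used, the longest kept whole and the second-longest trimmed symmetrically
#' so that the total is 180 s, or 160 s when 180 s is out of reach.  Subjects
#' whose two longest epochs total less than 160 s are excluded.
#'
#' @param ep data.frame of epochs (see [epochs()]), non-overlapping.
#' @param samplingPeriod sampling period in seconds.
#' @return data.frame of trimmed epochs (columns `start`, `end`), each a
#'   sub-interval of an input epoch, ordered by start.
#' @examples
#' selectAndTrimEpochs(epochs(0, 75000), 0.004)   # 300 s -> 240 s
#' @export
selectAndTrimEpochs <- function(ep, samplingPeriod) {
  if (!nrow(ep)) stop("no epochs supplied", call. = FALSE)
  T <- samplingPeriod
  toSamples <- function(sec) {
    n <- sec / T
    if (abs(n - round(n)) > 1e-8)
      stop("target duration is not a whole number of samples", call. = FALSE)
    as.integer(round(n))
  }
  len <- ep$end - ep$start
  ord <- order(len, decreasing = TRUE)
  T1 <- len[ord[1]] * T
  e1 <- ep[ord[1], ]
  if (T1 >= 240) {
    tr <- trimEpochTo(e1$start, e1$end, toSamples(240))
    return(data.frame(start = tr[["start"]], end = tr[["end"]]))
  }
  if (T1 >= 180) {
    tr <- trimEpochTo(e1$start, e1$end, toSamples(180))
    return(data.frame(start = tr[["start"]], end = tr[["end"]]))
  }
  if (nrow(ep) < 2L) {
    if (T1 >= 160) {
      tr <- trimEpochTo(e1$start, e1$end, toSamples(160))
      return(data.frame(start = tr[["start"]], end = tr[["end"]]))
    }
    stop(sprintf("insufficient data: longest epoch is %.1f s < 160 s", T1),
         call. = FALSE)
  }
  e2 <- ep[ord[2], ]
  total <- (len[ord[1]] + len[ord[2]]) * T
  target <- if (total >= 180) 180 else if (total >= 160) 160 else
    stop(sprintf("insufficient data: two longest epochs total %.1f s < 160 s",
                 total), call. = FALSE)
  need2 <- toSamples(target) - len[ord[1]]
  if (need2 <= 0L) {            # longest epoch alone reaches the target
    tr <- trimEpochTo(e1$start, e1$end, toSamples(target))
    return(data.frame(start = tr[["start"]], end = tr[["end"]]))
  }
  tr2 <- trimEpochTo(e2$start, e2$end, need2)
  out <- data.frame(start = c(e1$start, tr2[["start"]]),
                    end = c(e1$end, tr2[["end"]]))
  out[order(out$start), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Link tables
## ---------------------------------------------------------------------------

#' Write a link table
#'
#' Tab-delimited with columns `subject_id`, `node_a`, `node_b`,
#' `hemisphere_pair`, `d_mm`, `W_s`; unobservable links get an empty `W_s`
#' field.  Round-trips losslessly through [readLinkTable()].
#'
#' @param links a [LinkTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLinkTable <- function(links, path) {
  lk <- linkData(links)
  num <- function(v) vapply(v, function(x)
    if (is.finite(x)) format(x, digits = 15) else "", character(1))
  lk$W_s <- num(lk$W_s)
  lk$d_mm <- num(lk$d_mm)
  utils::write.table(lk, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a link table written by [writeLinkTable()]
#' @param path file path.
#' @return A [LinkTable-class].
#' @export
readLinkTable <- function(path) {
  lk <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "character",
                                         "character", "numeric", "character"),
                          na.strings = "", fill = TRUE)
  if (!nrow(lk)) {
    lk <- data.frame(subject_id = character(), node_a = character(),
                     node_b = character(), hemisphere_pair = character(),
                     d_mm = numeric(), W_s = numeric())
    return(linkTable(lk))
  }
  lk$W_s <- suppressWarnings(as.numeric(lk$W_s))
  linkTable(lk)
}
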