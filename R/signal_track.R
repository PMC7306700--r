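#' Interval-valued genome signal track
#'
#' A `signal_track` holds per-contig sorted, non-overlapping 0-based
#' half-open intervals with a non-negative value (e.g. pileup or fold
#' enrichment). Gaps between intervals mean "no signal observed" and are
#' excluded from all averages.
#'
#' @param x data.frame with columns `contig`, `start`, `end`, `value`.
#' @return the validated, sorted track (class `signal_track` + `data.frame`).
#' @export
signal_track <- function(x) {
  need <- c("contig", "start", "end", "value")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop("signal track lacks column(s): ", paste(miss, collapse = ", "))
  x <- data.frame(contig = as.character(x$contig),
                  start = as.numeric(x$start), end = as.numeric(x$end),
                  value = as.numeric(x$value), stringsAsFactors = FALSE)
  if (anyNA(x$value)) stop("non-numeric value in signal track")
  if (any(x$value < 0)) stop("negative value in signal track")
  if (any(x$end <= x$start)) stop("empty or inverted interval in signal track")
  o <- order(x$contig, x$start, method = "radix")
  x <- x[o, , drop = FALSE]
  rownames(x) <- NULL
  same <- x$contig[-1L] == x$contig[-nrow(x)]
  ovl <- which(same & x$start[-1L] < x$end[-nrow(x)])
  if (length(ovl) > 0L)
    stop("overlapping intervals in signal track at ", x$contig[ovl[1L]], ":",
         x$start[ovl[1L] + 1L])
  class(x) <- c("signal_track", "data.frame")
  x
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", nrow(x), "interval(s) on",
      length(unique(x$contig)), "contig(s)\n")
  NextMethod()
}

#' Read a bedGraph file into a signal track
#'
#' Standard 4-column bedGraph (0-based half-open); `track` header lines are
#' ignored. Overlapping intervals and non-numeric values are errors.
#'
#' @param path bedGraph file.
#' @return a [signal_track()].
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e)
                   stop("failed to parse bedGraph ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  signal_track(data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    value = as.numeric(gr$score), stringsAsFactors = FALSE))
}

# merge adjacent intervals with equal value (same contig, end == next start)
merge_equal_adjacent <- function(track) {
  if (nrow(track) < 2L) return(track)
  new_run <- c(TRUE,
               !(track$contig[-1L] == track$contig[-nrow(track)] &
                 track$start[-1L] == track$end[-nrow(track)] &
                 track$value[-1L] == track$value[-nrow(track)]))
  run <- cumsum(new_run)
  out <- data.frame(
    contig = track$contig[new_run],
    start = track$start[new_run],
    end = as.numeric(tapply(track$end, run, function(e) e[length(e)])),
    value = track$value[new_run], stringsAsFactors = FALSE)
  class(out) <- class(track)
  rownames(out) <- NULL
  out
}

#' Write a signal track as bedGraph
#'
#' Adjacent intervals with equal value are merged on write, so a
#' read/write round trip is lossless up to that merging.
#'
#' @param track a [signal_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  m <- merge_equal_adjacent(track)
  fmt <- function(x, digits = 15)
    vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                                 digits = digits), "")
  lines <- sprintf("%s\t%s\t%s\t%s", m$contig, fmt(m$start), fmt(m$end),
                   fmt(m$value))
  writeLines(lines, path)
  invisible(path)
}

#' Fold enrichment of a ChIP track relative to input
#'
#' Piecewise division on the intersection partition of the two tracks'
#' breakpoints: within every elementary interval covered by both tracks the
#' output value is `chip / max(input, pseudocount)`. Positions absent from
#' either track are absent from the output. This mirrors the usual
#' treatment-vs-input fold-enrichment computation on pileup tracks.
#'
#' @param chip ChIP [signal_track()].
#' @param input input/background [signal_track()].
#' @param pseudocount lower bound applied to the input value (> 0, default
#'   1), so zero-input positions stay finite.
#' @return a [signal_track()] of fold-enrichment values.
#' @export
fold_enrichment <- function(chip, input, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  ctgs <- intersect(unique(chip$contig), unique(input$contig))
  pieces <- lapply(ctgs, function(ctg) {
    a <- chip[chip$contig == ctg, , drop = FALSE]
    b <- input[input$contig == ctg, , drop = FALSE]
    brk <- sort(unique(c(a$start, a$end, b$start, b$end)))
    if (length(brk) < 2L) return(NULL)
    lo <- brk[-length(brk)]; hi <- brk[-1L]
    mid <- (lo + hi) / 2
    ia <- findInterval(mid, a$start)
    ib <- findInterval(mid, b$start)
    cov_a <- ia >= 1L & mid < a$end[pmax(ia, 1L)]
    cov_b <- ib >= 1L & mid < b$end[pmax(ib, 1L)]
    keep <- cov_a & cov_b
    if (!any(keep)) return(NULL)
    data.frame(contig = ctg, start = lo[keep], end = hi[keep],
               value = a$value[ia[keep]] /
                 pmax(b$value[ib[keep]], pseudocount),
               stringsAsFactors = FALSE)
  })
  pieces <- do.call(rbind, pieces)
  if (is.null(pieces) || nrow(pieces) == 0L) {
    empty <- data.frame(contig = character(), start = numeric(),
                        end = numeric(), value = numeric(),
                        stringsAsFactors = FALSE)
    class(empty) <- c("signal_track", "data.frame")
    return(empty)
  }
  merge_equal_adjacent(signal_track(pieces))
}

# Per-contig cumulative integrals for fast windowed means.
# F(x) = integral of value over covered bp in [contig start, x);
# C(x) = covered bp in [contig start, x).
track_integral <- function(track, contig) {
  t <- track[track$contig == contig, , drop = FALSE]
  if (nrow(t) == 0L) return(NULL)
  len <- t$end - t$start
  list(s = t$start, e = t$end,
       cumV = c(0, cumsum(t$value * len)), cumL = c(0, cumsum(len)),
       v = t$value)
}

integral_at <- function(ti, x) {
  i <- findInterval(x, ti$s)          # last interval starting at or before x
  ii <- pmax(i, 1L)
  part_len <- pmax(0, pmin(x, ti$e[ii]) - ti$s[ii])
  list(F = ifelse(i >= 1L, ti$cumV[ii] + ti$v[ii] * part_len, 0),
       C = ifelse(i >= 1L, ti$cumL[ii] + part_len, 0))
}

# base-pair-weighted mean of track values over [lo, hi); NA when uncovered
window_mean <- function(ti, lo, hi) {
  if (is.null(ti)) return(list(mean = rep(NA_real_, length(lo)),
                               covered = rep(0, length(lo))))
  a <- integral_at(ti, pmax(lo, 0))
  b <- integral_at(ti, pmax(hi, 0))
  covered <- b$C - a$C
  m <- ifelse(covered > 0, (b$F - a$F) / covered, NA_real_)
  list(mean = m, covered = covered)
}
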