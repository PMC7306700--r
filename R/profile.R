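#' Map genomic positions onto a cluster-relative axis
#'
#' Positions are expressed relative to a cluster span `[start, end)` of
#' length `L`: 0 at the cluster start, 1 at its end. Flanks extend half the
#' cluster length to each side, so the full profiled axis is `[-0.5, 1.5]`
#' (a 10 kb cluster gets 5 kb flanks).
#'
#' @param x genomic position(s), bp.
#' @param cluster_span numeric `(start, end)` of the cluster, bp.
#' @return relative position(s).
#' @seealso [flank_spans()] for the corresponding flank windows.
#' @export
scale_position <- function(x, cluster_span) {
  L <- cluster_span[2L] - cluster_span[1L]
  if (L <= 0) stop("cluster span must have positive length")
  (x - cluster_span[1L]) / L
}

#' Half-length flank windows of a cluster span
#'
#' @param start,end cluster span, bp (half-open).
#' @return list with `flank5` and `flank3`, each a `(start, end)` pair; the
#'   5' flank is the lower-coordinate flank (clusters carry no strand).
#' @export
flank_spans <- function(start, end) {
  L <- end - start
  if (L <= 0) stop("cluster span must have positive length")
  list(flank5 = c(start - L / 2, start), flank3 = c(end, end + L / 2))
}

profile_bin_edges <- function(bins = c(flank = 50L, body = 100L)) {
  f <- as.integer(bins[["flank"]]); b <- as.integer(bins[["body"]])
  if (f < 1L || b < 1L) stop("bin counts must be >= 1")
  c(seq(-0.5, 0, length.out = f + 1L)[-(f + 1L)],
    seq(0, 1, length.out = b + 1L)[-(b + 1L)],
    seq(1, 1.5, length.out = f + 1L))
}

as_cluster_table <- function(clusters) {
  if (inherits(clusters, "croc_scan")) clusters <- clusters$clusters
  need <- c("contig", "start", "end")
  if (!is.data.frame(clusters) || !all(need %in% names(clusters)))
    stop("clusters must be a croc_scan or a data.frame with contig/start/end")
  if (is.null(clusters$cluster_id))
    clusters$cluster_id <- sprintf("cl_%02d", seq_len(nrow(clusters)))
  clusters
}

#' Average signal profile across length-normalised clusters
#'
#' Each cluster span is mapped to the relative axis `[0, 1]` with
#' half-length flanks at `[-0.5, 0)` and `(1, 1.5]`; within each relative
#' bin the track is averaged base-pair-weighted for that cluster, and the
#' profile value is the unweighted mean over clusters with coverage in the
#' bin (so long clusters do not dominate). Flank bins falling off the start
#' of a contig, or over track gaps, simply contribute no coverage.
#'
#' @param track a [signal_track()] (e.g. fold enrichment).
#' @param clusters a `croc_scan` or a data.frame with `contig`, `start`,
#'   `end` (at least one cluster).
#' @param bins bins per flank and body: `c(flank = 50, body = 100)`.
#' @param condition label stored with the profile.
#' @return object of class `scaled_profile`: data.frame-like list with
#'   `profile` (`rel_lo`, `rel_hi`, `rel_mid`, `mean`, `n_clusters`),
#'   `condition`, `n_clusters`, `bins`.
#' @export
average_profile <- function(track, clusters, bins = c(flank = 50L, body = 100L),
                            condition = "") {
  clusters <- as_cluster_table(clusters)
  if (nrow(clusters) == 0L) stop("need at least one cluster")
  edges <- profile_bin_edges(bins)
  nb <- length(edges) - 1L
  acc <- matrix(NA_real_, nrow = nrow(clusters), ncol = nb)
  dropped <- character()
  for (i in seq_len(nrow(clusters))) {
    ti <- track_integral(track, clusters$contig[i])
    L <- clusters$end[i] - clusters$start[i]
    abs_edges <- clusters$start[i] + edges * L
    wm <- window_mean(ti, abs_edges[-length(abs_edges)], abs_edges[-1L])
    if (all(is.na(wm$mean))) {
      dropped <- c(dropped, clusters$cluster_id[i])
      next
    }
    acc[i, ] <- wm$mean
  }
  if (length(dropped) > 0L)
    warning("cluster(s) without track coverage excluded: ",
            paste(dropped, collapse = ", "))
  used <- rowSums(!is.na(acc)) > 0L
  acc <- acc[used, , drop = FALSE]
  if (nrow(acc) == 0L) stop("no cluster has track coverage")
  prof <- data.frame(
    rel_lo = edges[-length(edges)], rel_hi = edges[-1L],
    rel_mid = (edges[-length(edges)] + edges[-1L]) / 2,
    mean = colMeans(acc, na.rm = TRUE),
    n_clusters = colSums(!is.na(acc)))
  prof$mean[prof$n_clusters == 0L] <- NA_real_
  structure(list(profile = prof, condition = condition,
                 n_clusters = nrow(acc), bins = bins),
            class = "scaled_profile")
}

#' @export
print.scaled_profile <- function(x, ...) {
  cat("scaled_profile", if (nzchar(x$condition)) paste0("'", x$condition, "'"),
      ":", nrow(x$profile), "bins over [-0.5, 1.5],", x$n_clusters,
      "cluster(s)\n")
  invisible(x)
}

#' @export
#' @method plot scaled_profile
plot.scaled_profile <- function(x, ylab = "mean fold enrichment", ...) {
  p <- x$profile
  graphics::plot(p$rel_mid, p$mean, type = "l",
                 xlab = "position relative to cluster", ylab = ylab,
                 main = x$condition, ...)
  graphics::abline(v = c(0, 1), lty = 2, col = "grey40")
  invisible(x)
}

#' Mean signal over a cluster's flanks and body
#'
#' Base-pair-weighted means of the track over the 5' flank (lower
#' coordinates), the cluster body, and the 3' flank, each flank half the
#' cluster length. Uncovered regions yield `NA`; per-region covered
#' fractions are attached as the `"coverage"` attribute.
#'
#' @param track a [signal_track()].
#' @param cluster one cluster: list/data.frame row with `contig`, `start`,
#'   `end`.
#' @return named numeric `(mean_5prime, mean_body, mean_3prime)` with a
#'   `coverage` attribute.
#' @export
region_means <- function(track, cluster) {
  ctg <- as.character(cluster$contig)
  start <- as.numeric(cluster$start); end <- as.numeric(cluster$end)
  fl <- flank_spans(start, end)
  ti <- track_integral(track, ctg)
  lo <- c(fl$flank5[1L], start, fl$flank3[1L])
  hi <- c(fl$flank5[2L], end, fl$flank3[2L])
  wm <- window_mean(ti, lo, hi)
  out <- stats::setNames(wm$mean, c("mean_5prime", "mean_body", "mean_3prime"))
  attr(out, "coverage") <- stats::setNames(wm$covered / (hi - lo),
                                           c("cov_5prime", "cov_body", "cov_3prime"))
  out
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration when the pooled sample size is at most 12 and there are
#' no ties; otherwise midranks with tie correction and continuity-corrected
#' normal approximation.
#'
#' @param a,b numeric samples (non-empty).
#' @param sides `"two"`, `"greater"` or `"less"` (alternative: `a` vs `b`).
#' @return list with `statistic` (Mann-Whitney U of `a`), `p`, and `exact`.
#' @export
rank_sum_test <- function(a, b, sides = c("two", "greater", "less")) {
  sides <- match.arg(sides)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  alt <- c(two = "two.sided", greater = "greater", less = "less")[[sides]]
  exact <- (length(a) + length(b)) <= 12L && !anyDuplicated(c(a, b))
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = alt,
                                            exact = exact, correct = TRUE))
  p <- ht$p.value
  # completely tied pooled sample: the normal approximation degenerates
  # (zero variance); there is no evidence either way
  if (is.nan(p)) p <- 1
  list(statistic = unname(ht$statistic), p = p, exact = exact)
}

cluster_region_table <- function(track, clusters) {
  clusters <- as_cluster_table(clusters)
  out <- lapply(seq_len(nrow(clusters)), function(i) {
    rm <- region_means(track, clusters[i, ])
    data.frame(cluster_id = clusters$cluster_id[i],
               mean_5prime = rm[["mean_5prime"]],
               mean_body = rm[["mean_body"]],
               mean_3prime = rm[["mean_3prime"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Test flank-vs-body signal differences across clusters
#'
#' For each condition's track, computes per-cluster region means
#' ([region_means()]) and compares the 5' flank means and the 3' flank means
#' against the body means across clusters with the Wilcoxon rank-sum test
#' (two-sided). All comparisons in the report are Benjamini-Hochberg
#' adjusted together. The same machinery applied to individual gene spans
#' (pass gene spans as `clusters`) provides the per-feature control showing
#' whether a flank pattern is a cluster-level phenomenon.
#'
#' @param clusters a `croc_scan` or data.frame with `contig`, `start`, `end`;
#'   at least 3 clusters.
#' @param tracks named list of [signal_track()]s, one per condition.
#' @return object of class `flank_comparison`: `tests` (data.frame:
#'   `condition`, `comparison`, `n`, `mean_flank`, `mean_body`, `statistic`,
#'   `p`, `q`), `region_means` (per condition), `n_clusters`.
#' @export
compare_flanks <- function(clusters, tracks) {
  clusters <- as_cluster_table(clusters)
  if (nrow(clusters) < 3L) stop("need at least 3 clusters per comparison")
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("tracks must be a named list (one signal_track per condition)")
  means <- list(); rows <- list(); ri <- 0L
  for (cond in names(tracks)) {
    tab <- cluster_region_table(tracks[[cond]], clusters)
    means[[cond]] <- tab
    for (cmp in c("flank5_vs_body", "flank3_vs_body")) {
      fcol <- if (cmp == "flank5_vs_body") tab$mean_5prime else tab$mean_3prime
      ok <- !is.na(fcol) & !is.na(tab$mean_body)
      if (sum(ok) < 3L)
        stop("condition '", cond, "': fewer than 3 clusters with coverage")
      ht <- rank_sum_test(fcol[ok], tab$mean_body[ok], sides = "two")
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        condition = cond, comparison = cmp, n = sum(ok),
        mean_flank = mean(fcol[ok]), mean_body = mean(tab$mean_body[ok]),
        statistic = ht$statistic, p = ht$p, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  tests$q <- bh_adjust(tests$p)
  structure(list(tests = tests, region_means = means,
                 n_clusters = nrow(clusters)),
            class = "flank_comparison")
}

#' @export
print.flank_comparison <- function(x, ...) {
  cat("Flank-vs-body rank-sum tests over", x$n_clusters, "cluster(s)\n")
  t <- x$tests
  t$p <- signif(t$p, 3); t$q <- signif(t$q, 3)
  t$mean_flank <- round(t$mean_flank, 3); t$mean_body <- round(t$mean_body, 3)
  print(t, row.names = FALSE)
  invisible(x)
}
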