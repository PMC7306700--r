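#' Parameters for the positional cluster scan
#'
#' Defaults follow the common practice for this kind of scan: 5-gene windows
#' sliding one gene at a time (gene-based mode) or 50 kb windows advanced in
#' 1 kb offsets (window-based mode), a minimum of 3 list genes per window /
#' cluster, and a Benjamini-Hochberg FDR threshold of 0.01.
#'
#' @param mode `"gene_based"` (fixed number of genes per window) or
#'   `"window_based"` (fixed base-pair windows, gene membership by midpoint).
#' @param window_genes genes per window in gene-based mode (>= `min_hits`).
#' @param window_bp window size in bp for window-based mode.
#' @param offset_bp step between window starts in bp (<= `window_bp`).
#' @param min_hits minimum list genes for a window to be tested and the
#'   minimum cluster size (>= 2; default 3).
#' @param alpha FDR level applied to BH-adjusted window p-values.
#' @param universe `"annotation"` (all genes in the index) or `"background"`
#'   (restrict the frame and the hypergeometric universe to an expressed
#'   background list supplied to [detect_clusters()]).
#' @return object of class `detection_params`.
#' @export
detection_params <- function(mode = c("gene_based", "window_based"),
                             window_genes = 5L, window_bp = 50000,
                             offset_bp = 1000, min_hits = 3L, alpha = 0.01,
                             universe = c("annotation", "background")) {
  mode <- match.arg(mode)
  universe <- match.arg(universe)
  window_genes <- as.integer(window_genes)
  min_hits <- as.integer(min_hits)
  if (min_hits < 2L) stop("min_hits must be >= 2")
  if (window_genes < min_hits) stop("window_genes must be >= min_hits")
  if (window_bp <= 0 || offset_bp <= 0) stop("window_bp and offset_bp must be > 0")
  if (offset_bp > window_bp) stop("offset_bp must be <= window_bp")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  structure(list(mode = mode, window_genes = window_genes,
                 window_bp = window_bp, offset_bp = offset_bp,
                 min_hits = min_hits, alpha = alpha, universe = universe),
            class = "detection_params")
}

#' Upper tail of the hypergeometric distribution
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of seeing at
#' least `k` list genes in a window of `n` genes when the universe holds `N`
#' genes of which `K` are on the list. Exact (no sampling), evaluated via
#' [stats::phyper()].
#'
#' @param N universe size.
#' @param K list genes in the universe.
#' @param n genes in the window.
#' @param k list genes in the window. Vectorised over all four arguments.
#' @return upper-tail probability in `[0, 1]`.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (any(K > N) || any(n > N) || any(k > pmin(n, K)) || any(k < 0) ||
      any(K < 0) || any(n < 0))
    stop("hypergeometric bounds violated: need 0 <= k <= min(n, K), n <= N, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with enforced monotonicity, in input order.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Enumerate gene-count windows
#'
#' Per contig with `g` genes: windows over ordinals `[i, i + window_genes)`
#' sliding one gene at a time; a contig with fewer than `window_genes` genes
#' yields a single window covering all of its genes.
#'
#' @param index a [gene_index()].
#' @param window_genes genes per window.
#' @return data.frame with `contig`, `first`, `last` (0-based ordinals,
#'   inclusive), `start`, `end` (bp span of the window's genes) and `n`.
#' @export
enumerate_gene_windows <- function(index, window_genes = 5L) {
  window_genes <- as.integer(window_genes)
  if (window_genes < 1L) stop("window_genes must be >= 1")
  g <- index$genes
  out <- lapply(index$contigs, function(ctg) {
    rows <- which(g$contig == ctg)
    gg <- length(rows)
    if (gg == 0L) return(NULL)
    w <- min(window_genes, gg)
    first <- seq.int(0L, gg - w)
    data.frame(contig = ctg, first = first, last = first + w - 1L,
               start = g$start[rows[first + 1L]],
               end = g$end[rows[first + w]],
               n = w, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Enumerate fixed base-pair windows
#'
#' Windows `[s, s + window_bp)` for `s = 0, offset_bp, 2 offset_bp, ...` with
#' `s + window_bp <= contig length`; a contig shorter than `window_bp` yields
#' a single window covering it. Gene membership (used by the scan) is by gene
#' midpoint, half-open.
#'
#' @param index a [gene_index()].
#' @param window_bp window size (bp).
#' @param offset_bp step between window starts (bp).
#' @return data.frame with `contig`, `start`, `end`.
#' @export
enumerate_bp_windows <- function(index, window_bp = 50000, offset_bp = 1000) {
  if (window_bp <= 0 || offset_bp <= 0) stop("window_bp and offset_bp must be > 0")
  ctgs <- names(index$contig_lengths)
  out <- lapply(ctgs, function(ctg) {
    L <- index$contig_lengths[[ctg]]
    if (L < window_bp) {
      data.frame(contig = ctg, start = 0, end = L, stringsAsFactors = FALSE)
    } else {
      s <- seq(0, L - window_bp, by = offset_bp)
      data.frame(contig = ctg, start = s, end = s + window_bp,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Internal scan frame: everything the per-replicate core needs, precomputed
# once per (index, params) so bootstrap replicates only flip membership flags.
scan_frame <- function(index, params) {
  g <- index$genes
  ctgs <- index$contigs
  rows <- split(seq_len(nrow(g)), factor(g$contig, levels = ctgs))
  frame <- list(n_genes = nrow(g), contigs = ctgs, rows = rows,
                mode = params$mode)
  if (params$mode == "window_based") {
    frame$mid <- (g$start + g$end) / 2
    frame$windows <- lapply(ctgs, function(ctg) {
      L <- index$contig_lengths[[ctg]]
      if (L < params$window_bp) cbind(start = 0, end = L)
      else {
        s <- seq(0, L - params$window_bp, by = params$offset_bp)
        cbind(start = s, end = s + params$window_bp)
      }
    })
    names(frame$windows) <- ctgs
    frame$mid_sorted <- lapply(rows, function(r) sort(frame$mid[r]))
  }
  frame
}

# Core scan over a membership flag vector (aligned to index$genes rows).
# Returns tested-window stats and merged clusters as row-index lists.
# K/N: hypergeometric universe; N = frame$n_genes, K = sum(flags).
croc_core <- function(frame, flags, params, count_only = FALSE) {
  min_hits <- params$min_hits
  tested <- list(); ti <- 0L
  if (frame$mode == "gene_based") {
    w0 <- params$window_genes
    for (ci in seq_along(frame$contigs)) {
      r <- frame$rows[[ci]]
      g <- length(r)
      if (g == 0L) next
      w <- min(w0, g)
      z <- flags[r]
      cs <- cumsum(z)
      nw <- g - w + 1L
      # k for window starting at ordinal i (1-based index into r)
      k <- cs[w:g] - c(0L, cs)[1:nw]
      hit <- which(k >= min_hits)
      if (length(hit) == 0L) next
      ti <- ti + 1L
      tested[[ti]] <- list(ci = ci, first = hit, w = w, k = k[hit], cs = cs)
    }
  } else {
    for (ci in seq_along(frame$contigs)) {
      r <- frame$rows[[ci]]
      if (length(r) == 0L) next
      win <- frame$windows[[ci]]
      mids_all <- frame$mid_sorted[[ci]]
      mids_list <- sort(frame$mid[r[flags[r]]])
      if (length(mids_list) < min_hits) next
      # half-open [start, end): #(m < x) via findInterval on x - 0.25
      # (midpoints lie on a 0.5 grid, window bounds are integers)
      kk <- findInterval(win[, "end"] - 0.25, mids_list) -
            findInterval(win[, "start"] - 0.25, mids_list)
      hit <- which(kk >= min_hits)
      if (length(hit) == 0L) next
      nn <- findInterval(win[hit, "end"] - 0.25, mids_all) -
            findInterval(win[hit, "start"] - 0.25, mids_all)
      ti <- ti + 1L
      tested[[ti]] <- list(ci = ci, wi = hit, k = kk[hit], n = nn,
                           start = win[hit, "start"], end = win[hit, "end"])
    }
  }
  if (ti == 0L)
    return(list(count = 0L, clusters = list(), windows = NULL))

  N <- frame$n_genes
  K <- sum(flags)
  k_all <- unlist(lapply(tested, `[[`, "k"), use.names = FALSE)
  n_all <- if (frame$mode == "gene_based")
    unlist(lapply(tested, function(t) rep(t$w, length(t$first))), use.names = FALSE)
  else unlist(lapply(tested, `[[`, "n"), use.names = FALSE)
  p <- stats::phyper(k_all - 1, K, N - K, n_all, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  sig <- q < params$alpha

  clusters <- list()
  nclust <- 0L
  off <- 0L
  win_meta <- if (count_only) NULL else vector("list", length(tested))
  for (t in seq_along(tested)) {
    tw <- tested[[t]]
    m <- length(tw$k)
    idx <- off + seq_len(m)
    off <- off + m
    r <- frame$rows[[tw$ci]]
    if (!count_only) {
      if (frame$mode == "gene_based") {
        win_meta[[t]] <- data.frame(
          contig = frame$contigs[tw$ci],
          first = tw$first - 1L, last = tw$first + tw$w - 2L,
          start = NA_real_, end = NA_real_,
          n = tw$w, k = tw$k, p = p[idx], q = q[idx],
          significant = sig[idx], stringsAsFactors = FALSE)
      } else {
        win_meta[[t]] <- data.frame(
          contig = frame$contigs[tw$ci],
          first = NA_integer_, last = NA_integer_,
          start = tw$start, end = tw$end,
          n = tw$n, k = tw$k, p = p[idx], q = q[idx],
          significant = sig[idx], stringsAsFactors = FALSE)
      }
    }
    s <- which(sig[idx])
    if (length(s) == 0L) next
    if (frame$mode == "gene_based") {
      cs <- tw$cs
      w <- tw$w
      starts <- tw$first[s]          # 1-based position within contig
      cur_lo <- starts[1L]; cur_hi <- starts[1L] + w - 1L
      flush <- function(lo, hi) {
        members <- r[seq.int(lo, hi)]
        members[flags[members]]
      }
      for (j in seq_along(starts)[-1L]) {
        s2 <- starts[j]; e2 <- s2 + w - 1L
        # shared list gene iff a flagged gene lies in the overlap
        shared <- s2 <= cur_hi &&
          (cs[min(cur_hi, e2)] - cs[s2 - 1L]) >= 1L
        if (shared) cur_hi <- max(cur_hi, e2)
        else {
          nclust <- nclust + 1L
          if (!count_only) clusters[[nclust]] <- flush(cur_lo, cur_hi)
          cur_lo <- s2; cur_hi <- e2
        }
      }
      nclust <- nclust + 1L
      if (!count_only) clusters[[nclust]] <- flush(cur_lo, cur_hi)
    } else {
      ws <- tw$start[s]; we <- tw$end[s]
      mid <- frame$mid
      cur_lo <- ws[1L]; cur_hi <- we[1L]
      flush <- function(lo, hi) {
        cand <- r[flags[r]]
        cand[mid[cand] >= lo & mid[cand] < hi]
      }
      for (j in seq_along(ws)[-1L]) {
        if (ws[j] < cur_hi) cur_hi <- max(cur_hi, we[j])
        else {
          nclust <- nclust + 1L
          if (!count_only) clusters[[nclust]] <- flush(cur_lo, cur_hi)
          cur_lo <- ws[j]; cur_hi <- we[j]
        }
      }
      nclust <- nclust + 1L
      if (!count_only) clusters[[nclust]] <- flush(cur_lo, cur_hi)
    }
  }
  windows <- if (count_only) NULL else do.call(rbind, win_meta)
  list(count = nclust, clusters = clusters, windows = windows,
       N = N, K = K)
}

#' Detect positional clusters of list genes
#'
#' Slides windows along each contig (see [detection_params()]), tests every
#' window holding at least `min_hits` list genes with the hypergeometric
#' upper tail, adjusts those p-values by Benjamini-Hochberg, and merges
#' significant windows that share a list gene (window-based mode also merges
#' on bp overlap) into clusters. Only windows entering the test contribute to
#' the BH denominator.
#'
#' @param index a [gene_index()].
#' @param list a [gene_list()] (or character vector) of genes of interest;
#'   members must be present in the index.
#' @param params a [detection_params()].
#' @param background expressed-gene [gene_list()]; required when
#'   `params$universe == "background"`, in which case both the scan frame and
#'   the hypergeometric universe are restricted to it.
#' @return object of class `croc_scan`: list with `clusters` (data.frame:
#'   `cluster_id`, `contig`, `start`, `end`, `size`, `best_q` and a `members`
#'   list-column of member gene ids in genomic order), `windows` (tested
#'   windows with `n`, `k`, `p`, `q`), `params`, `N`, `K`, `list_name`,
#'   `n_list`.
#' @export
detect_clusters <- function(index, list, params = detection_params(),
                            background = NULL) {
  members <- as_members(list)
  list_name <- if (inherits(list, "gene_list")) list$name else "gene_list"
  unknown <- setdiff(members, index$genes$gene_id)
  if (length(unknown) > 0L)
    stop("list gene(s) not in index: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  if (params$universe == "background") {
    if (is.null(background))
      stop("universe = 'background' requires a background gene list")
    bg <- as_members(background)
    index <- subset_index(index, intersect(bg, index$genes$gene_id))
    drop <- setdiff(members, bg)
    if (length(drop) > 0L)
      warning(length(drop), " list gene(s) outside the background were dropped")
    members <- intersect(members, bg)
  }
  if (n_genes(index) < length(members))
    stop("universe smaller than the gene list")

  empty <- function() {
    cl <- data.frame(cluster_id = character(), contig = character(),
                     start = numeric(), end = numeric(), size = integer(),
                     best_q = numeric(), stringsAsFactors = FALSE)
    cl$members <- list()
    structure(list(clusters = cl, windows = NULL, params = params,
                   N = n_genes(index), K = length(members),
                   list_name = list_name, n_list = length(members)),
              class = "croc_scan")
  }
  if (length(members) == 0L) return(empty())

  frame <- scan_frame(index, params)
  flags <- index$genes$gene_id %in% members
  res <- croc_core(frame, flags, params, count_only = FALSE)
  if (res$count == 0L) {
    out <- empty()
    out$windows <- res$windows
    return(out)
  }
  g <- index$genes
  cl <- lapply(res$clusters, function(rows) {
    rows <- rows[order(g$start[rows], g$gene_id[rows])]
    data.frame(contig = g$contig[rows[1L]],
               start = min(g$start[rows]), end = max(g$end[rows]),
               size = length(rows), stringsAsFactors = FALSE)
  })
  cl <- do.call(rbind, cl)
  cl$members <- lapply(res$clusters, function(rows)
    g$gene_id[rows[order(g$start[rows], g$gene_id[rows])]])
  o <- order(cl$contig, cl$start, method = "radix")
  cl <- cl[o, , drop = FALSE]
  # best_q: min q over significant windows whose genes intersect the cluster
  win <- res$windows
  cl$best_q <- vapply(seq_len(nrow(cl)), function(i) {
    wct <- win$contig == cl$contig[i] & win$significant
    if (!any(wct)) return(NA_real_)
    wsub <- win[wct, , drop = FALSE]
    if (params$mode == "gene_based") {
      ords <- gene_rank(index, cl$members[[i]])$ordinal
      keep <- wsub$first <= max(ords) & wsub$last >= min(ords)
    } else {
      keep <- wsub$start < cl$end[i] & wsub$end > cl$start[i]
    }
    if (!any(keep)) NA_real_ else min(wsub$q[keep])
  }, 0)
  cl <- cbind(cluster_id = sprintf("cl_%02d", seq_len(nrow(cl))),
              cl, stringsAsFactors = FALSE)
  rownames(cl) <- NULL
  structure(list(clusters = cl, windows = res$windows, params = params,
                 N = res$N, K = res$K, list_name = list_name,
                 n_list = length(members)),
            class = "croc_scan")
}

#' @export
print.croc_scan <- function(x, ...) {
  cat("Positional cluster scan (", x$params$mode, ") of '", x$list_name,
      "': ", nrow(x$clusters), " cluster(s)\n", sep = "")
  cat("  universe N = ", x$N, ", list K = ", x$K, ", alpha = ",
      x$params$alpha, " (BH)\n", sep = "")
  if (nrow(x$clusters) > 0L) {
    cl <- x$clusters
    cl$members <- vapply(cl$members, function(m) paste(m, collapse = ","), "")
    print(utils::head(cl, 10L))
    if (nrow(cl) > 10L) cat("  ...", nrow(cl) - 10L, "more\n")
  }
  invisible(x)
}

#' @export
#' @method summary croc_scan
summary.croc_scan <- function(object, ...) {
  cl <- object$clusters
  in_cl <- length(unique(unlist(cl$members)))
  out <- list(
    n_clusters = nrow(cl),
    size_range = if (nrow(cl)) range(cl$size) else c(NA_integer_, NA_integer_),
    n_list = object$n_list,
    genes_in_clusters = in_cl,
    prop_list_in_clusters = if (object$n_list) in_cl / object$n_list else NA_real_
  )
  class(out) <- "summary.croc_scan"
  out
}

#' @export
print.summary.croc_scan <- function(x, ...) {
  cat(x$n_clusters, "cluster(s)")
  if (x$n_clusters > 0L)
    cat(", sizes", x$size_range[1L], "to", x$size_range[2L], "genes")
  cat("\n", x$genes_in_clusters, " of ", x$n_list, " list genes clustered (",
      round(100 * x$prop_list_in_clusters, 1), "%)\n", sep = "")
  invisible(x)
}

#' Write scan results to BED and TSV files
#'
#' The BED file has one line per cluster (`contig`, `start`, `end`,
#' `cluster_id`, `size`, `best_q`); the members TSV lists one member gene per
#' row; the optional windows TSV dumps every tested window.
#'
#' @param scan a `croc_scan` from [detect_clusters()].
#' @param bed_path cluster BED output.
#' @param members_path member-gene TSV output (optional).
#' @param windows_path tested-window TSV output (optional).
#' @return `bed_path`, invisibly.
#' @export
write_clusters <- function(scan, bed_path, members_path = NULL,
                           windows_path = NULL) {
  cl <- scan$clusters
  bed <- data.frame(cl$contig, as.integer(cl$start), as.integer(cl$end),
                    cl$cluster_id, cl$size, signif(cl$best_q, 6))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(members_path)) {
    mem <- data.frame(
      cluster_id = rep(cl$cluster_id, lengths(cl$members)),
      gene_id = unlist(cl$members),
      stringsAsFactors = FALSE)
    utils::write.table(mem, members_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(windows_path) && !is.null(scan$windows))
    utils::write.table(scan$windows, windows_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(bed_path)
}
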