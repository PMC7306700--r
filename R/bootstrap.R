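#' Bootstrap null for the genome-wide cluster count
#'
#' Is the number of clusters found for a gene list more (or fewer) than
#' expected for a random list of the same size drawn from the expressed
#' background? Each replicate samples `|list|` genes uniformly without
#' replacement from the background, reruns the cluster scan with identical
#' parameters, and records the cluster count. Empirical p-values use the
#' add-one estimator `(r + 1) / (B + 1)` so they are never zero.
#'
#' By default the detection universe is the background itself (`params`
#' defaults to `detection_params(universe = "background")`), which keeps the
#' observed scan and the null replicates exchangeable.
#'
#' Replicate streams are reproducible and order-independent: one seed vector
#' is drawn up front from `seed`, and replicate `b` reseeds from element `b`.
#'
#' @param index a [gene_index()].
#' @param list the observed [gene_list()]; must be a subset of `background`.
#' @param background expressed-gene [gene_list()].
#' @param params a [detection_params()].
#' @param B number of replicates (the usual choice in this workflow is
#'   10,000; smaller values give coarser p-values with floor `1/(B+1)`).
#' @param seed integer master seed.
#' @return object of class `croc_bootstrap`: `observed_count`,
#'   `replicate_counts` (length `B`), `B`, `seed`, `p_more`, `p_less`.
#' @export
bootstrap_cluster_count <- function(index, list, background,
                                    params = detection_params(universe = "background"),
                                    B = 10000L, seed = 1L) {
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  members <- as_members(list)
  bg <- as_members(background)
  if (!all(members %in% bg))
    stop("gene list must be a subset of the background")
  if (length(bg) < length(members))
    stop("background smaller than the gene list")

  if (params$universe == "background") {
    uni <- subset_index(index, intersect(bg, index$genes$gene_id))
  } else {
    uni <- index
  }
  frame <- scan_frame(uni, params)
  ids <- uni$genes$gene_id
  flags_obs <- ids %in% members
  observed <- croc_core(frame, flags_obs, params, count_only = TRUE)$count

  bg_rows <- which(ids %in% bg)
  n_draw <- length(members)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  counts <- integer(B)
  flags <- logical(length(ids))
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    flags[] <- FALSE
    flags[bg_rows[sample.int(length(bg_rows), n_draw)]] <- TRUE
    counts[b] <- croc_core(frame, flags, params, count_only = TRUE)$count
  }
  p_more <- (1 + sum(counts >= observed)) / (B + 1)
  p_less <- (1 + sum(counts <= observed)) / (B + 1)
  structure(list(observed_count = observed, replicate_counts = counts,
                 B = B, seed = seed, p_more = p_more, p_less = p_less),
            class = "croc_bootstrap")
}

#' @export
print.croc_bootstrap <- function(x, ...) {
  cat("Bootstrap cluster-count null (B = ", x$B, ", seed = ", x$seed, ")\n",
      "  observed clusters: ", x$observed_count, "\n",
      "  null mean: ", round(mean(x$replicate_counts), 2),
      "  range: ", min(x$replicate_counts), "-", max(x$replicate_counts), "\n",
      "  p(more) = ", signif(x$p_more, 4),
      "   p(less) = ", signif(x$p_less, 4), "\n", sep = "")
  invisible(x)
}

#' Write a bootstrap report as TSV
#'
#' @param boot a `croc_bootstrap`.
#' @param path output TSV.
#' @param replicates also write the full replicate-count column.
#' @return `path`, invisibly.
#' @export
write_bootstrap <- function(boot, path, replicates = FALSE) {
  df <- data.frame(observed = boot$observed_count, B = boot$B,
                   seed = boot$seed, p_more = boot$p_more,
                   p_less = boot$p_less)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (replicates) {
    utils::write.table(
      data.frame(replicate = seq_len(boot$B), count = boot$replicate_counts),
      sub("(\\.tsv)?$", "_replicates.tsv", path),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
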