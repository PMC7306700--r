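#' Read a per-species ortholog table
#'
#' The table maps focal genes to their orthologs in other species, with the
#' ortholog's scaffold and ordinal position along it. Ortholog inference
#' itself (BLAST, OrthoFinder, ...) is upstream of this package; the table is
#' consumed as input.
#'
#' @param path TSV with columns `focal_gene`, `species`, `ortho_gene`,
#'   `scaffold`, `order_index`, `strand`, `relation`
#'   (`one2one` / `one2many` / `missing`).
#' @return validated data.frame of ortholog records.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ortholog_records(df)
}

validate_ortholog_records <- function(df) {
  need <- c("focal_gene", "species", "ortho_gene", "scaffold",
            "order_index", "strand", "relation")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("ortholog table lacks column(s): ", paste(miss, collapse = ", "))
  df$order_index <- suppressWarnings(as.numeric(df$order_index))
  if (any(df$order_index < 0, na.rm = TRUE))
    stop("negative order_index in ortholog table")
  bad <- setdiff(unique(df$relation), c("one2one", "one2many", "missing"))
  if (length(bad) > 0L)
    stop("unknown relation value(s): ", paste(bad, collapse = ", "))
  present <- df$relation != "missing"
  if (any(present & (is.na(df$order_index) | is.na(df$scaffold) |
                     !nzchar(as.character(df$scaffold)))))
    stop("non-missing ortholog records need scaffold and order_index")
  df
}

#' Collapse one-to-many orthologs against a cluster's members
#'
#' For each focal gene with several candidate orthologs, keep the candidate
#' lying on the scaffold that carries the most *other* cluster members'
#' orthologs (ties broken by scaffold name, then lowest `order_index`).
#'
#' @param records ortholog records for one species (see
#'   [read_ortholog_table()]).
#' @param cluster_members character vector of the cluster's gene ids.
#' @return records with at most one non-missing row per focal gene.
#' @export
collapse_one2many <- function(records, cluster_members) {
  rec <- records[records$focal_gene %in% cluster_members, , drop = FALSE]
  present <- rec[rec$relation != "missing", , drop = FALSE]
  if (nrow(present) == 0L) return(rec)
  multi <- unique(present$focal_gene[duplicated(present$focal_gene)])
  if (length(multi) == 0L) return(rec)
  keep <- rep(TRUE, nrow(rec))
  for (g in multi) {
    cand <- which(rec$focal_gene == g & rec$relation != "missing")
    support <- vapply(cand, function(i) {
      sum(present$scaffold == rec$scaffold[i] & present$focal_gene != g)
    }, 0)
    o <- order(-support, rec$scaffold[cand], rec$order_index[cand])
    keep[cand[-o[1L]]] <- FALSE
  }
  rec[keep, , drop = FALSE]
}

# Longest common subsequence length of two vectors (classic DP).
lcs_length <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0L || lb == 0L) return(0L)
  prev <- integer(lb + 1L)
  for (i in seq_len(la)) {
    cur <- integer(lb + 1L)
    for (j in seq_len(lb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[lb + 1L]
}

#' Proportion of a cluster's genes in conserved order in another species
#'
#' Groups the cluster members' orthologs by scaffold; for each scaffold
#' carrying at least two of them, computes the longest common subsequence
#' (LCS) between the cluster's genomic gene order and the orthologs ordered
#' by `order_index` -- and against the reversed cluster order, so a
#' whole-block inversion still scores as fully conserved. The score is the
#' best scaffold's LCS length divided by the cluster size; genes with missing
#' orthologs, and scaffolds holding a single ortholog, count against the
#' proportion. Conservation must be witnessed on a single scaffold (a
#' "cluster" means physical colocation).
#'
#' @param cluster cluster members in genomic order: a character vector, or a
#'   single-row slice of a `croc_scan` clusters table.
#' @param records ortholog records (any number of species).
#' @param species species to score; must occur in `records$species`.
#' @return proportion in `[0, 1]`.
#' @export
cluster_order_conservation <- function(cluster, records, species) {
  members <- cluster_members(cluster)
  if (length(members) < 3L)
    stop("cluster must have >= 3 members")
  if (!species %in% records$species)
    stop("species '", species, "' absent from ortholog records")
  rec <- records[records$species == species, , drop = FALSE]
  rec <- collapse_one2many(rec, members)
  rec <- rec[rec$relation != "missing", , drop = FALSE]
  if (nrow(rec) == 0L) return(0)
  best <- 0L
  for (scf in unique(rec$scaffold)) {
    sub <- rec[rec$scaffold == scf, , drop = FALSE]
    if (nrow(sub) < 2L) next
    o <- order(sub$order_index, sub$focal_gene)
    seq_sp <- sub$focal_gene[o]
    fwd <- lcs_length(members, seq_sp)
    rev_ <- lcs_length(rev(members), seq_sp)
    best <- max(best, fwd, rev_)
  }
  best / length(members)
}

cluster_members <- function(cluster) {
  if (is.character(cluster)) return(cluster)
  if (is.data.frame(cluster) && !is.null(cluster$members)) {
    if (nrow(cluster) != 1L) stop("expected a single cluster")
    return(cluster$members[[1L]])
  }
  if (is.list(cluster) && !is.null(cluster$members) &&
      is.character(cluster$members))
    return(cluster$members)
  stop("cannot interpret 'cluster' as a member vector")
}

#' Cluster-by-species gene-order conservation matrix
#'
#' Scores every cluster against every species with
#' [cluster_order_conservation()] and calls a cluster "conserved" in a
#' species when the proportion reaches the threshold (default 0.75). Rows are
#' ordered by cluster size, largest first, matching the usual heatmap layout.
#'
#' @param clusters a `croc_scan` from [detect_clusters()], or a named list of
#'   member-id vectors in genomic order.
#' @param records ortholog records covering all species.
#' @param species_list character vector of species to score (non-empty).
#' @param threshold conservation call threshold on the proportion;
#'   default 0.75.
#' @return object of class `conservation_matrix`: `entries` (clusters x
#'   species proportions), `calls` (logical), `summary` (per-species fraction
#'   of clusters called conserved), `threshold`, `sizes`.
#' @export
conservation_matrix <- function(clusters, records, species_list,
                                threshold = 0.75) {
  if (length(species_list) == 0L) stop("species_list is empty")
  if (inherits(clusters, "croc_scan")) {
    mem <- clusters$clusters$members
    names(mem) <- clusters$clusters$cluster_id
  } else mem <- clusters
  if (length(mem) == 0L) stop("no clusters to score")
  sizes <- lengths(mem)
  o <- order(-sizes, names(mem))
  mem <- mem[o]; sizes <- sizes[o]
  entries <- matrix(NA_real_, nrow = length(mem), ncol = length(species_list),
                    dimnames = list(names(mem), species_list))
  for (sp in species_list) {
    for (i in seq_along(mem)) {
      entries[i, sp] <- cluster_order_conservation(mem[[i]], records, sp)
    }
  }
  calls <- entries >= threshold
  structure(list(entries = entries, calls = calls,
                 summary = colMeans(calls), threshold = threshold,
                 sizes = sizes),
            class = "conservation_matrix")
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat("Gene-order conservation of", nrow(x$entries), "cluster(s) across",
      ncol(x$entries), "species (call threshold", x$threshold, ")\n")
  print(round(x$entries, 3))
  cat("Fraction of clusters conserved per species:\n")
  print(round(x$summary, 3))
  invisible(x)
}

#' @export
#' @method plot conservation_matrix
plot.conservation_matrix <- function(x, ...) {
  e <- x$entries
  graphics::image(x = seq_len(ncol(e)), y = seq_len(nrow(e)),
                  z = t(e[rev(seq_len(nrow(e))), , drop = FALSE]),
                  col = grDevices::hcl.colors(21, "YlGnBu", rev = TRUE),
                  zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                  main = "Cluster gene-order conservation", ...)
  graphics::axis(1, at = seq_len(ncol(e)), labels = colnames(e), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(nrow(e)), labels = rev(rownames(e)), las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Write a conservation matrix as wide and long TSVs
#'
#' @param cm a `conservation_matrix`.
#' @param wide_path wide TSV (clusters x species).
#' @param long_path optional long TSV (`cluster_id`, `species`, `proportion`,
#'   `conserved`) convenient for plotting.
#' @return `wide_path`, invisibly.
#' @export
write_conservation_matrix <- function(cm, wide_path, long_path = NULL) {
  wide <- data.frame(cluster_id = rownames(cm$entries), size = cm$sizes,
                     cm$entries, check.names = FALSE)
  utils::write.table(wide, wide_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(long_path)) {
    long <- data.frame(
      cluster_id = rep(rownames(cm$entries), ncol(cm$entries)),
      species = rep(colnames(cm$entries), each = nrow(cm$entries)),
      proportion = as.vector(cm$entries),
      conserved = as.vector(cm$calls))
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(wide_path)
}
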