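#' Named set of genes of interest
#'
#' @param members character vector of gene ids (stored as a sorted unique set).
#' @param name list name (e.g. the contrast it came from).
#' @param direction_label free-text direction, e.g. "higher in queen-less".
#' @return object of class `gene_list` with fields `name`, `members`,
#'   `direction_label`.
#' @export
gene_list <- function(members, name = "gene_list", direction_label = "") {
  members <- sort(unique(as.character(members)))
  structure(list(name = name, members = members,
                 direction_label = direction_label),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat("gene_list '", x$name, "': ", length(x$members), " genes",
      if (nzchar(x$direction_label)) paste0(" (", x$direction_label, ")"),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$members)

as_members <- function(x) {
  if (inherits(x, "gene_list")) x$members else as.character(x)
}

#' Load a gene list from a text or TSV file
#'
#' One gene id per line (or the first tab-separated column). Ids not present
#' in the index are dropped with a warning; if more than half are unknown the
#' file is rejected as a likely id-space mismatch.
#'
#' @param path text/TSV file.
#' @param index a [gene_index()] to validate against.
#' @param name list name; defaults to the file name.
#' @param direction_label free-text direction label.
#' @return a [gene_list()] of the ids found in the index.
#' @export
load_gene_list <- function(path, index, name = basename(path),
                           direction_label = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE),
                function(f) if (length(f) > 0L) trimws(f[[1L]]) else "", "")
  ids <- unique(ids[nzchar(ids) & !startsWith(ids, "#")])
  if (length(ids) == 0L) stop("empty gene list file: ", path)
  known <- ids %in% index$genes$gene_id
  if (mean(!known) > 0.5)
    stop(sum(!known), "/", length(ids), " ids in ", path,
         " are not in the annotation; gene id spaces probably differ")
  if (any(!known))
    warning(sum(!known), " id(s) in ", path, " not in the annotation; dropped")
  gene_list(ids[known], name = name, direction_label = direction_label)
}

#' Write a gene list as plain text, one id per line
#'
#' @param list a [gene_list()] or character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(list, path) {
  writeLines(as_members(list), path)
  invisible(path)
}

#' Derive the expressed-gene background from an RPKM table
#'
#' A gene belongs to the expressed background if there is at least one
#' condition in which *all* of its replicates exceed the threshold
#' (strictly). This mirrors the usual "RPKM > 5 in both biological
#' replicates of at least one condition" filter used to define genes
#' expressed in the tissue.
#'
#' @param expr long-format data.frame with columns `gene_id`, `condition`,
#'   `replicate`, `rpkm`.
#' @param threshold strict RPKM threshold (> 0); default 5.
#' @param conditions conditions to consider; default all in `expr`. Each must
#'   have at least 2 replicates.
#' @return a [gene_list()] named `"background"`.
#' @export
derive_background <- function(expr, threshold = 5, conditions = NULL) {
  need <- c("gene_id", "condition", "replicate", "rpkm")
  miss <- setdiff(need, names(expr))
  if (length(miss) > 0L)
    stop("expression table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  if (is.null(conditions)) conditions <- unique(expr$condition)
  expr <- expr[expr$condition %in% conditions, , drop = FALSE]
  nrep <- tapply(expr$replicate, expr$condition,
                 function(r) length(unique(r)))
  few <- names(nrep)[nrep < 2L]
  if (length(few) > 0L || length(nrep) < length(conditions))
    stop("background derivation needs >= 2 replicates per condition; ",
         "offending condition(s): ",
         paste(c(few, setdiff(conditions, names(nrep))), collapse = ", "))
  # per gene x condition: pass iff every replicate is strictly above threshold
  key <- paste(expr$gene_id, expr$condition, sep = "\r")
  minv <- tapply(expr$rpkm, key, min)
  nobs <- tapply(expr$rpkm, key, length)
  # a gene absent from some replicates of a condition cannot pass via it
  pass <- minv > threshold & nobs >= nrep[sub("^.*\r", "", names(minv))]
  genes <- sub("\r.*$", "", names(minv))
  gene_list(unique(genes[pass]), name = "background",
            direction_label = paste0("RPKM>", threshold,
                                     " in all replicates of >=1 condition"))
}
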