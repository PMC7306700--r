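#' Ordered genomic frame of gene coordinates
#'
#' A `gene_index` is the frame every positional scan runs over: per contig, an
#' ordered table of gene records (0-based half-open coordinates, sorted by
#' start, ties broken by gene id) together with contig lengths and each gene's
#' ordinal rank on its contig.
#'
#' @param genes data.frame with columns `gene_id`, `contig`, `start`, `end`
#'   and optionally `strand` (`"+"`, `"-"` or `"*"` for unknown). Coordinates
#'   are 0-based half-open; `start < end` is required and `gene_id` must be
#'   unique.
#' @param contig_lengths optional named numeric vector of contig lengths (bp).
#'   Contigs absent from it get the maximum gene end observed; supplied
#'   lengths must cover the genes they carry.
#' @return An object of class `gene_index`: a list with `genes` (the sorted
#'   table, plus an integer `ordinal` column, 0-based within contig),
#'   `contig_lengths`, and `contigs` (contig names in scan order).
#' @seealso [read_annotation()] to build one from a GFF3 file.
#' @export
gene_index <- function(genes, contig_lengths = NULL) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "contig", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0L)
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(genes$strand)) genes$strand <- "*"
  genes <- data.frame(
    gene_id = as.character(genes$gene_id),
    contig  = as.character(genes$contig),
    start   = as.numeric(genes$start),
    end     = as.numeric(genes$end),
    strand  = as.character(genes$strand),
    stringsAsFactors = FALSE
  )
  if (nrow(genes) == 0L) stop("gene table is empty")
  bad <- which(!(genes$start < genes$end))
  if (length(bad) > 0L)
    stop("start < end violated for gene(s): ",
         paste(utils::head(genes$gene_id[bad], 5L), collapse = ", "))
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0L)
    stop("duplicate gene_id: ", paste(utils::head(dup, 5L), collapse = ", "))
  genes$strand[!genes$strand %in% c("+", "-")] <- "*"

  o <- order(genes$contig, genes$start, genes$gene_id, method = "radix")
  genes <- genes[o, , drop = FALSE]
  rownames(genes) <- NULL
  genes$ordinal <- stats::ave(genes$start, genes$contig,
                              FUN = function(x) seq_along(x) - 1L)
  genes$ordinal <- as.integer(genes$ordinal)

  contigs <- unique(genes$contig)
  obs_len <- tapply(genes$end, genes$contig, max)[contigs]
  len <- as.numeric(obs_len)
  names(len) <- contigs
  if (!is.null(contig_lengths)) {
    if (is.null(names(contig_lengths)))
      stop("contig_lengths must be named")
    for (ctg in intersect(names(contig_lengths), contigs)) {
      if (contig_lengths[[ctg]] < len[[ctg]])
        stop("contig_lengths[", ctg, "] shorter than last gene end")
      len[[ctg]] <- as.numeric(contig_lengths[[ctg]])
    }
    extra <- setdiff(names(contig_lengths), contigs)
    if (length(extra) > 0L) {
      add <- as.numeric(contig_lengths[extra])
      names(add) <- extra
      len <- c(len, add)
    }
  }

  structure(
    list(genes = genes, contig_lengths = len, contigs = contigs),
    class = "gene_index"
  )
}

#' @export
print.gene_index <- function(x, ...) {
  cat("gene_index:", nrow(x$genes), "genes on", length(x$contigs),
      "contig(s) (", sum(x$contig_lengths[x$contigs]), "bp )\n")
  invisible(x)
}

n_genes <- function(index) nrow(index$genes)

#' Look up the (contig, ordinal) rank of genes
#'
#' @param index a [gene_index()].
#' @param gene_ids character vector of gene ids; unknown ids are an error.
#' @return data.frame with `gene_id`, `contig`, `ordinal` (0-based).
#' @export
gene_rank <- function(index, gene_ids) {
  i <- match(gene_ids, index$genes$gene_id)
  if (anyNA(i))
    stop("gene id(s) not in index: ",
         paste(utils::head(gene_ids[is.na(i)], 5L), collapse = ", "))
  data.frame(gene_id = gene_ids,
             contig = index$genes$contig[i],
             ordinal = index$genes$ordinal[i],
             stringsAsFactors = FALSE)
}

#' Restrict a gene index to a subset of genes
#'
#' Drops all other genes and recomputes ordinal ranks, so window scans run
#' over the restricted universe (e.g. the expressed background). Contig
#' lengths are retained.
#'
#' @param index a [gene_index()].
#' @param gene_ids genes to keep; must all be present.
#' @return a new [gene_index()].
#' @export
subset_index <- function(index, gene_ids) {
  keep <- index$genes$gene_id %in% gene_ids
  unknown <- setdiff(gene_ids, index$genes$gene_id)
  if (length(unknown) > 0L)
    stop("gene id(s) not in index: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  gene_index(index$genes[keep, c("gene_id", "contig", "start", "end", "strand")],
             contig_lengths = index$contig_lengths)
}

#' Read a GFF3 annotation into a gene index
#'
#' Parses a GFF3 file (via `rtracklayer`), keeps records of one feature type,
#' and converts the 1-based closed GFF3 coordinates to the package's 0-based
#' half-open convention. Contig lengths come from `##sequence-region` pragmas
#' when present, otherwise from the maximum gene end per contig. Gene ids are
#' taken from the `ID` attribute.
#'
#' @param path GFF3 file.
#' @param feature_type feature type (column 3) to keep; default `"gene"`.
#' @return a [gene_index()].
#' @export
read_annotation <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  for (ln in which(body)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop("malformed GFF3 line ", ln, ": expected 9 tab-separated fields, got ",
           length(f))
    s <- suppressWarnings(as.numeric(f[4L])); e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e) || s > e)
      stop("malformed GFF3 line ", ln, ": bad coordinates '", f[4L], "'..'",
           f[5L], "'")
  }
  # ##sequence-region <ctg> <start> <end>
  sr <- lines[startsWith(lines, "##sequence-region")]
  contig_lengths <- NULL
  if (length(sr) > 0L) {
    parts <- strsplit(trimws(sr), "\\s+")
    ok <- vapply(parts, length, 1L) >= 4L
    parts <- parts[ok]
    if (length(parts) > 0L) {
      contig_lengths <- vapply(parts, function(p) as.numeric(p[4L]), 0)
      names(contig_lengths) <- vapply(parts, `[[`, "", 2L)
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L)
    stop("no '", feature_type, "' features in ", path)
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("feature(s) without an ID attribute in ", path)
  genes <- data.frame(
    gene_id = ids,
    contig  = as.character(GenomicRanges::seqnames(gr)),
    start   = GenomicRanges::start(gr) - 1,   # to 0-based half-open
    end     = as.numeric(GenomicRanges::end(gr)),
    strand  = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  gene_index(genes, contig_lengths = contig_lengths)
}

#' Write a gene index back to GFF3
#'
#' Emits `##sequence-region` pragmas for every contig and one `gene` record
#' per entry (converting back to 1-based closed coordinates), so that
#' `read_annotation(write_annotation(x))` preserves gene id, contig,
#' coordinates and strand.
#'
#' @param index a [gene_index()].
#' @param path output file.
#' @param source value for GFF3 column 2.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(index, path, source = "plastdom") {
  g <- index$genes
  strand <- ifelse(g$strand %in% c("+", "-"), g$strand, ".")
  ctgs <- names(index$contig_lengths)
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", ctgs,
            as.integer(index$contig_lengths[ctgs])),
    sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            g$contig, source, as.integer(g$start) + 1L, as.integer(g$end),
            strand, g$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}
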