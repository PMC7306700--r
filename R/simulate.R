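#' Configuration for the synthetic data generator
#'
#' The generator emulates the data shapes this pipeline consumes: a
#' fragmented genome annotation with genes on several contigs, a
#' differential-expression list carrying planted positional clusters plus
#' scattered background DE genes, per-species ortholog tables diverging by
#' inversions/transpositions/losses, and per-condition fold-enrichment
#' tracks with programmed flank/body structure. Defaults give a 2,000-gene
#' genome (5 contigs x 400 genes, ~10 kb per gene+gap), 10 planted clusters
#' of 3-9 genes, and a 5% background DE rate -- a desk-scale stand-in for an
#' insect genome scan.
#'
#' @param seed master seed; all randomness flows from it through named
#'   substreams (genome / list / orthologs / tracks), so each stage can be
#'   regenerated independently.
#' @param n_contigs number of contigs (>= 1).
#' @param genes_per_contig genes per contig (scalar or length `n_contigs`).
#' @param gene_len_range uniform range of gene lengths, bp.
#' @param intergenic_range uniform range of intergenic gaps, bp.
#' @param n_planted_clusters planted clusters in the DE list.
#' @param planted_size_range cluster sizes drawn uniformly from this range
#'   (minimum 3, matching the minimum detectable cluster).
#' @param background_de_rate i.i.d. probability that a non-planted gene is
#'   DE, in `[0, 1]`.
#' @param interleave_rate probability weight for non-DE genes interleaved
#'   between consecutive planted members (geometric gaps), so planted
#'   clusters are not always strictly consecutive; in `[0, 1)`.
#' @param species_panel data.frame with `species`, `inversions`,
#'   `transpositions`, `loss_rate` describing a divergence gradient; the
#'   default panel spans identity to heavy rearrangement.
#' @param track_patterns named list (per condition) of lists with `pattern`
#'   (`"plasticity"`, `"queen_responsive_3prime"` or `"null"`), `flank_fe`,
#'   `body_fe`, `noise_sd`. Default: the "plasticity" geometry (elevated
#'   flanks, depleted body) in both worker conditions.
#' @param track_bin_bp bin width for noisy track emission, bp.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_contigs = 5L, genes_per_contig = 400L,
                       gene_len_range = c(1000, 4000),
                       intergenic_range = c(2000, 12000),
                       n_planted_clusters = 10L,
                       planted_size_range = c(3L, 9L),
                       background_de_rate = 0.05,
                       interleave_rate = 0.2,
                       species_panel = default_species_panel(),
                       track_patterns = default_track_patterns(),
                       track_bin_bp = 200) {
  n_contigs <- as.integer(n_contigs)
  if (is.na(n_contigs) || n_contigs < 1L) stop("n_contigs must be >= 1")
  genes_per_contig <- as.integer(genes_per_contig)
  if (length(genes_per_contig) == 1L)
    genes_per_contig <- rep(genes_per_contig, n_contigs)
  if (length(genes_per_contig) != n_contigs || any(genes_per_contig < 1L))
    stop("genes_per_contig must be positive, length 1 or n_contigs")
  if (any(gene_len_range < 1) || gene_len_range[1L] > gene_len_range[2L])
    stop("invalid gene_len_range")
  if (any(intergenic_range < 0) || intergenic_range[1L] > intergenic_range[2L])
    stop("invalid intergenic_range")
  if (planted_size_range[1L] < 3L)
    stop("planted cluster size must be >= 3")
  if (background_de_rate < 0 || background_de_rate > 1)
    stop("background_de_rate must be in [0, 1]")
  if (interleave_rate < 0 || interleave_rate >= 1)
    stop("interleave_rate must be in [0, 1)")
  for (p in track_patterns) {
    if (!p$pattern %in% c("plasticity", "queen_responsive_3prime", "null"))
      stop("unknown track pattern: ", p$pattern)
    if (p$flank_fe < 0 || p$body_fe < 0)
      stop("fold-enrichment levels must be >= 0")
    if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  }
  structure(list(seed = as.integer(seed), n_contigs = n_contigs,
                 genes_per_contig = genes_per_contig,
                 gene_len_range = gene_len_range,
                 intergenic_range = intergenic_range,
                 n_planted_clusters = as.integer(n_planted_clusters),
                 planted_size_range = as.integer(planted_size_range),
                 background_de_rate = background_de_rate,
                 interleave_rate = interleave_rate,
                 species_panel = species_panel,
                 track_patterns = track_patterns,
                 track_bin_bp = track_bin_bp),
            class = "sim_config")
}

#' Default species divergence panel
#'
#' Six species along a rearrangement gradient, from a sister species with an
#' identical gene order to a distant outgroup with heavy shuffling and
#' ortholog loss -- the shape of a hymenopteran comparative panel.
#'
#' @return data.frame with `species`, `inversions`, `transpositions`,
#'   `loss_rate`.
#' @export
default_species_panel <- function() {
  data.frame(
    species = c("species_sister", "species_congener", "species_family1",
                "species_family2", "species_superfam", "species_outgroup"),
    inversions = c(0L, 2L, 5L, 10L, 20L, 40L),
    transpositions = c(0L, 1L, 3L, 6L, 12L, 25L),
    loss_rate = c(0, 0.03, 0.08, 0.15, 0.25, 0.35),
    stringsAsFactors = FALSE)
}

#' Default track patterns: plasticity geometry in both worker conditions
#' @return named list usable as `track_patterns` in [sim_config()].
#' @export
default_track_patterns <- function() {
  list(
    queen_right = list(pattern = "plasticity", flank_fe = 2, body_fe = 1,
                       noise_sd = 0.1),
    queen_less = list(pattern = "plasticity", flank_fe = 2, body_fe = 1,
                      noise_sd = 0.1))
}

# named substreams off the master seed, kept below 2^31
substream_seed <- function(seed, stream) {
  offset <- match(stream, c("genome", "list", "orthologs", "tracks"))
  if (is.na(offset)) stop("unknown substream: ", stream)
  (abs(as.numeric(seed)) %% 536870911) * 4 + (offset - 1)
}

#' Simulate a genome annotation
#'
#' Genes with uniform lengths and intergenic gaps laid down contig by
#' contig; reproducible given the config seed.
#'
#' @param config a [sim_config()].
#' @return a [gene_index()].
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "genome"))
  tabs <- lapply(seq_len(config$n_contigs), function(ci) {
    g <- config$genes_per_contig[ci]
    len <- floor(runif(g, config$gene_len_range[1L],
                       config$gene_len_range[2L] + 1))
    gap <- floor(runif(g, config$intergenic_range[1L],
                       config$intergenic_range[2L] + 1))
    start <- cumsum(gap) + c(0, cumsum(len))[seq_len(g)]
    data.frame(contig = sprintf("ctg%02d", ci),
               start = start, end = start + len,
               strand = sample(c("+", "-"), g, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, tabs)
  genes$gene_id <- sprintf("g%05d", seq_len(nrow(genes)))
  lens <- tapply(genes$end, genes$contig, max) + 5000
  gene_index(genes, contig_lengths = lens)
}

#' Plant a DE gene list with positional clusters
#'
#' Places `n_planted_clusters` non-overlapping runs of list genes (sizes
#' drawn from `planted_size_range`, optionally interleaved with non-list
#' genes at `interleave_rate`), then adds background DE genes i.i.d. at
#' `background_de_rate` over the remaining genes. Placements keep at least
#' 10 genes between planted runs so each planted cluster is a distinct
#' truth unit.
#'
#' @param index a [gene_index()] (e.g. from [simulate_genome()]).
#' @param config a [sim_config()].
#' @return list with `list` (a [gene_list()]) and `truth` (data.frame of
#'   planted clusters: `cluster`, `contig`, `start`, `end`, `size`, and a
#'   `members` list-column; plus attribute `background_genes`).
#' @export
plant_de_list <- function(index, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "list"))
  g <- index$genes
  ctg_rows <- split(seq_len(nrow(g)), factor(g$contig, levels = index$contigs))
  ctg_n <- lengths(ctg_rows)
  sizes <- sample(seq(config$planted_size_range[1L],
                      config$planted_size_range[2L]),
                  config$n_planted_clusters, replace = TRUE)
  occupied <- lapply(ctg_rows, function(x) integer(0))  # taken ordinals
  truth <- list()
  planted_rows <- integer(0)
  sep <- 10L
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    placed <- FALSE
    for (attempt in seq_len(1000L)) {
      ci <- sample.int(length(ctg_rows), 1L, prob = ctg_n)
      # member offsets with geometric interleaving gaps
      gaps <- if (config$interleave_rate > 0 && s > 1L)
        rgeom(s - 1L, 1 - config$interleave_rate) else integer(max(s - 1L, 0L))
      offs <- cumsum(c(0L, 1L + gaps))
      span <- offs[s] + 1L
      if (span > ctg_n[ci]) next
      o <- sample.int(ctg_n[ci] - span + 1L, 1L) - 1L   # 0-based first ordinal
      rng <- seq.int(o - sep, o + span - 1L + sep)
      if (length(intersect(rng, occupied[[ci]])) > 0L) next
      occupied[[ci]] <- c(occupied[[ci]], rng)
      rows <- ctg_rows[[ci]][o + offs + 1L]
      planted_rows <- c(planted_rows, rows)
      truth[[i]] <- data.frame(
        cluster = sprintf("planted_%02d", i),
        contig = g$contig[rows[1L]],
        start = min(g$start[rows]), end = max(g$end[rows]),
        size = s, stringsAsFactors = FALSE)
      truth[[i]]$members <- list(g$gene_id[rows])
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place planted cluster ", i,
           " after 1000 attempts; genome too small for the configuration")
  }
  truth <- do.call(rbind, truth)
  rest <- setdiff(seq_len(nrow(g)), planted_rows)
  bg_rows <- rest[runif(length(rest)) < config$background_de_rate]
  members <- g$gene_id[sort(c(planted_rows, bg_rows))]
  list(list = gene_list(members, name = "simulated_DE",
                        direction_label = "synthetic"),
       truth = structure(truth, background_genes = g$gene_id[bg_rows]))
}

#' Simulate diverging per-species ortholog tables
#'
#' Starts from the focal gene order on each contig (identity orthology),
#' applies each species' configured number of random segmental inversions
#' and transpositions to that order, and drops orthologs at the species'
#' loss rate. Records are emitted for planted-cluster member genes, with
#' `order_index` equal to the gene's rank in the rearranged order, so
#' expected cluster conservation decreases along the rearrangement gradient.
#'
#' @param index a [gene_index()].
#' @param truth planted-cluster truth from [plant_de_list()].
#' @param species_panel see [sim_config()]; defaults to the config panel.
#' @param seed substream seed; defaults to the orthologs substream of
#'   `config`.
#' @param config a [sim_config()] (source of panel/seed defaults).
#' @return data.frame of ortholog records across all panel species.
#' @export
simulate_ortholog_tables <- function(index, truth, config,
                                     species_panel = config$species_panel,
                                     seed = substream_seed(config$seed, "orthologs")) {
  set.seed(seed)
  g <- index$genes
  ctg_rows <- split(seq_len(nrow(g)), factor(g$contig, levels = index$contigs))
  members <- unlist(truth$members, use.names = FALSE)
  out <- list()
  for (si in seq_len(nrow(species_panel))) {
    sp <- species_panel$species[si]
    recs <- list()
    for (ctg in index$contigs) {
      ids <- g$gene_id[ctg_rows[[ctg]]]
      ord <- seq_along(ids)
      n <- length(ord)
      if (n >= 2L) {
        for (r in seq_len(species_panel$inversions[si])) {
          l <- sample(2:min(15L, n), 1L)
          i0 <- sample.int(n - l + 1L, 1L)
          ord[i0:(i0 + l - 1L)] <- rev(ord[i0:(i0 + l - 1L)])
        }
        for (r in seq_len(species_panel$transpositions[si])) {
          l <- sample(2:min(10L, n - 1L), 1L)
          i0 <- sample.int(n - l + 1L, 1L)
          seg <- ord[i0:(i0 + l - 1L)]
          restv <- ord[-(i0:(i0 + l - 1L))]
          at <- sample.int(length(restv) + 1L, 1L)
          ord <- append(restv, seg, after = at - 1L)
        }
      }
      pos <- match(seq_along(ids), ord)   # rank of each gene in new order
      keep <- ids %in% members
      if (!any(keep)) next
      lost <- runif(sum(keep)) < species_panel$loss_rate[si]
      idsk <- ids[keep]
      recs[[ctg]] <- data.frame(
        focal_gene = idsk, species = sp,
        ortho_gene = ifelse(lost, NA_character_,
                            paste0(sp, "_", idsk)),
        scaffold = ifelse(lost, NA_character_, paste0(sp, "_scf_", ctg)),
        order_index = ifelse(lost, NA_real_, pos[keep]),
        strand = ifelse(lost, NA_character_, "+"),
        relation = ifelse(lost, "missing", "one2one"),
        stringsAsFactors = FALSE)
    }
    out[[sp]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  validate_ortholog_records(res)
}

#' Write per-species ortholog tables as TSVs
#'
#' @param records combined records from [simulate_ortholog_tables()].
#' @param dir output directory; one `orthologs_<species>.tsv` per species.
#' @return written paths, invisibly.
#' @export
write_ortholog_tables <- function(records, dir) {
  paths <- vapply(unique(records$species), function(sp) {
    p <- file.path(dir, paste0("orthologs_", sp, ".tsv"))
    utils::write.table(records[records$species == sp, , drop = FALSE], p,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Simulate per-condition fold-enrichment tracks
#'
#' Builds one fold-enrichment track per configured condition. The
#' `"plasticity"` pattern raises both half-length flanks of every planted
#' cluster to `flank_fe` with the body at `body_fe` (a sharp step at the
#' cluster edges); `"queen_responsive_3prime"` raises only the 3' flank;
#' `"null"` leaves the track flat at `body_fe`. Gaussian noise of the
#' configured sd is added on `track_bin_bp` bins (noise 0 keeps the exact
#' step geometry), values clipped at 0.
#'
#' @param index a [gene_index()].
#' @param truth planted-cluster truth from [plant_de_list()].
#' @param config a [sim_config()].
#' @return list with `tracks` (named list of [signal_track()]s) and
#'   `truth_means` (programmed per-region levels per condition).
#' @export
simulate_tracks <- function(index, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "tracks"))
  tracks <- list(); truth_means <- list()
  for (cond in names(config$track_patterns)) {
    pat <- config$track_patterns[[cond]]
    pieces <- list(); pi <- 0L
    for (ctg in index$contigs) {
      L <- index$contig_lengths[[ctg]]
      cl <- truth[truth$contig == ctg, , drop = FALSE]
      # breakpoints of the programmed geometry
      brk <- c(0, L)
      # flanks drawn to the ceiling of the half-length keep breakpoints on
      # integers (bedGraph-safe) while fully covering the scored L/2 flanks
      if (nrow(cl) > 0L && pat$pattern != "null") {
        half <- ceiling((cl$end - cl$start) / 2)
        brk <- c(brk, pmax(cl$start - half, 0), cl$start, cl$end,
                 pmin(cl$end + half, L))
      }
      brk <- sort(unique(pmin(pmax(brk, 0), L)))
      lo <- brk[-length(brk)]; hi <- brk[-1L]
      mid <- (lo + hi) / 2
      val <- rep(pat$body_fe, length(mid))
      if (nrow(cl) > 0L && pat$pattern == "plasticity") {
        half <- ceiling((cl$end - cl$start) / 2)
        for (i in seq_len(nrow(cl))) {
          in5 <- mid >= cl$start[i] - half[i] & mid < cl$start[i]
          in3 <- mid >= cl$end[i] & mid < cl$end[i] + half[i]
          val[in5 | in3] <- pat$flank_fe
        }
      } else if (nrow(cl) > 0L && pat$pattern == "queen_responsive_3prime") {
        half <- ceiling((cl$end - cl$start) / 2)
        for (i in seq_len(nrow(cl))) {
          in3 <- mid >= cl$end[i] & mid < cl$end[i] + half[i]
          val[in3] <- pat$flank_fe
        }
      }
      if (pat$noise_sd > 0) {
        # subdivide into bins and add noise per bin
        sub <- lapply(seq_along(lo), function(j) {
          edges <- unique(c(seq(lo[j], hi[j], by = config$track_bin_bp), hi[j]))
          cbind(lo = edges[-length(edges)], hi = edges[-1L],
                val = val[j])
        })
        sub <- do.call(rbind, sub)
        v <- pmax(sub[, "val"] + rnorm(nrow(sub), 0, pat$noise_sd), 0)
        pi <- pi + 1L
        pieces[[pi]] <- data.frame(contig = ctg, start = sub[, "lo"],
                                   end = sub[, "hi"], value = v,
                                   stringsAsFactors = FALSE)
      } else {
        pi <- pi + 1L
        pieces[[pi]] <- data.frame(contig = ctg, start = lo, end = hi,
                                   value = val, stringsAsFactors = FALSE)
      }
    }
    tracks[[cond]] <- signal_track(do.call(rbind, pieces))
    truth_means[[cond]] <- list(
      pattern = pat$pattern,
      mean_5prime = if (pat$pattern == "plasticity") pat$flank_fe else pat$body_fe,
      mean_body = pat$body_fe,
      mean_3prime = if (pat$pattern %in% c("plasticity", "queen_responsive_3prime"))
        pat$flank_fe else pat$body_fe)
  }
  list(tracks = tracks, truth_means = truth_means)
}

#' Generate a complete synthetic dataset
#'
#' Runs the whole generator (genome, DE list, ortholog tables, tracks) and
#' optionally writes every input format the pipeline reads: GFF3 annotation,
#' gene-list and background text files, per-species ortholog TSVs, bedGraph
#' tracks, and a truth JSON.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (created if needed).
#' @return list with `index`, `list`, `truth`, `orthologs`, `tracks`,
#'   `truth_means`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  index <- simulate_genome(config)
  de <- plant_de_list(index, config)
  orth <- simulate_ortholog_tables(index, de$truth, config)
  trk <- simulate_tracks(index, de$truth, config)
  out <- list(index = index, list = de$list, truth = de$truth,
              orthologs = orth, tracks = trk$tracks,
              truth_means = trk$truth_means, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_annotation(index, file.path(dir, "annotation.gff3"))
    write_gene_list(de$list, file.path(dir, "de_genes.txt"))
    write_gene_list(index$genes$gene_id, file.path(dir, "background.txt"))
    write_ortholog_tables(orth, dir)
    for (cond in names(trk$tracks))
      write_bedgraph(trk$tracks[[cond]],
                     file.path(dir, paste0("fe_", cond, ".bedGraph")))
    truth <- de$truth
    truth_json <- list(
      clusters = data.frame(truth[, c("cluster", "contig", "start", "end",
                                      "size")],
                            members = vapply(truth$members, paste,
                                             "", collapse = ",")),
      background_genes = attr(de$truth, "background_genes"),
      truth_means = trk$truth_means, seed = config$seed)
    jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
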