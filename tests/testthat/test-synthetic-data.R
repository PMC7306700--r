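small_cfg <- function(seed = 3, background_de_rate = 0.02, ...) {
  sim_config(seed = seed, n_contigs = 2, genes_per_contig = 150,
             n_planted_clusters = 4, planted_size_range = c(3L, 6L),
             background_de_rate = background_de_rate, ...)
}

test_that("genome simulation is seed-deterministic and validated", {
  cfg <- small_cfg()
  i1 <- simulate_genome(cfg)
  i2 <- simulate_genome(cfg)
  expect_identical(i1$genes, i2$genes)
  i3 <- simulate_genome(small_cfg(seed = 4))
  expect_false(identical(i1$genes$start, i3$genes$start))
  expect_true(all(i1$genes$end > i1$genes$start))
  expect_equal(nrow(i1$genes), 300L)
  expect_error(sim_config(n_contigs = 0), "n_contigs")
  expect_error(sim_config(planted_size_range = c(2L, 5L)), ">= 3")
})

test_that("planted lists record truth and honour the background rate", {
  cfg <- small_cfg(background_de_rate = 0)
  idx <- simulate_genome(cfg)
  de <- plant_de_list(idx, cfg)
  expect_equal(length(de$list), sum(de$truth$size))
  expect_true(all(unlist(de$truth$members) %in% idx$genes$gene_id))
  expect_true(all(de$truth$size >= 3 & de$truth$size <= 6))
  # members of one planted cluster sit on one contig in genomic order
  for (i in seq_len(nrow(de$truth))) {
    r <- gene_rank(idx, de$truth$members[[i]])
    expect_equal(length(unique(r$contig)), 1L)
    expect_true(all(diff(r$ordinal) >= 1))
  }
  cfg2 <- small_cfg(background_de_rate = 0.1)
  de2 <- plant_de_list(simulate_genome(cfg2), cfg2)
  n_bg <- length(attr(de2$truth, "background_genes"))
  expect_gt(n_bg, 10)   # ~0.1 * ~280 non-planted genes
  expect_lt(n_bg, 60)
})

test_that("an overfull configuration fails placement with a clear error", {
  cfg <- sim_config(seed = 1, n_contigs = 1, genes_per_contig = 30,
                    n_planted_clusters = 10, planted_size_range = c(3L, 3L))
  idx <- simulate_genome(cfg)
  expect_error(plant_de_list(idx, cfg), "1000 attempts")
})

test_that("ortholog tables degrade along the rearrangement gradient", {
  cfg <- small_cfg()
  idx <- simulate_genome(cfg)
  de <- plant_de_list(idx, cfg)
  orth <- simulate_ortholog_tables(idx, de$truth, cfg)
  panel <- cfg$species_panel
  score <- function(sp) mean(vapply(seq_len(nrow(de$truth)), function(i)
    cluster_order_conservation(de$truth$members[[i]], orth, sp), 0))
  # zero rearrangements: identity orthology scores 1 for every cluster
  expect_equal(score(panel$species[1]), 1)
  scores <- vapply(panel$species, score, 0)
  expect_lt(scores[length(scores)], scores[1])
  # gradient trends down: deep divergences score below shallow ones
  expect_lt(mean(scores[5:6]), mean(scores[1:2]))
})

test_that("track patterns reproduce their programmed region means", {
  cfg <- small_cfg(track_patterns = list(
    queen_right = list(pattern = "plasticity", flank_fe = 2, body_fe = 1,
                       noise_sd = 0),
    queen_less = list(pattern = "null", flank_fe = 2, body_fe = 1,
                      noise_sd = 0)))
  idx <- simulate_genome(cfg)
  de <- plant_de_list(idx, cfg)
  trk <- simulate_tracks(idx, de$truth, cfg)
  rm_qr <- region_means(trk$tracks$queen_right, de$truth[1, ])
  expect_equal(as.numeric(rm_qr), c(2, 1, 2))
  rm_ql <- region_means(trk$tracks$queen_less, de$truth[1, ])
  expect_equal(as.numeric(rm_ql), c(1, 1, 1))

  cfg3 <- small_cfg(track_patterns = list(
    qr = list(pattern = "queen_responsive_3prime", flank_fe = 2, body_fe = 1,
              noise_sd = 0)))
  trk3 <- simulate_tracks(idx, de$truth, cfg3)
  rm3 <- region_means(trk3$tracks$qr, de$truth[1, ])
  expect_equal(as.numeric(rm3), c(1, 1, 2))
  expect_error(small_cfg(track_patterns = list(
    qr = list(pattern = "null", flank_fe = -1, body_fe = 1, noise_sd = 0))),
    ">= 0")
})

test_that("noisy tracks are byte-identical across regenerations", {
  cfg <- small_cfg()
  idx <- simulate_genome(cfg)
  de <- plant_de_list(idx, cfg)
  t1 <- simulate_tracks(idx, de$truth, cfg)
  t2 <- simulate_tracks(idx, de$truth, cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_bedgraph(t1$tracks$queen_right, p1)
  write_bedgraph(t2$tracks$queen_right, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("a written dataset reloads through the package's own readers", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg()
  dat <- simulate_dataset(cfg, dir = dir)
  idx <- read_annotation(file.path(dir, "annotation.gff3"))
  expect_equal(idx$genes, dat$index$genes)
  lst <- load_gene_list(file.path(dir, "de_genes.txt"), idx)
  expect_setequal(lst$members, dat$list$members)
  orth <- read_ortholog_table(
    file.path(dir, "orthologs_species_sister.tsv"))
  expect_true(all(orth$species == "species_sister"))
  trk <- read_bedgraph(file.path(dir, "fe_queen_right.bedGraph"))
  expect_gt(nrow(trk), 0)
  expect_true(file.exists(file.path(dir, "truth.json")))
})

test_that("detection recovers planted clusters on generator output", {
  recovered <- 0L; total <- 0L; false_cl <- 0L
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, n_contigs = 3, genes_per_contig = 300,
                      n_planted_clusters = 6, background_de_rate = 0.02)
    idx <- simulate_genome(cfg)
    de <- plant_de_list(idx, cfg)
    scan <- detect_clusters(idx, de$list)
    planted <- de$truth$members
    total <- total + length(planted)
    hit <- vapply(planted, function(m)
      any(vapply(scan$clusters$members, function(d)
        length(intersect(d, m)) >= 3L, TRUE)), TRUE)
    recovered <- recovered + sum(hit)
    false_cl <- false_cl + sum(vapply(scan$clusters$members, function(d)
      length(intersect(d, unlist(planted))) == 0L, TRUE))
  }
  expect_gte(recovered / total, 0.9)
  expect_lte(false_cl, 3L)   # rare chance triples from background DE genes
})
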