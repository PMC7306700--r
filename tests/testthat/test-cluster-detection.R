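test_that("gene windows slide one gene and short contigs give one window", {
  idx <- make_index(20)
  expect_equal(nrow(enumerate_gene_windows(idx, 5)), 16L)   # 20 - 5 + 1
  idx3 <- make_index(3)
  w <- enumerate_gene_windows(idx3, 5)
  expect_equal(nrow(w), 1L)
  expect_equal(w$n, 3L)
})

test_that("bp windows tile contigs at the offset and short contigs give one window", {
  idx <- gene_index(data.frame(gene_id = "g1", contig = "c1",
                               start = 10, end = 20),
                    contig_lengths = c(c1 = 100050))
  w <- enumerate_bp_windows(idx, 50000, 1000)
  expect_equal(nrow(w), 51L)                                # starts 0..50,000
  expect_equal(w$start[1L], 0); expect_equal(w$start[51L], 50000)

  idx2 <- gene_index(data.frame(gene_id = "g1", contig = "c1",
                                start = 10, end = 20),
                     contig_lengths = c(c1 = 30000))
  w2 <- enumerate_bp_windows(idx2, 50000, 1000)
  expect_equal(nrow(w2), 1L)
  expect_equal(c(w2$start, w2$end), c(0, 30000))
})

test_that("hypergeometric tail matches frozen exact values and sums to one", {
  expect_equal(hypergeom_tail(20, 5, 5, 3), 1126 / 15504, tolerance = 1e-12)
  expect_equal(hypergeom_tail(200, 6, 5, 5), 6 / choose(200, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_tail(100, 10, 7, 0), 1)
  expect_error(hypergeom_tail(10, 11, 5, 2), "bounds")
  expect_error(hypergeom_tail(10, 5, 5, 6), "bounds")

  set.seed(9)
  for (rep in 1:20) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    ks <- max(0, n + K - N):min(n, K)
    pmf <- vapply(ks, function(k)
      hypergeom_tail(N, K, n, k) -
        if (k < min(n, K)) hypergeom_tail(N, K, n, k + 1) else 0, 0)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
  }
})

test_that("hypergeometric tail agrees with placement enumeration at small N", {
  for (N in 2:8) for (K in 1:N) for (n in 1:N) {
    for (k in max(0, n + K - N):min(n, K)) {
      expect_equal(hypergeom_tail(N, K, n, k), hyper_brute(N, K, n, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment is step-up with monotonicity in input order", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("a run of six list genes in a 200-gene contig yields one cluster of six", {
  idx <- make_index(200)
  lst <- gene_list(genes_at(idx, 50:55), "run6")
  scan <- detect_clusters(idx, lst)
  expect_equal(nrow(scan$clusters), 1L)
  expect_equal(scan$clusters$size, 6L)
  expect_setequal(scan$clusters$members[[1L]], lst$members)
  # the two all-hit windows carry the frozen tail C(6,5)/C(200,5)
  w <- scan$windows
  expect_equal(min(w$p), choose(6, 5) / choose(200, 5) * choose(194, 0),
               tolerance = 1e-12)
  expect_true(all(w$q[w$k == 5] < 0.01))
})

test_that("degenerate lists give no clusters", {
  idx <- make_index(100)
  expect_equal(nrow(detect_clusters(idx, gene_list(character(0)))$clusters), 0L)
  # every gene on the list: k = n and K = N, tail is 1 everywhere
  allg <- detect_clusters(idx, gene_list(idx$genes$gene_id))
  expect_equal(nrow(allg$clusters), 0L)
  # two adjacent genes stay below the minimum cluster size
  expect_equal(nrow(detect_clusters(idx, gene_list(genes_at(idx, 10:11)))$clusters), 0L)
  expect_error(detect_clusters(idx, gene_list("nope")), "not in index")
})

test_that("clusters never share genes and members come from the list", {
  set.seed(11)
  for (rep in 1:5) {
    idx <- make_index(300, n_contigs = 2)
    lst <- gene_list(sample(idx$genes$gene_id, 60), "rand")
    scan <- detect_clusters(idx, lst)
    mem <- unlist(scan$clusters$members)
    expect_false(any(duplicated(mem)))
    expect_true(all(mem %in% lst$members))
    if (nrow(scan$clusters) > 0L)
      expect_true(all(scan$clusters$size >= scan$params$min_hits))
  }
})

test_that("scan is invariant to gene renaming and input row order", {
  set.seed(3)
  idx <- make_index(250, n_contigs = 2)
  lst_ids <- c(genes_at(idx, 40:44), genes_at(idx, 100:103, "c2"),
               sample(idx$genes$gene_id, 20))
  scan1 <- detect_clusters(idx, gene_list(lst_ids))

  # rename ids (order-reversing names), same coordinates
  g <- idx$genes
  newid <- setNames(sprintf("x%04d", rev(seq_len(nrow(g)))), g$gene_id)
  g2 <- g[sample(nrow(g)), 1:5]          # also shuffle row order
  g2$gene_id <- unname(newid[g2$gene_id])
  scan2 <- detect_clusters(gene_index(g2, idx$contig_lengths),
                           gene_list(unname(newid[lst_ids])))
  expect_equal(scan2$clusters[, c("contig", "start", "end", "size")],
               scan1$clusters[, c("contig", "start", "end", "size")])
  expect_equal(sort(unname(newid[unlist(scan1$clusters$members)])),
               sort(unlist(scan2$clusters$members)))
})

test_that("gene windows and 50 kb windows agree when 5 genes span 50 kb", {
  idx <- make_index(200, spacing = 10000, len = 5000)
  lst <- gene_list(c(genes_at(idx, 60:64), genes_at(idx, 120:125)))
  g_scan <- detect_clusters(idx, lst, detection_params("gene_based"))
  b_scan <- detect_clusters(idx, lst, detection_params("window_based"))
  expect_equal(nrow(g_scan$clusters), 2L)
  expect_equal(nrow(b_scan$clusters), 2L)
  expect_equal(lapply(g_scan$clusters$members, sort),
               lapply(b_scan$clusters$members, sort))
})

test_that("bp-mode gene membership is by midpoint, half-open", {
  # window [0, 50000): midpoints 45500, 47500, 50000 -> only two inside
  g <- data.frame(
    gene_id = c("a", "b", "c", "d"), contig = "c1",
    start = c(45000, 47000, 49500, 70000), end = c(46000, 48000, 50500, 71000))
  idx <- gene_index(g, contig_lengths = c(c1 = 100000))
  scan <- detect_clusters(idx, gene_list(c("a", "b", "c")),
                          detection_params("window_based", min_hits = 3,
                                           alpha = 1))
  w <- scan$windows
  expect_false(any(w$start == 0))            # k = 2 there: not tested
  expect_true(any(w$start == 1000 & w$k == 3))
})

test_that("universe can be restricted to an expressed background", {
  idx <- make_index(200)
  lst <- gene_list(genes_at(idx, 50:55))
  bg <- gene_list(genes_at(idx, 0:99))
  scan <- detect_clusters(idx, lst,
                          detection_params(universe = "background"),
                          background = bg)
  expect_equal(scan$N, 100L)
  expect_equal(scan$K, 6L)
  expect_equal(nrow(scan$clusters), 1L)
  expect_error(detect_clusters(idx, lst,
                               detection_params(universe = "background")),
               "background")
})

test_that("detection parameter invariants are enforced", {
  expect_error(detection_params(min_hits = 1), ">= 2")
  expect_error(detection_params(window_genes = 2, min_hits = 3), ">= min_hits")
  expect_error(detection_params(window_bp = 500, offset_bp = 1000), "<=")
})

test_that("cluster BED and member TSV round out the scan", {
  idx <- make_index(200)
  scan <- detect_clusters(idx, gene_list(genes_at(idx, 50:55)))
  bed <- withr::local_tempfile(fileext = ".bed")
  mem <- withr::local_tempfile(fileext = ".tsv")
  write_clusters(scan, bed, mem)
  b <- read.table(bed, sep = "\t")
  expect_equal(nrow(b), 1L)
  expect_equal(b$V5, 6L)
  m <- read.delim(mem)
  expect_equal(nrow(m), 6L)
})
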