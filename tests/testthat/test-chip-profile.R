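test_that("bedGraph round trip is lossless up to equal-value merging", {
  trk <- track_of("c1", c(0, 100, 300), c(100, 200, 400), c(2.5, 2.5, 1))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(trk, path)
  back <- read_bedgraph(path)
  # the two adjacent 2.5 intervals merged on write
  expect_equal(nrow(back), 2L)
  expect_equal(back$start, c(0, 300))
  expect_equal(back$end, c(200, 400))
  expect_equal(back$value, c(2.5, 1))

  writeLines(c("track type=bedGraph name=x",
               "c1\t0\t100\t1.5", "c1\t100\t150\t0"), path)
  expect_equal(nrow(read_bedgraph(path)), 2L)   # track line ignored

  expect_error(track_of("c1", c(0, 50), c(100, 150), c(1, 2)), "overlap")
  writeLines(c("c1\t0\t100\tNaNope"), path)
  expect_error(read_bedgraph(path), "bedGraph")
})

test_that("fold enrichment divides on the breakpoint intersection", {
  chip <- track_of("c1", 0, 100, 10)
  input <- track_of("c1", 0, 100, 5)
  fe <- fold_enrichment(chip, input)
  expect_equal(fe$value, 2)

  fe0 <- fold_enrichment(chip, track_of("c1", 0, 100, 0), pseudocount = 1)
  expect_equal(fe0$value, 10)

  split_in <- track_of("c1", c(0, 50), c(50, 100), c(2, 4))
  fe2 <- fold_enrichment(track_of("c1", 0, 100, 4), split_in)
  expect_equal(fe2$start, c(0, 50))
  expect_equal(fe2$value, c(2, 1))

  # multiplicative: scaling chip scales the output exactly
  set.seed(8)
  chip3 <- track_of("c1", seq(0, 900, 100), seq(100, 1000, 100), runif(10, 1, 5))
  in3 <- track_of("c1", seq(0, 950, 50), seq(50, 1000, 50), runif(20, 0.5, 3))
  f1 <- fold_enrichment(chip3, in3)
  chip3c <- chip3; chip3c$value <- chip3c$value * 7
  f7 <- fold_enrichment(chip3c, in3)
  expect_equal(f7$value, 7 * f1$value, tolerance = 1e-12)
  # regions absent from either track are absent from the output
  gap <- fold_enrichment(track_of("c1", 0, 50, 1), track_of("c1", 100, 150, 1))
  expect_error(gap, NA)
})

test_that("relative coordinates put flanks at half the cluster length", {
  span <- c(100000, 110000)
  expect_identical(scale_position(105000, span), 0.5)
  expect_identical(scale_position(100000, span), 0)
  expect_identical(scale_position(110000, span), 1)
  fl <- flank_spans(100000, 110000)
  expect_identical(fl$flank5, c(95000, 100000))   # 5 kb for a 10 kb cluster
  expect_identical(fl$flank3, c(110000, 115000))
})

test_that("region means recover programmed step values and flag partial coverage", {
  cl <- data.frame(contig = "c1", start = 20000, end = 30000)
  trk <- step_track(cl, 60000, flank_fe = 2, body_fe = 1, base = 1)
  rm <- region_means(trk, cl)
  expect_equal(as.numeric(rm), c(2, 1, 2))

  uni <- track_of("c1", 0, 60000, 3.3)
  expect_equal(as.numeric(region_means(uni, cl)), rep(3.3, 3))

  half <- track_of("c1", 20000, 25000, 1)     # only half the body covered
  rmh <- region_means(half, cl)
  expect_equal(unname(rmh[["mean_body"]]), 1)
  expect_true(is.na(rmh[["mean_5prime"]]))
  expect_equal(unname(attr(rmh, "coverage")[["cov_body"]]), 0.5)
})

test_that("scaled profiles are flat for constant tracks and step at cluster edges", {
  cl <- data.frame(contig = "c1", start = 20000, end = 30000)
  const <- track_of("c1", 0, 60000, 3)
  prof <- average_profile(const, cl)
  expect_equal(nrow(prof$profile), 200L)
  expect_true(all(abs(prof$profile$mean - 3) < 1e-12))

  stepped <- step_track(cl, 60000, flank_fe = 2, body_fe = 1, base = 0)
  p2 <- average_profile(stepped, cl)$profile
  expect_true(all(abs(p2$mean[p2$rel_mid > 0 & p2$rel_mid < 1] - 1) < 1e-9))
  expect_true(all(abs(p2$mean[p2$rel_mid < 0] - 2) < 1e-9))
  expect_true(all(abs(p2$mean[p2$rel_mid > 1] - 2) < 1e-9))
})

test_that("the scaled profile is invariant to cluster length", {
  # same relative-shape signal painted over a 10 kb and a 40 kb cluster
  shape <- function(start, L) {
    brk <- start + L * c(-0.5, 0.13, 0.57, 1, 1.5)
    track_of("c1", brk[-5], brk[-1], c(1.7, 0.4, 2.9, 0.8))
  }
  cl1 <- data.frame(contig = "c1", start = 100000, end = 110000)
  cl2 <- data.frame(contig = "c1", start = 400000, end = 440000)
  p1 <- average_profile(shape(100000, 10000), cl1)$profile$mean
  p2 <- average_profile(shape(400000, 40000), cl2)$profile$mean
  expect_true(max(abs(p1 - p2)) < 1e-9)
})

test_that("clusters without coverage are excluded with a warning", {
  cls <- data.frame(contig = "c1", start = c(1000, 50000), end = c(2000, 60000))
  trk <- track_of("c1", 500, 3000, 1)
  expect_warning(prof <- average_profile(trk, cls), "excluded")
  expect_equal(prof$n_clusters, 1L)
})

test_that("rank-sum exact branch matches enumeration and handles degenerate inputs", {
  expect_equal(rank_sum_test(1:3, 4:6)$p, 0.1)
  expect_equal(rank_sum_test(1, 2)$p, 1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 1)  # ties -> approx
  expect_error(rank_sum_test(numeric(0), 1), "empty")

  set.seed(12)
  for (rep in 1:15) {
    m <- sample(1:5, 1); n <- sample(1:5, 1)
    x <- sample(100, m + n)          # distinct -> tie-free
    a <- x[seq_len(m)]; b <- x[-seq_len(m)]
    for (sides in c("two", "greater", "less")) {
      rs <- rank_sum_test(a, b, sides)
      expect_true(rs$exact)
      expect_equal(rs$p, rank_sum_brute(a, b, sides), tolerance = 1e-12)
    }
  }
})

test_that("flank comparisons find programmed contrasts and stay silent on nulls", {
  set.seed(31)
  n_cl <- 12L
  starts <- seq(50000, by = 60000, length.out = n_cl)
  cls <- data.frame(contig = "c1", start = starts, end = starts + 10000)
  contig_len <- max(cls$end) + 50000
  hot <- step_track(cls, contig_len, flank_fe = 2, body_fe = 1, base = 1)
  # jitter per cluster so rank-sum sees distinct values
  jitter_track <- function(trk, sd = 0.01) {
    trk$value <- pmax(trk$value + rnorm(nrow(trk), 0, sd), 0)
    trk
  }
  fc <- compare_flanks(cls, list(qr = jitter_track(hot), ql = jitter_track(hot)))
  expect_true(all(fc$tests$p < 0.01))

  # null signal: non-significant at the 5% level in almost all repetitions
  bins <- seq(0, contig_len, by = 1000)
  null_ok <- vapply(1:10, function(r) {
    flat <- jitter_track(track_of("c1", bins[-length(bins)], bins[-1], 1.5),
                         sd = 0.05)
    all(compare_flanks(cls, list(qr = flat))$tests$p > 0.05)
  }, TRUE)
  expect_gte(sum(null_ok), 8L)

  # identical constant signal in 3 clusters: every comparison is a wash
  cls3 <- cls[1:3, ]
  const <- track_of("c1", 0, contig_len, 2)
  fc1 <- compare_flanks(cls3, list(only = const))
  expect_true(all(fc1$tests$p == 1))

  expect_error(compare_flanks(cls[1:2, ], list(a = const)), "at least 3")
  expect_error(compare_flanks(cls3, list(const)), "named")
})
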