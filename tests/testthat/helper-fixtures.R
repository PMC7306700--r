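# In-code fixtures shared across the suite.

# Deterministic gene index: genes of length `len` every `spacing` bp on each
# contig; contig names c1, c2, ...
make_index <- function(genes_per_contig = 200L, n_contigs = 1L,
                       spacing = 10000, len = 5000) {
  tabs <- lapply(seq_len(n_contigs), function(ci) {
    start <- (seq_len(genes_per_contig) - 1L) * spacing
    data.frame(gene_id = sprintf("c%d_g%03d", ci, seq_len(genes_per_contig)),
               contig = sprintf("c%d", ci),
               start = start, end = start + len, strand = "+",
               stringsAsFactors = FALSE)
  })
  gene_index(do.call(rbind, tabs))
}

# gene ids at 0-based ordinals `ords` of contig `contig`
genes_at <- function(index, ords, contig = index$contigs[1L]) {
  g <- index$genes
  g$gene_id[g$contig == contig][ords + 1L]
}

write_toy_gff3 <- function(path, lines = NULL) {
  if (is.null(lines)) lines <- c(
    "##gff-version 3",
    "##sequence-region ctgA 1 50000",
    "##sequence-region ctgB 1 30000",
    "ctgA\ttoy\tgene\t1\t100\t.\t+\t.\tID=gA",
    "ctgA\ttoy\tgene\t501\t900\t.\t-\t.\tID=gB",
    "ctgB\ttoy\tgene\t201\t400\t.\t.\t.\tID=gC")
  writeLines(lines, path)
  path
}

# signal track from parallel vectors
track_of <- function(contig, start, end, value) {
  signal_track(data.frame(contig = contig, start = start, end = end,
                          value = value, stringsAsFactors = FALSE))
}

# step track: `flank_fe` on both half-length flanks of each cluster row,
# `body_fe` inside, `base` elsewhere over [0, contig_len)
step_track <- function(clusters, contig_len, flank_fe = 2, body_fe = 1,
                       base = 1) {
  pieces <- lapply(unique(clusters$contig), function(ctg) {
    cl <- clusters[clusters$contig == ctg, , drop = FALSE]
    half <- (cl$end - cl$start) / 2
    brk <- sort(unique(c(0, contig_len, pmax(cl$start - half, 0), cl$start,
                         cl$end, pmin(cl$end + half, contig_len))))
    lo <- brk[-length(brk)]; hi <- brk[-1L]
    mid <- (lo + hi) / 2
    val <- rep(base, length(mid))
    for (i in seq_len(nrow(cl))) {
      val[mid >= cl$start[i] - half[i] & mid < cl$start[i]] <- flank_fe
      val[mid >= cl$end[i] & mid < cl$end[i] + half[i]] <- flank_fe
      val[mid >= cl$start[i] & mid < cl$end[i]] <- body_fe
    }
    data.frame(contig = ctg, start = lo, end = hi, value = val,
               stringsAsFactors = FALSE)
  })
  signal_track(do.call(rbind, pieces))
}

# Brute-force LCS: longest subsequence of `a` that is also a subsequence of
# `b`, by enumerating all subsets of `a` (lengths <= ~10).
lcs_brute <- function(a, b) {
  is_subseq <- function(s, v) {
    if (length(s) == 0L) return(TRUE)
    j <- 1L
    for (x in v) {
      if (x == s[j]) {
        j <- j + 1L
        if (j > length(s)) return(TRUE)
      }
    }
    FALSE
  }
  best <- 0L
  n <- length(a)
  for (m in seq_len(2^n) - 1L) {
    s <- a[bitwAnd(m, 2^(seq_len(n) - 1L)) > 0L]
    if (length(s) > best && is_subseq(s, b)) best <- length(s)
  }
  best
}

# Exhaustive rank-sum p-value: enumerate all C(m+n, m) assignments of the
# pooled ranks to group a; two-sided p doubles the smaller tail (capped at 1),
# matching the exact Mann-Whitney convention for tie-free data.
rank_sum_brute <- function(a, b, sides = "two") {
  m <- length(a); n <- length(b)
  pooled <- rank(c(a, b))
  u_obs <- sum(pooled[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  r <- seq_len(m + n)
  us <- apply(combos, 2L, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  total <- ncol(combos)
  switch(sides,
    greater = sum(us >= u_obs) / total,
    less = sum(us <= u_obs) / total,
    two = min(1, 2 * min(sum(us >= u_obs), sum(us <= u_obs)) / total))
}

# Exhaustive hypergeometric upper tail: enumerate all placements of K list
# genes among N slots; window = first n slots; P(at least k in window).
hyper_brute <- function(N, K, n, k) {
  if (K == 0L) return(as.numeric(k <= 0))
  placements <- utils::combn(N, K)
  hits <- colSums(placements <= n)
  mean(hits >= k)
}
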