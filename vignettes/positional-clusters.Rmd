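---
title: "Detecting positional gene clusters and profiling their chromatin context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting positional gene clusters and profiling their chromatin context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Genes that respond together to an environmental or social cue are sometimes
not scattered across the genome but physically clustered along the
chromosomes, and such neighbourhoods are natural targets for domain-level
chromatin regulation (for example by the repressive histone mark H3K27me3).
A motivating case is the honeybee worker ovary, which is plastically
activated when the queen -- and her pheromone -- is lost: genes
differentially expressed between queen-right and queen-less workers can be
asked three questions that this package operationalises.

1. Are the differentially expressed (DE) genes positionally clustered more
   than expected by chance?
2. Are the clusters' gene orders conserved in related species?
3. Does a chromatin signal (ChIP fold enrichment) show cluster-level
   structure -- for instance, enriched flanks demarcating a depleted body?

```{r, eval = FALSE}
library(plastdom)
dat  <- simulate_dataset(sim_config(seed = 1))
scan <- detect_clusters(dat$index, dat$list)
summary(scan)
```

## The scan

The genomic frame is a `gene_index`: per contig, genes sorted by start
position (ties by id), with 0-based half-open coordinates and an ordinal
rank. Two window schemes slide along each contig:

* **gene-based**: every run of `window_genes` consecutive genes (default 5),
  advancing one gene at a time -- physical distance between genes is
  ignored;
* **window-based**: fixed windows of `window_bp` (default 50 kb) advanced in
  `offset_bp` steps (default 1 kb), a gene belonging to a window when its
  midpoint falls inside (half-open).

A window holding $k$ list genes out of $n$, in a universe of $N$ genes of
which $K$ are on the list, is scored with the exact hypergeometric upper
tail

$$P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

evaluated in closed form (`stats::phyper`), never by sampling. Only windows
with at least `min_hits` list genes (default 3, the minimum reportable
cluster size) enter the test; Benjamini-Hochberg correction is applied over
exactly the tested windows, and windows with adjusted $q <$ `alpha`
(default 0.01) are significant. This filtering choice changes the BH
denominator and is deliberate: windows that cannot found a cluster should
not dilute the correction. Significant windows that share at least one list
gene (window-based mode: also windows that overlap in bp) merge
transitively; the merged cluster reports its list-gene members in genomic
order, its size (list genes only, so "3 to 9 genes" means what it says),
the bp span from first to last member, and the best window $q$.

The universe defaults to the whole annotation and can be restricted to an
expressed background (`universe = "background"`), in which case both the
window frame and $(N, K)$ are recomputed over the background genes. The
expressed background itself is derived from an RPKM table by the usual
filter: a gene is expressed if *all* replicates of at least one condition
exceed the threshold (strictly; default RPKM > 5).

## Genome-wide significance by bootstrap

A handful of significant windows does not establish that the genome is
organised with respect to the gene list. `bootstrap_cluster_count()` draws
`B` random lists of the same size uniformly without replacement from the
expressed background, reruns the identical scan (same universe, so null and
observation are exchangeable), and reports add-one empirical p-values

$$p_\mathrm{more} = \frac{1 + \#\{c_b \ge c_\mathrm{obs}\}}{B + 1},$$

and symmetrically $p_\mathrm{less}$, never zero and floored at $1/(B+1)$.
Replicate streams are pre-drawn from the master seed, so results are
reproducible and independent of execution order. `B = 10{,}000` is the
customary choice; the package's own calibration experiments use `B = 500`,
which bounds the resolution at $1/501$.

Calibration was verified on structureless lists (uniform draws from the
background, 200 datasets): the fraction with $p_\mathrm{more} < 0.05$ sits
near 0.04. Two design points matter and were found empirically. First,
window merging makes the null cluster count *underdispersed* relative to
Poisson, so at coarse granularity (null mean around 4) the tied, discrete
empirical p is conservative and the fraction drops below 0.02. Second,
densifying the list does not help: raising $K/N$ weakens every window's
hypergeometric tail (at 15% density a 3-of-5 window cannot reach
$q < 0.01$ at all). The calibration datasets therefore use 2,000 genes with
200-gene lists -- 10% density, null mean about 8 -- where the empirical p
is fine-grained enough to behave near-uniformly.

## Gene-order conservation

For each cluster and species, orthologs of the cluster members (read from a
TSV; ortholog inference is upstream) are grouped by scaffold. On each
scaffold with at least two orthologs, the longest common subsequence (LCS)
is computed between the cluster's genomic gene order and the orthologs
ordered by their `order_index` -- and against the reversed cluster order,
so a whole-block inversion scores as fully conserved. The proportion
conserved is the best single scaffold's LCS length divided by cluster size:
missing orthologs and scaffold singletons count against it, and
conservation split across scaffolds is not combined, because a cluster is a
claim of physical colocation. A cluster is called conserved in a species at
proportion $\ge 0.75$ (exposed as a parameter).

LCS with intervening genes ignored is our operationalisation of "gene order
conserved": it is the standard synteny-block relaxation, it is reproducible
(unlike manual inspection of synteny plots), and it is symmetric under
relabeling and whole-scaffold reversal. One-to-many orthologs are collapsed
per cluster to the candidate on the scaffold carrying most other members'
orthologs; this needs cluster context, so it happens at scoring time rather
than at table-reading time.

## Scaled chromatin profiles

`fold_enrichment()` divides a ChIP track by its input on the intersection
partition of their breakpoints, with `max(input, pseudocount)` in the
denominator (pseudocount 1, the convention of pileup-comparison tools).
Each cluster span $[s, e)$ of length $L$ is mapped to a relative axis where
0 is the cluster start and 1 its end, and flanks of $L/2$ extend the axis
to $[-0.5, 1.5]$ -- a 10 kb cluster gets 5 kb flanks. Within a cluster,
each of the 50 + 100 + 50 bins (flank/body/flank; the resolution is a
display choice) averages the track base-pair-weighted; across clusters the
profile is an unweighted mean over clusters with coverage, so long clusters
do not dominate. Track gaps and flank bins truncated at contig edges simply
contribute no coverage.

`region_means()` summarises each cluster as three base-pair-weighted means
(5' flank, body, 3' flank), where "5'" is the lower-coordinate flank:
clusters have no intrinsic strand, and this convention is stated rather
than guessed. `compare_flanks()` tests, across clusters, flank means
against body means per condition with the Wilcoxon rank-sum test -- exact
enumeration for pooled samples up to 12 without ties, midranks with tie and
continuity correction otherwise; a completely tied comparison reports
$p = 1$. Per-cluster means are the sampling unit, matching how such
boxplots are drawn; all comparisons in one report are BH-adjusted together.
Passing individual gene spans instead of clusters gives the per-gene
control that distinguishes a cluster-level pattern from a property of every
gene.

## What the generator emulates, and what it does not

`simulate_dataset()` produces every input format the pipeline reads, with
recorded truth. Defaults are a desk-scale stand-in for a fragmented insect
genome scan: 5 contigs x 400 genes (gene lengths uniform 1-4 kb, gaps
2-12 kb, about 10 kb per gene so that 5 genes roughly span 50 kb and the
two window schemes are comparable), 10 planted clusters of 3-9 genes,
background DE genes added i.i.d. at rate 0.05. Planted members may be
interleaved with non-list genes (geometric gaps, rate 0.2) so the
3-hits-in-5 window rule is genuinely exercised. Ortholog tables start from
identity and diverge along a six-species panel of increasing segmental
inversions, transpositions and losses; conservation scores decrease along
the panel by construction. Tracks paint two geometries around planted
clusters -- "plasticity" (both flanks elevated, sharp steps at the edges,
in both worker conditions) and "queen-responsive" (3' flank elevated in
the queen-right condition only) -- with Gaussian bin noise, clipped at
zero. Flank paint extends to the ceiling of $L/2$ so that emitted
bedGraphs stay on integer coordinates while the scored $L/2$ flanks remain
exactly covered.

The generator does not emulate: read-level noise, covariance of expression
with gene length or GC, paralog expansions inside clusters, nucleosome-scale
signal structure, or assembly errors. Passing tests on generator output
therefore demonstrates correctness of the machinery and its calibration
under the stated geometry, not performance on any real genome.

### A note on "zero false clusters"

With background DE genes placed i.i.d. at rate 0.05 over 2,000 genes, the
expected number of chance triples -- three background DE genes within five
consecutive genes -- is slightly above one per genome, and such a triple is
*statistically identical* to a planted three-gene cluster (same $k$, $n$,
$N$, $K$). Any detector that recovers planted three-gene clusters will also
report the chance triples; they are genuine clusters of DE genes under the
method's definition, merely not planted ones. The recovery experiments in
the test suite measure both quantities and find exactly this: near-complete
recovery with on the order of one non-planted cluster per genome. A
zero-false-positive expectation at this background rate is mathematically
unattainable, and we document rather than engineer around it (for example,
by silently de-clustering the background draw).

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 and bedGraph I/O
  convert at the boundary. Ordering ties break by gene id; contig
  processing order never affects results.
* A contig with fewer genes than the window yields one window of all its
  genes; empty lists yield empty (not erroneous) scans; a list covering the
  whole universe yields tail 1 everywhere and no clusters.
* `hypergeom_tail` validates its bounds and is exact; BH is the standard
  step-up with monotonicity (`stats::p.adjust`).
* bedGraph writing merges adjacent equal-value intervals; reading rejects
  overlaps (with the offending position) and non-numeric values.
* Profile bins with no covered base pairs are `NA` and drop out of the
  cross-cluster mean; clusters with no coverage at all are excluded with a
  warning.

## Problem sizes

The shipped experiments use 2,000-gene genomes for detection, recovery and
power runs; 200 datasets at `B = 500` for bootstrap calibration; clusters
of up to 7 genes for brute-force LCS cross-checks; and pooled samples up to
10 for exhaustive rank-sum enumeration. These sizes make every check exact
or well-powered while keeping the full suite fast.

## Limitations

* The scan tests over-representation per window; it does not model
  correlated expression within clusters or distinguish tandem duplicates
  from unrelated neighbours.
* The bootstrap preserves list size only, not gene spacing or expression
  level matching.
* Conservation scoring trusts the supplied ortholog tables; one-to-many
  collapse is a heuristic, and paralog-rich clusters will score
  conservatively.
* Flank/body tests treat clusters as independent units; overlapping or
  nearby clusters share flanking sequence and are not de-correlated.
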