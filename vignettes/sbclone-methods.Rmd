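---
title: "Methods: single-cell transposon insertion genotyping and clonal co-occurrence analysis"
author: "sbclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell transposon insertion genotyping and clonal co-occurrence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbclone)
```

## The problem

Sleeping Beauty (SB) transposon mutagenesis screens identify candidate driver
genes by the positions and orientations of transposon insertions, which
integrate exclusively into TA dinucleotides. Bulk sequencing of a tumor
collapses its clonal structure: hundreds of independent insertions in one
gene may come from one clone or from dozens. `sbclone` reconstructs that
structure from barcoded single-cell sequencing of transposon junctions, and
asks a second-order question: do insertions in particular *pairs* of genes
co-occur within the same cells more often than chance would allow?

The package covers the full computational path: a seeded synthetic-data
generator (so every stage is testable without controlled-access tumor data),
read processing, per-cell insertion calling with quality control, subclone
reconstruction from an insertion-site adjacency matrix, driver annotation,
and a structure-preserving permutation test for co-occurring gene pairs.

## Data model

An **insertion site** is a `(contig, TA position, orientation)` triple; the
coordinate is the 0-based position of the T of the TA, shared by both
orientations (SB duplicates the TA on integration, so the two orientations
share one genomic coordinate; orientation is carried separately because it
matters mechanistically but not for the permutation null). A **cell
profile** maps each barcode to its sites with supporting read counts. A
**sample** holds the post-QC cells and the nonredundant union of their
qualifying sites.

## Read processing

Read 1 carries the 16-base cell barcode (first 16 bases; optional whitelist
correction at Hamming distance 1, off by default because the assay as
modeled has no whitelist). Read 2 starts with the transposon tag (inverted
repeat sequence); reads whose tag matches within one substitution at one of
the first five start offsets are trimmed to their genomic flank, all others
are rejected and counted. Flanks are mapped by exact 20-mer seeding with
full-length verification on both strands, and only unique placements are
kept; multi-mapping and unplaced fragments are counted by category. The
junction coordinate must dereference to TA; if the aligned start is off by
up to `snap_tolerance` (default 2) bases the coordinate snaps to the nearest
TA, otherwise the call is rejected. Rejection categories plus kept calls
always sum to the input pair count.

Exact unique placement is the contract the downstream statistics assume; an
external aligner can be plugged through the `map_fun` seam of
`process_reads()` for real libraries with sequencing errors.

## Quality control

A site *qualifies* within a cell when it has strictly more than 9 supporting
reads (`min_reads_per_site = 10`); a cell is kept when it has at least two
qualifying sites (`min_sites = 2`). Both thresholds are exposed. Kept cells
contribute only their qualifying sites downstream by default; sub-threshold
sites of kept cells are preserved in an audit layer
(`keep_subthreshold = TRUE` retains them instead), since the rule defines
qualification per site but is silent on residual low-count sites. The filter
is idempotent and monotone in the read threshold, and the boundary (9 is not
more than 9) is tested explicitly.

## Subclone reconstruction

The adjacency matrix M counts, for every pair of nonredundant sites, the
cells harboring both (diagonal: cells per site). Sites are clustered with
average-linkage agglomerative hierarchical clustering on the normalized
co-occurrence distance

    d(i, j) = 1 - M[i][j] / min(M[i][i], M[j][j]),

with pairs supported by fewer than `min_support = 2` cells forced to
distance 1 so that single doublet artifacts cannot bridge clusters. The tree
is cut at `cut = 0.5`; clusters with fewer than `min_cluster_sites = 2`
sites dissolve into the unclustered pool (the smallest real subclone
observed had 2 sites). The linkage, distance, cut and support threshold were
open choices — the source analysis names only "hierarchical clustering" —
and all are exposed as arguments. On clean data this distance is essentially
0 within a subclone and 1 across subclones, so recovery is exact and
degrades gracefully as noise adds weak off-diagonal support.

Cells are then assigned to the unique subclone whose site set they overlap
(`min_overlap_sites = 1`); cells overlapping two or more subclones are
labeled `MULTI` (doublet suspects, reported rather than discarded), cells
overlapping none are `UNASSIGNED` (in real tumors these are dominated by
cells carrying globally unique private sites). Driver annotation marks each
subclone with the genes from a bulk-derived driver list (FDR <= 0.05) hit by
at least one of its sites under the gene-body-plus-promoter-window
annotation below.

## Gene annotation and the promoter window

A site annotates to a gene when it lies in the gene body `[start, end)` or
within `promoter_window` bases (default 40 000) upstream of the
transcription start, strand-aware: upstream of `start` for `+` genes,
beyond `end` for `-` genes. Whether the published window was upstream-only
or symmetric is not stated; upstream-only is the default here because
activating insertions act from the promoter side, and
`promoter_mode = "symmetric"` is available. Coordinates are 0-based
half-open internally (BED convention); GFF3 input is converted on read. One
interval per gene; transcript isoforms are out of scope.

## Co-occurrence events and the one-event-per-site rule

For a gene pair (A, B), build the bipartite graph whose nodes are the
distinct sites of A and of B (orientations collapsed to coordinates) with an
edge when at least one cell harbors both sites. The event count k is the
size of a **maximum bipartite matching**: each unique site contributes to at
most one event, so a subclone of a thousand related cells sharing one
(a, b) pair counts once, while three subclones with private pairs count
three times. Maximum matching (Kuhn's augmenting paths; instances are tiny)
is deterministic and order-independent, unlike greedy pairing, which is
kept as `method = "greedy"` for sensitivity analysis. A site annotated to
both genes of an overlapping pair is one unique site: it may be used on one
side of the matching only (the count maximizes over side assignments of
shared sites), never paired with itself.

## The permutation null

Each trial replaces the sample's nonredundant sites by TA sites drawn
uniformly *without replacement* from the genome-wide TA index — a bijection,
so distinct sites stay distinct — and rewrites every cell through it. The
cell-site incidence structure (cell count, per-cell multiplicities, site
degree sequences) is exactly preserved: the permuted dataset is isomorphic
to the original as a bipartite graph, so the null keeps the clonal
structure and breaks only the genomic identity of the sites. Replacement
sites are annotated against the same gene universe and promoter window as
the observed data.

Per pair, `c` counts the trials showing at least one co-occurrence event
("single co-occurrence rate") over `n_iter` trials (default 10 000), and

* `p_raw = c / n_iter` (when `c = 0` the value is reported at the
  resolution floor `1/n_iter` and flagged — a bound, not an estimate);
* `p_adj` is the Benjamini-Hochberg step-up adjustment of `p_raw` over all
  evaluated pairs within one sample (the family is per sample because the
  published tables adjust per sample; a pooled family is a caller choice);
* `p_est = p_adj^k` extends the adjusted single-event p-value to the k
  observed independent events (for k = 1 it is `p_adj` itself). It is
  computed from the unrounded `p_adj`; comparisons against printed tables
  round to 3 significant figures.

The result also carries `p_obs`, the Monte-Carlo exceedance p-value of the
observed count (`#{trials with k_trial >= k_obs} / n_iter`, 1 when
`k_obs = 0`). For pairs observed with a single event — the typical case —
`p_obs` equals `p_raw` exactly; it is the quantity whose null distribution
is checked in the calibration test, because `p_raw` alone is a property of
the pair's null rate rather than of the observed data.

Randomness: one master seed; per-trial seeds are derived deterministically,
so runs are reproducible and trials are parallelizable by contract.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode the observed per-tumor regime: 6-16
subclones per sample defined by disjoint TA-site sets, 2-84 sites per
subclone, 19-1250 cells per subclone, singleton cells (default rate 0.05)
carrying never-reused private sites, and doublet barcodes (default rate
0.01, a typical droplet assay figure) merging two subclones. Per-(cell,
site) read counts are negative binomial (`mu = 20`, `size = 10` by default)
because amplification is overdispersed and the tails let tests place counts
on either side of the >9-read threshold; no depth or dispersion figures
were published, so these are stated defaults, not estimates. Genomes are
i.i.d. sequences with letter frequencies set so the expected TA density
matches `ta_enrichment` (default 0.05). A configurable fraction of junk
read pairs lacks the transposon tag. The default transposon tag is an
arbitrary 20-mer: the real inverted-repeat sequence is configuration, not
code.

Not modeled: sequencing errors beyond optional junk reads, PCR chimeras,
ambient contamination, repeat-driven multi-mapping, cross-sample barcode
collisions. Passing the recovery tests therefore shows the algorithms are
correct under the stated generative model, not that the thresholds are
optimal for any particular real library.

## Numerical choices and test scales

Degenerate inputs: a single-site sample yields one trivial cluster or an
empty pool depending on `min_cluster_sites`; an empty post-QC sample is an
error carrying the audit counts; an empty BH family returns an empty
vector; equal genes in a pair query are an error. Tie-breaks: TA snapping
prefers the smaller offset and the left side on ties; matching is
order-independent by construction.

The test suite exercises: subclone recovery on 20 seeded simulations at the
full regime above (profile level, zero read noise, adjusted Rand index
exactly 1 and 100% correct assignment of non-singleton non-doublet cells),
read-level recovery with 5% junk reads on three smaller replicates (6
subclones, 2-10 sites, 19-25 cells — scales chosen so the whole suite runs
on a laptop in minutes), and permutation calibration on a fully null sample
(40 genes, 200 pairs, 400 sites in 40 cell clusters, 2000 trials). The
calibration fraction of null pairs with p < 0.05 sits below the nominal
0.05 (0.015 in the checked-in configuration) because event counts are small
integers: achievable p-values are a discrete set and the test statistic is
conservative between achievable levels, which is the expected behavior of
permutation p-values at finite resolution; the mean null `p_raw` is 0.46,
within sampling noise of the 0.5 expected when null rates span the unit
interval.

## Known limitations

* Exact-match mapping assumes error-free reads; use the aligner seam for
  real data.
* One interval per gene; no isoform-aware promoter definitions.
* No phylogenetic ordering of subclones and no emergence-time inference —
  the data cannot support either.
* The permutation test conditions on the observed cell-site structure; it
  does not model selection acting during tumor growth, only the genomic
  placement of sites.
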