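---
title: "Reference-free smRNA-seq analysis with high-frequency conserved K-mers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free smRNA-seq analysis with high-frequency conserved K-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hckmer)
```

## Motivation and model

Single-microbe RNA sequencing (smRNA-seq) captures the transcripts of
individual microbes in droplets: R1 carries a 20 bp cell barcode followed
by an 8 bp unique molecular identifier (UMI), R2 the cDNA read. The usual
route to an expression matrix — alignment against reference genomes —
breaks down for microbiomes, where references are incomplete and any
pre-selected genome set biases which organisms are even visible.

`hckmer` sidesteps alignment entirely. Every read of length $L$ contains
$L-K+1$ overlapping K-mers; a community's cleaned reads therefore define
a K-mer count spectrum with no reference involved. The key empirical
structure this package exploits is that the spectrum is sharply bimodal:

* **high-frequency conserved K-mers (HCKs)** — K-mers from sequence
  shared across many cells and often across species (rRNA, conserved
  protein-motif coding regions, shared operons). From a taxonomy
  viewpoint these behave like lowest-common-ancestor sequence: the more
  species and cells carry a K-mer, the deeper its total count.
* **low-frequency K-mers** — mostly sequencing errors and rare sequence,
  overwhelmingly observed once. They carry almost no taxonomic signal.

Substituting the gene axis of the canonical cell-by-gene matrix with the
HCK set gives a cell-by-HCK matrix $M_{ji}$ = occurrence count of HCK
$i$ in cell $j$, which then flows through the standard single-cell
toolchain (normalization, PCA, graph clustering, marker detection).

## Pipeline stages and their parameters

### Quality control

`build_whitelist` counts reads per barcode prefix and keeps the deepest
barcodes; `extract_reads` re-headers R2 with `_<barcode>_<UMI>` so every
downstream record carries its 29-character molecule identifier;
`dedup_reads` collapses reads sharing an identifier, keeping the copy
with maximal mean Phred score
$Q_{avg} = \frac{1}{|Q|}\sum_i(\mathrm{ord}(Q_i) - 33)$. The update rule
uses a strict inequality, so among equal-quality copies the first seen
wins — deduplication is deterministic and idempotent.

Parameters: the barcode pattern (`C`*20 + `N`*8 by default, in the
CCCC/NNNN notation of UMI-handling tools), `expect_cells` (caps the rank
curve scanned for the knee, never changes counting; default 10000), and
`set_cell_number` (forces the whitelist size — the recommended mode when
the cell count is known from the experiment, mirroring common practice of
fixing the count at the barcode rank plot's inflection). Barcode matching
is exact: no 1-mismatch correction is attempted, which keeps dedup
semantics crisp but will drop reads whose barcode was missequenced — a
documented limitation.

### K-mer spectrum and the optimal K

`count_kmers` counts every window containing only A/C/G/T; windows
touching any other symbol are skipped entirely so no phantom K-mers
arise. Counting is forward-strand by default because the input is
stranded cDNA; `canonical = TRUE` pools reverse-complement pairs for
users who want canonical semantics. Counting is exact (a hash of actual
windows), not probabilistic.

The default K is 12. The `select_optimal_k` rule makes the choice
data-driven: the smallest K whose frequency histogram peaks at count
$x = 1$. At ~1x random-primed coverage, K just large enough that random
K-mers stop colliding produces a singleton-dominated histogram; smaller K
over-collapses distinct sequence, larger K fragments conserved signal
into needlessly specific features.

### HCK selection at the rank-curve knee

K-mers are sorted by count (descending; ties broken lexicographically so
results are platform-independent), and the rank curve plots the
cumulative mean count of the top-$x$ K-mers. `knee_point` transforms rank
and cumulative mean to log10 scales, takes adjacent-point first-order
differences with no smoothing, restricts attention to the central 80% of
the **log-rank range** (excluding the first and last 10% of the decades
spanned, where single-step slopes are dominated by grid spacing and tail
noise), and returns the rank at the first slope of maximal absolute
value. Slopes within a $10^{-9}$ relative tolerance of the maximum are
treated as tied (exactly tied slopes differ by float noise after the
log/division round trip) and the earliest wins.

Defining the window on the log-rank range rather than on raw rank indices
matters: on a rank axis spanning many decades, the central 80% of
*indices* is a thin slice of the last decade and can exclude the knee
region entirely, whereas the central 80% of the *log range* covers the
decades where a knee can meaningfully occur. The same detector serves the
barcode rank curve in whitelisting.

`select_hck` keeps the top-$N$ K-mers ($N$ defaulting to the knee rank,
user-overridable via `topkmer`) and reports for each its total count
$T_k = \sum_i C_{i,k}$ and read incidence
$A_k = \sum_i \mathbb{1}(C_{i,k} > 0)$, with $1 \le A_k \le T_k$.

### The cell-by-HCK matrix

`build_cell_matrix` groups reads by barcode, counts sliding-window
matches of each HCK per cell (overlapping matches all count, matching the
indicator-sum definition of the per-cell sequence vector), and processes
cells in chunks of 1000 whose partial matrices are merged — the result is
provably independent of chunk size and read order, which the tests assert.
Cells with no HCK content are kept as explicit zero columns so columns
stay aligned with the whitelist. UMIs are *not* re-collapsed here:
deduplication already ran upstream, and $M_{ji}$ is an occurrence count,
not a binary presence.

### Clustering and quality metrics

`log_normalize` computes $\ln(1 + s\,c/t)$ with scale factor
$s = 10^4$; zero counts stay exactly zero and the transform is invariant
to scaling a cell's counts. `select_variable_features` keeps the 6000
highest-variance features. PCA runs on per-feature z-scores clipped at
+10 (a guard against single-cell outliers dominating a component);
constant features are dropped; components whose singular value is below
$10^{-8}$ of the leading one are treated as null rank; each component's
sign is fixed so its largest-magnitude loading is positive, making the
embedding fully deterministic. The 6000 selected features (not all
features) feed PCA; scaling everything instead is available by passing
`features = rownames(norm)`.

`snn_cluster` builds a k-nearest-neighbour graph (k = 20, Euclidean
distance in the 30-PC embedding, each neighbour set including the cell
itself), weights edges by Jaccard overlap of neighbour sets, prunes
weights below 1/15, and runs Louvain modularity optimization at
resolution 0.5 under a fixed seed. Labels are relabelled 0..C−1 by
decreasing cluster size. Davies–Bouldin index and silhouette coefficient
are computed in the same PC embedding the clustering saw; a singleton's
silhouette is defined as 0.

### Taxonomic annotation

Per-read classifications (a 5-column classifier read-output table; only
read id and taxon id are used, minimizing coupling to classifier
versions) are aggregated per cell leaf-to-root over a 4-column taxonomy
table, then a greedy root-to-leaf descent follows the heaviest child
(ties to the lexicographically smallest name) down to species rank. The
call's confidence, `fraction_total_reads`, is the species' cumulative
reads divided by the cell's total reads *including* unclassified ones — a
deliberately conservative denominator, since the source field is produced
externally and its denominator is not pinned down. Cells pass only with
fraction strictly greater than 0.5; species annotating fewer than 0.1% of
fraction-passing *cells* (cells, not reads: the natural basis in a
single-cell context) are failed community-wide. The external classifier's
Bayesian abundance redistribution is not reimplemented; the fraction here
is exact whenever reads classify at species level.

### Markers, motifs and enrichment

`find_markers` tests each cluster against all other cells with a
two-sided Wilcoxon rank-sum test, the default test of the single-cell
toolchain this stage mirrors. Features must be expressed in at least 25%
of one side (`min_pct`), show $\ln$ fold change
$\ln(\overline{\mathrm{expm1}(x_{in})}+1) -
\ln(\overline{\mathrm{expm1}(x_{out})}+1) \ge 0.25$, and only positive
markers are kept; Bonferroni correction runs over features × clusters
tests (configurable in spirit — the raw p-values are returned alongside).

Marker K-mers export two ways: `write_meme_motifs` writes each as a
one-hot position-weight matrix in MEME minimal format (K-mers containing
N are rejected: motifs must be unambiguous), and `six_frame_translate`
translates all six reading frames, retaining only peptides of the full
length $K/3$ (frames +1/−1 for K = 12; other offsets cannot yield 4
complete codons) without stop codons — a stop-containing 4-mer cannot
match a protein motif. Downstream database searches (motif comparison,
domain scanning) consume these standard files externally; the package
resumes from a motif→GO mapping table and computes exact hypergeometric
upper-tail enrichment with Benjamini–Hochberg adjustment.

## The synthetic community generator

`simulate_community` is first-class, tested code and defines the
package's reference study conditions (see `sim_config`): 5 species × 50
cells × 200 reads per cell, 100 bp reads from 1 kb circular genomes
(≈20x per-cell coverage of the expressed sequence space), three 60 bp
conserved blocks implanted verbatim in every genome plus one 60 bp
species-specific marker block, 10% PCR duplication, 0.1% per-base
substitution error, and 500 empty-droplet barcodes at a fixed depth of 2
reads. Qualities are uniform Phred 30–40 for originals and 20–40 for PCR
copies, so the maximal-quality dedup rule is genuinely exercised.

Construction guarantees, enforced by regeneration: every K-mer occurs at
most once within a genome, so a K-mer's total depth is proportional to
the number of species carrying it; marker-block K-mers occur in exactly
one species. The ground truth records, besides the planted blocks, the
set of K-mers present in ≥2 genomes — the *conserved* set. This includes
block-edge windows that species share by chance through matching
flanking bases; they are genuinely cross-species-conserved sequence and
sit at intermediate depth, and treating them as such is what makes the
knee's position an exact, structural prediction rather than an
approximate one.

Deliberate simplifications: substitution-only errors (no indels — K-mer
analyses are substitution-dominated and analytic expectations stay
closed-form), no transcript structure (reads sample the genome directly,
matching the random-primer ~1x coverage rationale), no doublets or
ambient RNA in cell droplets, flat duplication with no amplification
bias, and circular genome sampling (linear sampling would leave coverage
ramps at the ends whose K-mers form an artificial low-count tail;
bacterial chromosomes are circular anyway). UMIs are drawn without
replacement within a cell so barcode+UMI identifies a molecule uniquely.
Passing tests on this generator therefore demonstrates algorithmic
correctness under controlled conditions, not robustness to the full mess
of real libraries (indels, barcode missequencing, chimeras, expression
heterogeneity within species).

## What the recovery checks assert, and under which regime

Exact-recovery statements are made in the **noise-free regime**
(`error_rate = 0`): the planted all-species block K-mers are exactly the
top of the rank curve, and the knee rank equals the size of the conserved
(≥2 species) set with set equality. With substitution errors on, error
K-mers observed twice or more sit between the genomic plateau and the
count-1 tail and shift the maximum-slope position deeper into the curve
by their number — so under noise the honest guarantee, also tested, is
containment: the conserved set is a subset of the HCKs at the knee. The
end-to-end recovery suite (clustering against true species, annotation of
fraction-passing cells, marker K-mers from the planted specific blocks)
runs at the reference study conditions with the whitelist forced to the
true cell count, and builds the matrix with `topkmer = 6000` so that
species-specific K-mers — the substrate of marker detection — are
features alongside the conserved ones.

Problem sizes were chosen so the whole suite runs comfortably on a
single CPU: the reference community is 250 cells and 50000 molecules
(~4.5M windows at K = 12), module tests use 2–3 species at 10–20 cells,
and oracle-equivalence suites run 100 randomized small instances per
operation (Wilcoxon enumeration at group sizes 4–8, hypergeometric
backgrounds ≤30, PCA on matrices up to 7×12).

## Known limitations

* Exact barcode matching (no error-correction network for barcodes or
  UMIs) trades sensitivity for crisp dedup semantics.
* `fraction_total_reads` is a proxy for the external classifier's
  abundance re-estimate; they agree when reads classify at species level
  but can differ when much of a cell's signal stops at higher ranks.
* The knee is a global maximum-slope statistic: on curves without a
  clear two-regime structure (e.g. smooth power laws) its position is
  data-noise sensitive, and on noisy plateaus it lands at the boundary of
  the noise floor rather than at any biologically privileged rank.
* In-memory counting: the hash of distinct K-mers and the window table
  must fit in RAM; the design targets desk-scale data, not billions of
  distinct K-mers.
* Functional annotation stops at standard interchange files (MEME
  motifs, peptide FASTA, GO mapping tables); database searches are out of
  scope, so GO conclusions inherit whatever mapping the user supplies.
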