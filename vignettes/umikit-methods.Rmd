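---
title: "umikit: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{umikit: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umikit)
```

umikit implements the computational core of plate-based, cell-barcoded
single-cell RNA-seq with unique molecular identifiers (UMIs): barcode code
design, error-correcting demultiplexing, UMI counting, quantitative quality
metrics, cluster-level expression statistics, and cell-cycle-aware variable
gene classification, together with a ground-truthed simulator that makes
the whole pipeline testable without sequencing data. This vignette records
the models behind each step, the parameters that matter, and the choices we
made where the design was genuinely open.

## 1. Sequence-Levenshtein barcode codes

In these libraries the cell barcode sits at the start of read 1 and is
immediately followed by the UMI and a poly(T) stretch. An insertion or
deletion inside the barcode therefore shifts everything downstream: the
observed prefix of the read is no longer the barcode itself but a frame-
shifted version of it. The plain Levenshtein distance between barcodes
overstates the separation of such codes. The Sequence-Levenshtein (SL)
distance repairs this: build the unit-cost Levenshtein dynamic-programming
matrix $D$ of size $(|a|+1)\times(|b|+1)$ and take

$$ d_{SL}(a,b) \;=\; \min\Big(\min_j D[|a|,j],\; \min_i D[i,|b|]\Big), $$

the minimum over the last row and last column, modelling that an alignment
may stop early because the rest of the read supplies arbitrary continuation
bases. $d_{SL}$ is symmetric, zero on the diagonal, bounded above by the
Levenshtein distance, and **not** a metric (the triangle inequality can
fail), which is why `verify_set()` always checks pairs exhaustively rather
than pruning through intermediate sequences. A code with minimum pairwise
SL distance $2e+1$ decodes uniquely under up to $e$ edits; the shipped
default (distance 5) corrects two errors of substitution, insertion, or
deletion, and the `tests/` suite checks the edit-ball disjointness
explicitly.

**Code generation.** `generate_candidates()` draws random k-mers under a
fixed seed, applies composition filters, and greedily accepts a candidate
iff its SL distance to every accepted sequence is at least the design
minimum, within an attempt budget (default $10^6$ draws). Random greedy
closure is simple, reproducible, and mirrors the two-phase
"create candidates, then select" structure used for the published 384- and
1536-barcode primer sets. The published candidate pool sizes (1582 and
4714) depend on the internals of the external generator that produced them
and are not reproducible from first principles; the shipped designer
instead grows a pool of `pool_factor` (default 1.15) times the requested
set size, which leaves the balancing step genuine room to choose.

**Composition filters.** The source protocol states no explicit filters.
We reject homopolymer runs of 4+ and GC fractions outside [0.3, 0.7] —
standard primer-design hygiene — and both are configurable or can be
switched off (`composition_filters(none = TRUE)`).

**Composition balancing.** The selection objective is the variance over
the four bases of the aggregate base frequencies pooled over all positions
and sequences (a scalar; 0 means perfect 25/25/25/25 composition). The
published description says only that sequences were selected "so that the
variance of base composition decreased"; whether that variance was pooled
or per-position is unknowable from the text, so the pooled scalar was
chosen and isolated behind `composition_variance()` where a per-position
objective could be swapped in. Minimization is greedy exchange — repeatedly
apply the best single in/out swap until no swap improves — started from
**five** seeded random subsets, keeping the best local optimum. A single
start provably stalls above the optimum on small instances (our exhaustive
C(8,4) oracle test catches exactly this), and multi-start preserves the
mechanism, determinism, and runtime while fixing it. Ties anywhere in the
designer are broken by lexicographic sequence order.

## 2. Demultiplexing and error correction

`correct_barcode()` decodes the first `length + max_dist` bases of read 1
(22 sequencing cycles carry a 14-nt barcode and 8-nt UMI exactly, so a
2-edit decoder needs a window of 16 from a longer read or works with what
a 22-cycle read provides). The decoding distance of barcode $b$ against
window $w$ is $\min_j \mathrm{Lev}(b, w_{1..j})$ — the barcode must be
fully consumed, the window only partially — and the minimizing $j$ is the
*consumed length*, which locates the first UMI base after net indels. Ties
in $j$ prefer the value closest to the barcode length.

Two consequences are worth recording. First, a read whose corrupted
barcode plus UMI no longer fits in read 1 (a net insertion in a 22-cycle
read) is rejected rather than padded: fabricating UMI bases would create
phantom molecules. Second, an edit at the barcode/UMI boundary can be
absorbed by a matching UMI base (deleting the last barcode base is
invisible when the first UMI base equals it), so a small fraction of
corrected reads carry a UMI shifted by one. This is an inherent ambiguity
of indel decoding, not an implementation artifact; the tests quantify it
(> 90% of UMIs exactly recovered under forced single edits) and barcode
identity itself is never affected.

Reads are gated on quality before correction (any barcode/UMI base below
Phred 10 by default, following the convention of the plate/droplet
demultiplexing tools this mirrors), and `assigned + uncorrectable +
low_quality` always equals the input read count. Pool (index) barcodes are
routed with one tolerated mismatch, which is unambiguous because the pool
table is required to be pairwise Hamming distance ≥ 3.

## 3. UMI counting and normalization

`count_umis()` collapses gene-tagged reads per (cell, gene) either by
exact distinct UMIs or by single-linkage merging of UMIs within Hamming
distance 1 (the default, mirroring the behaviour of the established
digital-expression tools; sequencing errors in the UMI otherwise inflate
molecule counts). Whether the published matrices used Hamming-1 collapse
or exact counting is not stated in the source; both are provided, and the
exact mode doubles as the oracle in tests. Counting is order-invariant and
`hamming1 ≤ exact` entrywise by construction.

Cells enter the matrix only through the barcode whitelist — the plate
design fixes the cell set, so no knee-point inference is attempted.
`filter_cells()` applies the detected-gene threshold inclusively (4000
genes for deeply sequenced cell-line plates, 500 for tissue are the
published working points). `normalize_dge()` scales each cell to a common
total (10,000 or the mean total), adds one, takes the natural log, and
optionally z-scales each gene; the identity
`colSums(expm1(values)) == scale_target` is tested to float precision.
Mitochondrial content is reported per cell (`mito_fraction()`) but no
filtering judgment is attached to it.

## 4. Quantitative metrics

**UMI conversion efficiency** is the fraction of a cell's initial fastq
reads that survive into the final matrix as UMI counts:
$\mathrm{eff} = \mathrm{UMI}_{sc} / (\mathrm{fastq}_{sc} +
\mathrm{fastq}_{non\text{-}sc})$, where the denominator includes byproduct
reads (adaptor artifacts, empty wells) attributed to the cell. By default
initial reads are attributed as an equal share of the run total — matching
how per-well read budgets are quoted — with per-cell tallies from
demultiplexing available instead. On simulated data the metric is a pure
bookkeeping identity and is tested as such. For orientation: 11,000 UMIs
from 24,000 reads is 45.8% efficiency; the same UMIs from 169,000 reads is
6.5%, i.e. a sevenfold read requirement.

**ERCC capture efficiency** is the slope, through the origin, of mean
detected UMI count per cell against input spike-in molecules per well
across species. The intercept is physically zero (no input molecules, no
capture), hence the through-origin form; the per-species response uses the
mean across cells by default (`stat = "sum"` is the alternative dialect).
On Binomial($m_i$, $p$) simulations the estimator recovers $p$ within
sampling error and is unbiased over replicates.

**Copy number at 50% detection** fits a Bernoulli logistic regression of
per-cell detection (count > 0) on $\log_{10}$ input molecules by maximum
likelihood and solves $m_{50} = 10^{-\beta_0/\beta_1}$. The observed
detection fractions must bracket 0.5, and the fitted slope must be
positive, otherwise the fit errors out with the observed range. Binomial
thinning of the counts (read downsampling) demonstrably raises $m_{50}$.

The package ships no real spike-in concentration table;
`synthetic_ercc_reference()` is an explicitly synthetic stand-in (92
species log-spaced over 0.05–20,000 copies per well) reproducing only the
qualitative structure of a commercial mix.

## 5. Differential expression and markers

`deg_deviance_test()` fits, per gene, a null and an alternative count GLM
(single mean vs group-specific means) with a per-cell log-total offset,
and refers the deviance difference to $\chi^2_1$. The family is a genuinely
open choice — the source says only "generalized linear model" — and we
declare Poisson with log link: it makes the deviance difference equal the
closed-form two-sample Poisson likelihood-ratio statistic, which gives the
test suite an independent oracle (agreement to $10^{-8}$ on random
instances), and a negative-binomial family with fixed dispersion is
available (`family = "nb"`). Under NB-distributed data the Poisson LR is
anti-conservative; the null-calibration guarantee is stated for the
Poisson world it tests.

The noise prefilter follows the published order: pseudocount 1 on the
depth-normalized cluster means, fold change ≥ 2 required *before*
Benjamini–Hochberg correction, significance at FDR < 0.05. The
no-pseudocount variant used for bulk comparisons is `pseudocount = 0`.
The named correction is BH (the source says only "corrections for multiple
testing"); it is configurable. A subtlety the tests document: because the
prefilter is a hard threshold on a shrunk fold change, genes whose true
pseudocounted fold change sits near 2 drift in and out of the tested set
as group means converge, so detection-power monotonicity is only asserted
for effects clearly beyond the threshold.

`binomial_marker_test()` evaluates cluster markers by the exact binomial
tail $P(X \ge k \mid n_{in}, p_0)$ with $p_0$ the outside detection
fraction, floored at $1/(n_{out}+1)$ (and flagged) when the gene is never
seen outside, since a zero null probability would make any inside
detection infinitely significant.

## 6. Cell-cycle-associated variable genes

Cells of one cell type are ranked by Hoechst 33342 intensity (a DNA-content
proxy that orders cells G1 → S → G2/M) and split into 40 equal-sized bins
(remainder cells go one-per-bin to the lowest-intensity bins; ties in
intensity break by stable input order; only ranks matter, so any monotone
transform of intensity gives identical bins). For each gene two
coefficients of variation are computed: across cells (`cell_cv`) and
across the 40 bin means (`bin_cv`). Both are z-scaled over all genes with
nonzero mean. Genes with $z_{bin} \ge 2$ are *cell-cycle associated* —
their average expression tracks DNA content — and, among the rest, genes
with $z_{cell} - z_{bin} \ge 2$ are *variable but less associated with the
cycle*. The z→CV mapping (mean + z·sd of the bin-CV distribution) is
reported alongside the counts, and counts are nested across z ∈ {1,2,3,4}
by construction.

Open choices, resolved as follows: the z-scaling population is all genes
passing the zero-mean exclusion (no reference population is stated in the
source); `diff_threshold` defaults to 2 on the same z scale ("large" is
all the source says); and counts are depth-normalized before binning by
default so sequencing depth cannot masquerade as cycle signal, with
`normalize = FALSE` available as the literal reading.

A quantitative caveat the tests make explicit: the bin CV of a
cycle-independent gene is sampling noise of the bin means, roughly
$\mathrm{CV}_{cell}/\sqrt{n/40}$. With few cells per bin, genuinely bursty
genes can exceed the $z_{bin}$ threshold and be mis-labelled as
cycle-associated; with ~50+ cells per bin a CV ≈ 0.6 burst separates
cleanly. This is a property of the published rule itself, not of this
implementation, and is the reason the classification was originally run on
thousands of cells.

## 7. The synthetic world

`sim_config()` fixes the stated world the pipeline is tested in. Where the
source quantifies a condition we use it verbatim; the remaining defaults
were chosen once, a priori, for realism:

* **Cluster structure**: two clusters, 23.6% of genes differentially
  expressed with |log2 fold changes| from gamma(shape 1.02, rate 0.78)
  with random sign — the parameters estimated from bulk embryonic-stem /
  primitive-endoderm RNA-seq and used for published power analysis.
* **Gene means**: lognormal, meanlog log 6, sdlog 0.6. Deeply sequenced
  wells yield ≈ 44,100 UMIs over ≈ 7,400 detected genes, i.e. ≈ 6 counts
  per detected gene; the generator emulates this *detected-gene regime*
  and deliberately omits the long tail of near-zero genes present in real
  data (a stated limitation: green tests certify behaviour on adequately
  expressed genes, not on dropout-dominated ones).
* **Noise**: negative binomial with size 20 — technical variability of
  these libraries is close to Poisson, and within-cell-type biological
  dispersion adds modestly on top. Heterogeneity beyond that is modelled
  explicitly by the planted gene classes rather than by inflating global
  dispersion.
* **Cycle program**: 5% of genes scale their mean linearly with DNA
  content in [1, 2] (doubling from G1 to G2/M). DNA content follows an
  *embryonic* mixture G1/S/G2M = 0.25/0.25/0.5 (G2M-dominant, as observed
  for ES cells) or a *somatic* 0.6/0.2/0.2 mixture. Hoechst intensity is
  content × lognormal noise (sdlog 0.05).
* **Bursty genes**: 1% of genes get NB size 0.3 independent of the cycle —
  "tens" of such genes among thousands is what cell-type-resolved data
  show.
* **Reads**: each molecule draws a UMI uniformly from the 4^8 space
  (`unique_umis = TRUE` switches to collision-free assignment, defining
  the zero-noise identity mode used by the end-to-end test) and a
  geometric number of PCR duplicates with mean 5; per-read barcode error
  rates default to 0.5% substitution, 0.1% insertion, 0.1% deletion, which
  exercises the full correction radius; 5% of reads are barcode-less
  byproducts. Read 1 defaults to barcode + UMI cycles (the 22-cycle
  format), so net-insertion reads lose their last UMI base and are
  rejected by the pad policy — faithful to the sequencing format.

Everything is a deterministic function of (config, seed), and all emitted
artifacts (FASTQ, gene-tagged tables, flow tables) are re-derivable from
the ground-truth object. What a green test establishes: the pipeline's
bookkeeping, error-correction radius, estimator recovery, and
classification behaviour in this world. What it does not: performance
under real dropout structure, ambient RNA, doublets, or alignment error,
none of which the generator emulates.

## 8. Numerical and runtime notes

* The SL dynamic program is implemented in C++ with early abandonment
  (row minima of the DP matrix are non-decreasing), making the exhaustive
  1536² pairwise verification ≈ 6 s and the full 1536-barcode design
  ≈ 50 s on one CPU.
* GLM fits use `glm.control(epsilon = 1e-12)` so deviance differences are
  comparable to the closed-form oracle at 1e-8.
* Degenerate inputs are first-class: zero-total cells error with a pointer
  to `filter_cells()`; all-zero genes are excluded and reported; detection
  curves refuse to extrapolate an $m_{50}$ outside the observed range;
  decoder ties (impossible for a verified code, possible for a corrupt
  one) return "no decode" rather than guessing.
* Simulation scales in tests are desk-scale stand-ins (hundreds of cells,
  ~10³ genes) chosen to keep the suite under a few minutes; the statistics
  they check are scale-free or carry explicit sampling-error bands.
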