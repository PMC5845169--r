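# umikit

Error-correcting cell barcodes and UMI-based expression analysis for
plate-based single-cell RNA-seq.

## The problem

High-throughput plate-based single-cell RNA-seq tags every cDNA molecule
with a **cell barcode** (identifying the well/cell, 14 or 15 nt) and a
**UMI** (an 8-nt random tag identifying the molecule), pools up to 1536
cells into one library, and sequences the barcode+UMI in read 1 and the
transcript in read 2. Sequencers are the scarce resource: the fraction of
initial fastq reads that survive into the final expression matrix as UMI
counts — the *UMI conversion efficiency* — decides how many cells a run can
serve. Two computational ingredients matter: barcodes robust to sequencing
errors **including indels** (an indel shifts everything downstream of the
barcode), and careful accounting from raw reads to deduplicated molecule
counts.

umikit implements that computational core for analysts and method
developers:

* **Barcode design** under the Sequence–Levenshtein (SL) distance — the
  minimum over the last row and column of the Levenshtein DP matrix
  $D_{(|a|+1)\times(|b|+1)}$:
  $d_{SL}(a,b)=\min(\min_j D[|a|,j], \min_i D[i,|b|])$. A code with
  minimum pairwise $d_{SL} \ge 2e+1$ corrects $e$ errors of substitution,
  insertion, or deletion; the shipped designs use distance 5 ($e=2$),
  balanced for base composition, verified exhaustively.
* **Demultiplexing**: indel-aware decoding of observed read-1 windows
  against the barcode set, with the consumed alignment length relocating
  the UMI, Phred quality gating, and pool (index) barcode routing.
* **Counting**: UMI collapse per (cell, gene) — exact distinct UMIs or
  Hamming-1 single-linkage components — into a sparse digital expression
  matrix; cell filtering by detected genes; log-normalization
  (`ln(1 + counts/total * 10000)`) with optional per-gene scaling.
* **Quality metrics**: UMI conversion efficiency
  $\mathrm{UMI}_{sc}/(\mathrm{fastq}_{sc}+\mathrm{fastq}_{non\text{-}sc})$;
  ERCC spike-in capture efficiency (through-origin slope of detected UMIs
  vs input molecules); spike-in copy number at 50% detection probability
  (logistic fit in log10 molecules).
* **Expression statistics**: per-gene deviance (likelihood-ratio) test
  between clusters from nested Poisson GLMs with depth offsets
  ($\Delta\mathrm{deviance} \sim \chi^2_1$), fold-change-2 prefilter with
  pseudocount, BH-FDR; exact binomial cluster-marker tests.
* **Cell-cycle classification**: 40 rank bins of per-cell Hoechst 33342
  (DNA content) intensity; genes with high z-scored bin-CV are
  *cell-cycle-associated*, genes with high cell-CV but low bin-CV are
  *variable but less cycle-associated*.
* **Simulation**: a seeded, ground-truthed generator of cells, molecule
  counts, FASTQ-like reads (with injected barcode errors, PCR duplicates,
  byproduct reads), ERCC spike-ins, and flow-cytometry metadata, so every
  claim above is testable offline.

## Worked example

```r
library(umikit)

# design and verify a 96-barcode, 2-error-correcting code
set <- design_barcode_set(length = 14, n = 96, min_distance = 5, seed = 1)
print(set)
print(verify_set(set))

# simulate a plate (two clusters, ERCC spike-ins), emit and demux reads
cfg <- sim_config(n_cells = 96, n_genes = 400, duplication_mean = 3,
                  ercc = synthetic_ercc_reference(24, 1, 2000))
truth <- simulate_cells(cfg, seed = 1)
reads <- emit_reads(truth, set, seed = 1)
tagged <- tag_reads(reads$reads, set)
st <- demux_stats(tagged)

# count UMIs and compute the quantitative metrics
mat  <- count_umis(reads$tagged, collapse = "hamming1",
                   cells = sort(unname(reads$barcode_map)))
conv <- umi_conversion_efficiency(nrow(reads$reads), mat)
cap  <- ercc_capture_efficiency(mat, synthetic_ercc_reference(24, 1, 2000))
m50  <- molecules_at_half_detection(mat, synthetic_ercc_reference(24, 1, 2000))

# differential expression between the two simulated clusters
cl  <- split(truth$cells$cell_id, truth$cells$cluster)
bcs <- reads$barcode_map
deg <- deg_deviance_test(mat, bcs[cl[[1]]], bcs[cl[[2]]])
```

Output:

```
barcode_set: 96 sequences of length 14 (design min SL distance 5)
  composition variance: 0
barcode set verification: PASS
  min observed pairwise SL distance: 5 (required >= 5)
assigned 1117833 / 1177634 reads (6820 corrected at distance 1, 68 at distance 2)
dge_matrix: 424 genes x 96 cells, 370883 total counts
  median per-cell total 4074, median genes per cell 400
UMI conversion efficiency: 31.49% +/- 3.79% (n = 96 cells)
ERCC capture efficiency: 4.95% (24 species, mean response)
spike-in copy number at 50% detection: 10.98 molecules
45 of 424 genes significant at FDR < 0.05 (fold change >= 2)
of which 44 are among the 102 planted DE genes
```

Reading it: the designed code is perfectly base-balanced (composition
variance 0) and exhaustively verified at SL distance 5. Demultiplexing
assigns 95% of reads (the missing 5% are the simulated barcode-less
byproduct reads), correcting ~6.9k reads carrying injected barcode errors.
The measured conversion efficiency (31.5%) reflects the simulated
duplication and byproduct load; the ERCC capture estimate (4.95%) recovers
the simulated 5% per-molecule capture probability; and the deviance test
calls 45 genes at FDR < 0.05 with 44 of them truly differentially
expressed (the planted fraction whose fold change survives the
pseudocounted prefilter).

## Command line

```sh
Rscript inst/cli/umikit.R design --length 14 --min-dist 5 --n 384 --seed 1 --out barcodes.tsv
Rscript inst/cli/umikit.R verify --barcodes barcodes.tsv --min-dist 5
Rscript inst/cli/umikit.R demux --r1 R1.fq.gz --barcodes barcodes.tsv --qual 10 --out demux/
Rscript inst/cli/umikit.R count --tagged tagged.tsv --collapse hamming1 --out matrix/
Rscript inst/cli/umikit.R qc --matrix matrix/ --initial-reads 2000000 --ercc ercc.tsv --out qc.json
Rscript inst/cli/umikit.R deg --matrix matrix/ --clusters clusters.tsv --a 1 --b 2 --out deg.tsv
Rscript inst/cli/umikit.R cellcycle --matrix matrix/ --flow flow.tsv --bins 40 --z 2 --out var.tsv
```

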