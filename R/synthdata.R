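#' Simulation configuration
#'
#' Collects the parameters of the ground-truthed generator. Defaults encode
#' the stated world the pipeline is tested in: two clusters with 23.6% of
#' genes differentially expressed at log2 fold changes drawn from a
#' gamma(shape 1.02, rate 0.78) with random sign (the estimate from bulk
#' embryonic-stem/primitive-endoderm RNA-seq used for simulation-based
#' power analysis); a 5% fraction of genes whose mean scales linearly with
#' DNA content in \[1, 2\] (doubling from G1 to G2/M); a 1% fraction of
#' cycle-independent overdispersed ("bursty") genes, matching the tens of
#' such genes found among thousands; negative-binomial noise close to
#' Poisson (size 20), as plate-based technical variability is near-
#' Poissonian; gene means lognormal around 6 counts (about 44,100 UMIs over
#' about 7,400 detected genes per deeply sequenced cell); ERCC spike-ins
#' captured with per-molecule probability 0.05; and a read model with
#' geometric PCR duplication (mean 5 reads per molecule) and per-read
#' barcode error rates of 0.5% substitution, 0.1% insertion, 0.1% deletion.
#'
#' @param n_cells Number of cells (default 384, one plate).
#' @param n_genes Number of endogenous genes (default 1000; a desk-scale
#'   stand-in for the ~7000 detected in real data).
#' @param gene_mean_meanlog,gene_mean_sdlog Lognormal parameters of the
#'   per-gene base mean counts.
#' @param nb_size Negative-binomial size (inverse dispersion) of ordinary
#'   genes.
#' @param cluster_props Cluster mixing proportions (defines the number of
#'   clusters).
#' @param de_fraction Fraction of genes differentially expressed between
#'   clusters 1 and 2 (default 0.236).
#' @param de_lfc_shape,de_lfc_rate Gamma parameters of the absolute log2
#'   fold changes (defaults 1.02 and 0.78).
#' @param cycle_fraction Fraction of genes whose mean scales with DNA
#'   content (default 0.05).
#' @param noisy_fraction,noisy_size Fraction and NB size of bursty,
#'   cycle-independent variable genes (defaults 0.01 and 0.3).
#' @param dna_pattern `"embryonic"` (G1/S/G2M weights 0.25/0.25/0.5, the
#'   high-G2M pattern of embryonic cells) or `"somatic"` (0.6/0.2/0.2);
#'   recycled over clusters.
#' @param hoechst_noise_sdlog Lognormal sdlog of the measurement noise
#'   multiplying DNA content to give Hoechst intensity (default 0.05).
#' @param ercc Spike-in reference data.frame (`ercc_id`,
#'   `molecules_per_well`); default [synthetic_ercc_reference()]. `NULL`
#'   disables spike-ins.
#' @param ercc_capture Per-molecule spike-in capture probability
#'   (default 0.05).
#' @param umi_len UMI length (default 8).
#' @param duplication_mean Mean reads per molecule, geometric (default 5).
#' @param sub_rate,ins_rate,del_rate Independent per-read probabilities of
#'   injecting one barcode substitution / insertion / deletion.
#' @param byproduct_fraction Fraction of emitted reads that are
#'   non-single-cell byproducts carrying no valid barcode (default 0.05).
#' @param read1_len Read-1 length in cycles; default
#'   `barcode_length + umi_len` (the 22-cycle format for 14-nt barcodes).
#' @param barcode_length Cell-barcode length used when no explicit barcode
#'   set is given to the emitters (default 14).
#' @param pool_barcodes Named character vector of 6-nt pool barcodes; cells
#'   are split across pools evenly.
#' @param unique_umis If `TRUE`, molecules of the same (cell, gene) receive
#'   distinct UMIs (the collision-free, zero-noise identity mode).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 384L, n_genes = 1000L,
                       gene_mean_meanlog = log(6), gene_mean_sdlog = 0.6,
                       nb_size = 20,
                       cluster_props = c(0.5, 0.5),
                       de_fraction = 0.236,
                       de_lfc_shape = 1.02, de_lfc_rate = 0.78,
                       cycle_fraction = 0.05,
                       noisy_fraction = 0.01, noisy_size = 0.3,
                       dna_pattern = "embryonic",
                       hoechst_noise_sdlog = 0.05,
                       ercc = synthetic_ercc_reference(),
                       ercc_capture = 0.05,
                       umi_len = 8L, duplication_mean = 5,
                       sub_rate = 0.005, ins_rate = 0.001, del_rate = 0.001,
                       byproduct_fraction = 0.05,
                       read1_len = NULL, barcode_length = 14L,
                       pool_barcodes = c(pool01 = "ATCACG"),
                       unique_umis = FALSE) {
  probs <- c(de_fraction, cycle_fraction, noisy_fraction, ercc_capture,
             sub_rate, ins_rate, del_rate, byproduct_fraction)
  stopifnot(all(probs >= 0 & probs <= 1), all(cluster_props > 0),
            n_cells >= 0, n_genes >= 1, duplication_mean >= 1)
  cfg <- as.list(environment())
  cfg$cluster_props <- cluster_props / sum(cluster_props)
  cfg$dna_pattern <- rep_len(dna_pattern, length(cluster_props))
  if (is.null(read1_len)) cfg$read1_len <- barcode_length + umi_len
  structure(cfg, class = "sim_config")
}

#' Synthetic spike-in reference table (stand-in for a commercial mix)
#'
#' A synthetic stand-in for an external-RNA spike-in reference: `n_species`
#' species log-spaced in input copies per well between `min_molecules` and
#' `max_molecules`. It is not the published concentration table of any
#' commercial mix; it reproduces only the qualitative structure (many
#' species spanning several orders of magnitude of abundance).
#'
#' @param n_species Number of spike-in species (default 92).
#' @param min_molecules,max_molecules Copies-per-well range (defaults 0.05
#'   and 20000).
#' @return A data.frame with `ercc_id` and `molecules_per_well`.
#' @export
synthetic_ercc_reference <- function(n_species = 92L, min_molecules = 0.05,
                                     max_molecules = 2e4) {
  data.frame(
    ercc_id = sprintf("ERCC-%05d", seq_len(n_species)),
    molecules_per_well = 10 ^ seq(log10(min_molecules), log10(max_molecules),
                                  length.out = n_species),
    stringsAsFactors = FALSE)
}

.dna_weights <- function(pattern) {
  switch(pattern,
         embryonic = c(G1 = 0.25, S = 0.25, G2M = 0.5),
         somatic = c(G1 = 0.6, S = 0.2, G2M = 0.2),
         stop("unknown DNA-content pattern: ", pattern))
}

#' Simulate ground-truth cells, genes, and molecule counts
#'
#' Draws the full latent state of a synthetic experiment: per-cell cluster,
#' cell-cycle phase and DNA content; per-gene class flags (differential,
#' cycle-scaling, bursty) and cluster means; and the true molecule counts
#' per gene per cell (negative binomial around the cell-specific mean, with
#' cycle-scaling genes multiplied by DNA content in \[1, 2\]). Spike-in
#' molecule counts are Binomial(input molecules, capture probability).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole truth object is a deterministic
#'   function of (config, seed).
#' @return A list of class `ground_truth`: `config`, `cells` (data.frame
#'   `cell_id`, `cluster`, `phase`, `dna_content`, `pool`), `genes`
#'   (data.frame `gene`, `base_mean`, `de_flag`, `log2_fc`, `cycle_flag`,
#'   `noisy_flag`, `is_ercc`), and `counts` (genes x cells integer matrix
#'   of true molecule counts, spike-in rows included).
#' @export
simulate_cells <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  nc <- config$n_cells
  ng <- config$n_genes
  nk <- length(config$cluster_props)

  if (nc == 0L) {
    return(structure(list(config = config,
                          cells = data.frame(cell_id = character(0),
                                             cluster = integer(0),
                                             phase = character(0),
                                             dna_content = numeric(0),
                                             pool = character(0)),
                          genes = data.frame(), counts = matrix(0, 0, 0)),
                     class = "ground_truth"))
  }

  cluster <- sample.int(nk, nc, replace = TRUE, prob = config$cluster_props)
  phase <- character(nc)
  content <- numeric(nc)
  for (k in seq_len(nk)) {
    idx <- which(cluster == k)
    w <- .dna_weights(config$dna_pattern[k])
    ph <- sample(names(w), length(idx), replace = TRUE, prob = w)
    phase[idx] <- ph
    content[idx] <- ifelse(ph == "G1", 1,
                           ifelse(ph == "G2M", 2, runif(length(idx), 1, 2)))
  }
  pools <- names(config$pool_barcodes)
  pool <- pools[1L + (seq_len(nc) - 1L) %% length(pools)]
  cells <- data.frame(cell_id = sprintf("cell%04d", seq_len(nc)),
                      cluster = cluster, phase = phase, dna_content = content,
                      pool = pool, stringsAsFactors = FALSE)

  base_mean <- rlnorm(ng, config$gene_mean_meanlog, config$gene_mean_sdlog)
  de_flag <- runif(ng) < config$de_fraction
  lfc <- ifelse(de_flag,
                rgamma(ng, config$de_lfc_shape, config$de_lfc_rate) *
                  sample(c(-1, 1), ng, replace = TRUE),
                0)
  # cycle / bursty classes drawn from the non-DE genes when possible so the
  # class signals stay interpretable in tests
  cycle_flag <- runif(ng) < config$cycle_fraction & !de_flag
  noisy_flag <- runif(ng) < config$noisy_fraction & !de_flag & !cycle_flag
  genes <- data.frame(gene = sprintf("gene%04d", seq_len(ng)),
                      base_mean = base_mean, de_flag = de_flag,
                      log2_fc = lfc, cycle_flag = cycle_flag,
                      noisy_flag = noisy_flag, is_ercc = FALSE,
                      stringsAsFactors = FALSE)

  # per-gene-per-cell means: cluster fold change on cluster 2, cycle scaling
  mean_mat <- matrix(base_mean, ng, nc)
  if (nk >= 2L) {
    in2 <- cluster >= 2L
    if (any(in2))
      mean_mat[, in2] <- mean_mat[, in2] * 2 ^ lfc
  }
  if (any(cycle_flag))
    mean_mat[cycle_flag, ] <-
      sweep(mean_mat[cycle_flag, , drop = FALSE], 2L, content, `*`)
  size <- ifelse(noisy_flag, config$noisy_size, config$nb_size)
  counts <- matrix(rnbinom(ng * nc, size = rep(size, nc),
                           mu = as.numeric(mean_mat)), ng, nc)
  rownames(counts) <- genes$gene
  colnames(counts) <- cells$cell_id

  if (!is.null(config$ercc)) {
    er <- ercc_molecules(config$ercc)
    ne <- nrow(er)
    ecounts <- matrix(rbinom(ne * nc,
                             size = rep(round(er$molecules_per_well), nc),
                             prob = config$ercc_capture), ne, nc)
    rownames(ecounts) <- er$ercc_id
    colnames(ecounts) <- cells$cell_id
    counts <- rbind(counts, ecounts)
    genes <- rbind(genes,
                   data.frame(gene = er$ercc_id,
                              base_mean = er$molecules_per_well * config$ercc_capture,
                              de_flag = FALSE, log2_fc = 0, cycle_flag = FALSE,
                              noisy_flag = FALSE, is_ercc = TRUE,
                              stringsAsFactors = FALSE))
  }
  structure(list(config = config, cells = cells, genes = genes,
                 counts = counts),
            class = "ground_truth")
}

# cDNA-like filler: substrings of a long random reference, which avoids
# materializing an n x len character matrix for millions of reads
.random_cdna <- function(n, len, ref_len = 100000L) {
  if (!n) return(character(0))
  ref <- paste(sample(c("A", "C", "G", "T"), max(ref_len, len + 1L),
                      replace = TRUE), collapse = "")
  start <- 1L + floor(runif(n) * (nchar(ref) - len))
  substring(ref, start, start + len - 1L)
}

.int_to_dna <- function(codes, width) {
  bases <- c("A", "C", "G", "T")
  out <- matrix("", length(codes), width)
  x <- codes
  for (j in seq(width, 1L)) {
    out[, j] <- bases[(x %% 4L) + 1L]
    x <- x %/% 4L
  }
  do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
}

.inject_edit <- function(seqs, type) {
  bases <- c("A", "C", "G", "T")
  n <- length(seqs)
  if (!n) return(seqs)
  len <- nchar(seqs)
  pos <- 1L + floor(runif(n) * len)
  if (type == "sub") {
    old <- substr(seqs, pos, pos)
    repl <- vapply(old, function(b) sample(setdiff(bases, b), 1L), "",
                   USE.NAMES = FALSE)
    substr(seqs, pos, pos) <- repl
    return(seqs)
  }
  if (type == "ins") {
    ins <- bases[sample.int(4L, n, replace = TRUE)]
    return(paste0(substr(seqs, 1L, pos - 1L), ins,
                  substring(seqs, pos)))
  }
  # deletion
  paste0(substr(seqs, 1L, pos - 1L), substring(seqs, pos + 1L))
}

#' Emit reads and a gene-tagged table from a ground truth
#'
#' Converts true molecule counts into sequencing-like output. Each molecule
#' receives a UMI (uniform random 8-mer, or distinct per (cell, gene) when
#' `unique_umis`) and spawns a geometric number of duplicate reads. Read 1
#' is the (possibly corrupted) cell barcode followed by the UMI and a
#' poly(T) tail, truncated to `read1_len`; barcode edits are injected
#' independently per read at the configured substitution / insertion /
#' deletion rates and logged in the output. Byproduct reads carry random
#' sequence with no valid barcode. Read 2 is random cDNA-like sequence.
#'
#' @param truth A `ground_truth` from [simulate_cells()].
#' @param barcodes A [barcode_set()] (or character vector) with at least as
#'   many sequences as cells; barcode `i` is assigned to cell `i`.
#' @param seed Integer seed (separate from the truth seed).
#' @param read2_len Length of the synthetic cDNA read (default 62).
#' @return A list of class `synthetic_reads`:
#'   `reads` (data.frame `read_id`, `read1_seq`, `read1_qual`,
#'   `index1_seq`, `read2_seq`, plus truth columns `true_cell`,
#'   `true_gene`, `true_umi`, `n_sub`, `n_ins`, `n_del`, `is_byproduct`),
#'   `tagged` (the alignment-free gene-tagged table: `cell_barcode`, `umi`,
#'   `gene`, `pool`), and `barcode_map` (cell_id -> barcode).
#' @export
emit_reads <- function(truth, barcodes, seed = 1L, read2_len = 62L) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  seqs <- if (inherits(barcodes, "barcode_set")) barcodes$sequences else
    .check_dna(barcodes, "barcodes")
  nc <- nrow(truth$cells)
  if (length(seqs) < nc)
    stop("need at least as many barcodes as cells")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  bc <- seqs[seq_len(nc)]
  names(bc) <- truth$cells$cell_id

  # molecule table
  nz <- which(truth$counts > 0, arr.ind = TRUE)
  mol_n <- truth$counts[nz]
  mol_cell <- rep(nz[, 2L], mol_n)
  mol_gene <- rep(rownames(truth$counts)[nz[, 1L]], mol_n)
  nmol <- length(mol_cell)
  uspace <- 4 ^ cfg$umi_len
  if (isTRUE(cfg$unique_umis)) {
    grp <- rep(seq_len(nrow(nz)), mol_n)
    # grp is non-decreasing by construction, so split() preserves order
    codes <- unlist(lapply(split(seq_len(nmol), grp), function(ix)
      sample.int(uspace, length(ix)) - 1L), use.names = FALSE)
    umi <- .int_to_dna(codes, cfg$umi_len)
  } else {
    umi <- .int_to_dna(floor(runif(nmol) * uspace), cfg$umi_len)
  }

  dups <- 1L + rgeom(nmol, prob = 1 / cfg$duplication_mean)
  rd_mol <- rep(seq_len(nmol), dups)
  nread <- length(rd_mol)

  rd_cell <- mol_cell[rd_mol]
  rd_gene <- mol_gene[rd_mol]
  rd_umi <- umi[rd_mol]
  rd_bc <- bc[rd_cell]

  n_sub <- as.integer(runif(nread) < cfg$sub_rate)
  n_ins <- as.integer(runif(nread) < cfg$ins_rate)
  n_del <- as.integer(runif(nread) < cfg$del_rate)
  ed <- which(n_sub > 0L); rd_bc[ed] <- .inject_edit(rd_bc[ed], "sub")
  ed <- which(n_ins > 0L); rd_bc[ed] <- .inject_edit(rd_bc[ed], "ins")
  ed <- which(n_del > 0L); rd_bc[ed] <- .inject_edit(rd_bc[ed], "del")

  tail_len <- cfg$read1_len  # ample poly(T) to pad any deletion shift
  r1 <- substr(paste0(rd_bc, rd_umi, strrep("T", tail_len)), 1L, cfg$read1_len)
  pool_id <- truth$cells$pool[rd_cell]
  idx1 <- unname(cfg$pool_barcodes[pool_id])
  is_byp <- rep(FALSE, nread)

  nbyp <- round(cfg$byproduct_fraction / max(1e-12, 1 - cfg$byproduct_fraction)
                * nread)
  if (nbyp > 0L) {
    bseq <- .random_cdna(nbyp, cfg$read1_len)
    r1 <- c(r1, bseq)
    rd_cell <- c(rd_cell, rep(NA_integer_, nbyp))
    rd_gene <- c(rd_gene, rep(NA_character_, nbyp))
    rd_umi <- c(rd_umi, rep(NA_character_, nbyp))
    pool_id <- c(pool_id, sample(names(cfg$pool_barcodes), nbyp, replace = TRUE))
    idx1 <- c(idx1, unname(cfg$pool_barcodes[pool_id[nread + seq_len(nbyp)]]))
    n_sub <- c(n_sub, rep(NA_integer_, nbyp))
    n_ins <- c(n_ins, rep(NA_integer_, nbyp))
    n_del <- c(n_del, rep(NA_integer_, nbyp))
    is_byp <- c(is_byp, rep(TRUE, nbyp))
  }
  ntot <- length(r1)
  ord <- sample.int(ntot)  # shuffle so byproducts interleave
  reads <- data.frame(
    read_id = sprintf("read%07d", seq_len(ntot)),
    read1_seq = r1[ord],
    read1_qual = strrep("I", nchar(r1[ord])),
    index1_seq = idx1[ord],
    read2_seq = .random_cdna(ntot, read2_len),
    true_cell = ifelse(is.na(rd_cell[ord]), NA_character_,
                       truth$cells$cell_id[rd_cell[ord]]),
    true_gene = rd_gene[ord],
    true_umi = rd_umi[ord],
    n_sub = n_sub[ord], n_ins = n_ins[ord], n_del = n_del[ord],
    is_byproduct = is_byp[ord],
    stringsAsFactors = FALSE)

  sc <- !reads$is_byproduct
  tagged <- data.frame(cell_barcode = unname(bc[reads$true_cell[sc]]),
                       umi = reads$true_umi[sc],
                       gene = reads$true_gene[sc],
                       pool = reads$index1_seq[sc],
                       stringsAsFactors = FALSE)
  structure(list(reads = reads, tagged = tagged, barcode_map = bc),
            class = "synthetic_reads")
}

#' Emit a flow-cytometry metadata table from a ground truth
#'
#' Hoechst intensity is DNA content times lognormal measurement noise (so
#' with zero noise the intensity rank equals the DNA-content rank); the
#' Calcein flag marks cluster-1 cells (emulating dye-labelling of one
#' culture condition); SSC is a lognormal size proxy shifted by cluster.
#'
#' @param truth A `ground_truth` from [simulate_cells()].
#' @param barcode_map Optional named barcode vector (from [emit_reads()])
#'   to report barcodes instead of cell ids.
#' @param seed Integer seed.
#' @return A data.frame: `cell_barcode`, `hoechst`, `calcein`, `ssc`,
#'   `cluster`.
#' @export
emit_flow_table <- function(truth, barcode_map = NULL, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  nc <- nrow(truth$cells)
  id <- truth$cells$cell_id
  if (!is.null(barcode_map)) id <- unname(barcode_map[id])
  data.frame(
    cell_barcode = id,
    hoechst = truth$cells$dna_content *
      rlnorm(nc, 0, cfg$hoechst_noise_sdlog),
    calcein = truth$cells$cluster == 1L,
    ssc = rlnorm(nc, meanlog = log(100) + 0.1 * truth$cells$cluster,
                 sdlog = 0.2),
    cluster = truth$cells$cluster,
    stringsAsFactors = FALSE)
}

#' Write synthetic reads to FASTQ files
#'
#' @param reads The `reads` data.frame of a `synthetic_reads` object.
#' @param r1,r2,i1 Output paths (`.gz` supported); `NULL` skips a file.
#' @return Invisibly, the vector of files written.
#' @export
write_fastq <- function(reads, r1, r2 = NULL, i1 = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("writing FASTQ requires the Biostrings package")
  emit <- function(seqs, quals, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(quals))
    names(x) <- reads$read_id
    Biostrings::writeQualityScaledXStringSet(
      x, path, compress = grepl("\\.gz$", path))
    path
  }
  written <- emit(reads$read1_seq, reads$read1_qual, r1)
  if (!is.null(r2))
    written <- c(written, emit(reads$read2_seq,
                               strrep("I", nchar(reads$read2_seq)), r2))
  if (!is.null(i1))
    written <- c(written, emit(reads$index1_seq,
                               strrep("I", nchar(reads$index1_seq)), i1))
  invisible(written)
}
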