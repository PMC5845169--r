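test_that("empty and deterministic simulations", {
  cfg <- sim_config(n_cells = 0, n_genes = 5, ercc = NULL)
  tr <- simulate_cells(cfg, seed = 1)
  expect_equal(nrow(tr$cells), 0)

  cfg <- sim_config(n_cells = 20, n_genes = 15, ercc = synthetic_ercc_reference(6))
  t1 <- simulate_cells(cfg, seed = 33)
  t2 <- simulate_cells(cfg, seed = 33)
  expect_identical(t1, t2)
  bs <- cached_design(14, 20, seed = 6)
  e1 <- emit_reads(t1, bs, seed = 33)
  e2 <- emit_reads(t2, bs, seed = 33)
  expect_identical(e1, e2)
  f1 <- emit_flow_table(t1, seed = 33)
  expect_identical(f1, emit_flow_table(t2, seed = 33))
  # a different seed changes the draw
  expect_false(identical(t1$counts, simulate_cells(cfg, seed = 34)$counts))
})

test_that("marginal gene means match the NB parameters over 1000 cells", {
  cfg <- sim_config(n_cells = 1000, n_genes = 40, ercc = NULL,
                    cluster_props = 1, de_fraction = 0, cycle_fraction = 0,
                    noisy_fraction = 0)
  tr <- simulate_cells(cfg, seed = 35)
  mu <- tr$genes$base_mean
  got <- rowMeans(tr$counts)
  se <- sqrt((mu + mu^2 / cfg$nb_size) / 1000)
  expect_true(all(abs(got - mu) < 3.5 * se))
  # ERCC means match molecules * capture
  cfg2 <- sim_config(n_cells = 1000, n_genes = 2,
                     ercc = synthetic_ercc_reference(10, 10, 5000))
  tr2 <- simulate_cells(cfg2, seed = 36)
  er <- tr2$genes[tr2$genes$is_ercc, ]
  gotE <- rowMeans(tr2$counts[er$gene, ])
  mE <- round(synthetic_ercc_reference(10, 10, 5000)$molecules_per_well)
  seE <- sqrt(mE * 0.05 * 0.95 / 1000)
  expect_true(all(abs(gotE - mE * 0.05) < 3.5 * seE))
})

test_that("zero-error reads demultiplex perfectly to true cells", {
  cfg <- sim_config(n_cells = 16, n_genes = 25, ercc = NULL,
                    sub_rate = 0, ins_rate = 0, del_rate = 0,
                    byproduct_fraction = 0, duplication_mean = 2,
                    gene_mean_meanlog = log(1.5))
  tr <- simulate_cells(cfg, seed = 37)
  bs <- cached_design(14, 16, seed = 7)
  em <- emit_reads(tr, bs, seed = 37)
  tg <- tag_reads(em$reads, bs)
  expect_equal(demux_stats(tg)$assigned, nrow(em$reads))
  expect_true(all(tg$correction_distance == 0))
  expect_equal(tg$cell_barcode, unname(em$barcode_map[em$reads$true_cell]))
  expect_equal(tg$umi, em$reads$true_umi)
})

test_that("end-to-end zero-noise pipeline reproduces the truth matrix", {
  cfg <- sim_config(n_cells = 24, n_genes = 40,
                    ercc = synthetic_ercc_reference(8, 5, 2000),
                    sub_rate = 0, ins_rate = 0, del_rate = 0,
                    byproduct_fraction = 0, duplication_mean = 4,
                    unique_umis = TRUE, gene_mean_meanlog = log(2))
  tr <- simulate_cells(cfg, seed = 38)
  bs <- cached_design(14, 24, seed = 8)
  em <- emit_reads(tr, bs, seed = 38)
  tg <- tag_reads(em$reads, bs)
  tagged <- data.frame(cell_barcode = tg$cell_barcode, umi = tg$umi,
                       gene = em$reads$true_gene, stringsAsFactors = FALSE)
  m <- count_umis(tagged, "exact", cells = unname(em$barcode_map),
                  genes = rownames(tr$counts))
  truth <- tr$counts
  colnames(truth) <- unname(em$barcode_map[colnames(truth)])
  expect_equal(unname(as.matrix(m$counts)), unname(truth[m$genes, m$cells]))
})

test_that("single-edit injection is logged and decodable", {
  cfg <- sim_config(n_cells = 12, n_genes = 20, ercc = NULL,
                    sub_rate = 1, ins_rate = 0, del_rate = 0,
                    byproduct_fraction = 0, duplication_mean = 1,
                    gene_mean_meanlog = log(1))
  tr <- simulate_cells(cfg, seed = 39)
  bs <- cached_design(14, 12, seed = 9)
  em <- emit_reads(tr, bs, seed = 39)
  expect_true(all(em$reads$n_sub == 1))
  tg <- tag_reads(em$reads, bs)
  expect_equal(demux_stats(tg)$assigned, nrow(em$reads))
  expect_equal(tg$cell_barcode, unname(em$barcode_map[em$reads$true_cell]))
})

test_that("byproduct reads halve the measured conversion efficiency", {
  base <- list(n_cells = 16, n_genes = 30, ercc = NULL, sub_rate = 0,
               ins_rate = 0, del_rate = 0, duplication_mean = 3,
               unique_umis = TRUE, gene_mean_meanlog = log(2))
  bs <- cached_design(14, 16, seed = 7)
  eff <- vapply(c(0, 0.5), function(bf) {
    cfg <- do.call(sim_config, c(base, list(byproduct_fraction = bf)))
    tr <- simulate_cells(cfg, seed = 40)
    em <- emit_reads(tr, bs, seed = 40)
    m <- count_umis(em$tagged, "exact", cells = sort(unname(em$barcode_map)))
    umi_conversion_efficiency(nrow(em$reads), m)$mean_efficiency
  }, numeric(1))
  # doubling the read total at fixed UMIs halves the efficiency
  expect_equal(eff[2] / eff[1], 0.5, tolerance = 0.01)
})

test_that("flow table mirrors the truth", {
  cfg <- sim_config(n_cells = 200, n_genes = 5, ercc = NULL,
                    hoechst_noise_sdlog = 0)
  tr <- simulate_cells(cfg, seed = 41)
  fl <- emit_flow_table(tr, seed = 41)
  # zero noise: intensity rank equals DNA-content rank
  expect_equal(order(fl$hoechst), order(tr$cells$dna_content))
  expect_equal(fl$calcein, tr$cells$cluster == 1)

  # embryonic pattern: more cells near content 2 than near content 1
  cfgE <- sim_config(n_cells = 600, n_genes = 5, ercc = NULL,
                     cluster_props = 1, dna_pattern = "embryonic")
  trE <- simulate_cells(cfgE, seed = 42)
  flE <- emit_flow_table(trE, seed = 42)
  h <- hist(flE$hoechst, breaks = seq(0.5, 3, by = 0.25), plot = FALSE)
  g1_mode <- max(h$counts[h$mids < 1.4])
  g2_mode <- max(h$counts[h$mids > 1.6])
  expect_gte(g2_mode, g1_mode)
  # somatic pattern reverses the ratio of G1 to G2/M cells
  cfgS <- sim_config(n_cells = 600, n_genes = 5, ercc = NULL,
                     cluster_props = 1, dna_pattern = "somatic")
  trS <- simulate_cells(cfgS, seed = 42)
  expect_gt(mean(trS$cells$phase == "G1"), mean(trE$cells$phase == "G1"))
})

test_that("FASTQ round-trip preserves reads and qualities", {
  skip_if_not_installed("Biostrings")
  cfg <- sim_config(n_cells = 6, n_genes = 10, ercc = NULL,
                    duplication_mean = 1, gene_mean_meanlog = log(1))
  tr <- simulate_cells(cfg, seed = 43)
  bs <- cached_design(14, 6, seed = 10)
  em <- emit_reads(tr, bs, seed = 43)
  d <- tempfile()
  dir.create(d)
  write_fastq(em$reads, file.path(d, "R1.fastq.gz"),
              r2 = file.path(d, "R2.fastq.gz"),
              i1 = file.path(d, "I1.fastq.gz"))
  rec <- read_fastq_records(file.path(d, "R1.fastq.gz"),
                            r2 = file.path(d, "R2.fastq.gz"),
                            i1 = file.path(d, "I1.fastq.gz"))
  expect_equal(rec$read1_seq, em$reads$read1_seq)
  expect_equal(rec$read1_qual, em$reads$read1_qual)
  expect_equal(rec$read2_seq, em$reads$read2_seq)
  expect_equal(rec$index1_seq, em$reads$index1_seq)
  unlink(d, recursive = TRUE)
})
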