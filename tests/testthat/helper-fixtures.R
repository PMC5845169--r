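# Designed barcode sets are expensive; memoize them for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

cached_design <- function(length, n, min_distance = 5, seed = 1L,
                          pool_factor = 1.15) {
  key <- paste(length, n, min_distance, seed, pool_factor, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- design_barcode_set(
      length, n, min_distance, seed = seed, pool_factor = pool_factor)
  }
  .fixture_cache[[key]]
}

# small gene-tagged table builder
tagged_table <- function(cell, umi, gene) {
  data.frame(cell_barcode = cell, umi = umi, gene = gene,
             stringsAsFactors = FALSE)
}

# dge_matrix from a dense matrix with default names
toy_dge <- function(m, genes = sprintf("g%02d", seq_len(nrow(m))),
                    cells = sprintf("c%02d", seq_len(ncol(m)))) {
  dimnames(m) <- list(genes, cells)
  dge_matrix(m)
}
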