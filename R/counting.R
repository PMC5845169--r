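#' Digital expression matrix container
#'
#' A genes x cells matrix of non-negative integer UMI (or read) counts,
#' stored sparsely, with per-cell totals and detected-gene counts kept in
#' step with the matrix.
#'
#' @param counts A matrix or `Matrix::dgCMatrix` (genes in rows, cells in
#'   columns) with dimnames.
#' @return An object of class `dge_matrix`: a list with `counts` (a
#'   `dgCMatrix`), `genes`, `cells`, `cell_totals`, `cell_gene_counts`.
#' @export
dge_matrix <- function(counts) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must carry gene (row) and cell (column) names")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be non-negative integers")
  structure(list(
    counts = counts,
    genes = rownames(counts),
    cells = colnames(counts),
    cell_totals = Matrix::colSums(counts),
    cell_gene_counts = Matrix::colSums(counts > 0)),
    class = "dge_matrix")
}

#' @export
print.dge_matrix <- function(x, ...) {
  cat(sprintf("dge_matrix: %d genes x %d cells, %.0f total counts\n",
              length(x$genes), length(x$cells), sum(x$cell_totals)))
  cat(sprintf("  median per-cell total %.0f, median genes per cell %.0f\n",
              stats::median(x$cell_totals), stats::median(x$cell_gene_counts)))
  invisible(x)
}

#' @export
dim.dge_matrix <- function(x) dim(x$counts)

#' Count UMIs (or reads) per gene per cell
#'
#' Collapses a gene-tagged read table into a digital expression matrix. With
#' `collapse = "exact"` the count for a (cell, gene) pair is the number of
#' distinct UMI sequences observed. With `collapse = "hamming1"` (the
#' default, mirroring the behaviour of established digital-expression tools)
#' UMIs within Hamming distance 1 of each other are merged by single
#' linkage, and the count is the number of connected components of the
#' Hamming-1 graph. `count_reads()` counts reads without UMI filtering and
#' is entrywise `>=` the UMI-filtered matrix.
#'
#' @param reads A data.frame with columns `cell_barcode`, `umi`, `gene`
#'   (e.g. a `tagged_reads` table joined to gene tags, or the gene-tagged
#'   TSV emitted by the simulator). Rows with `NA` in any of the three
#'   columns are dropped.
#' @param collapse UMI collapsing rule, `"hamming1"` or `"exact"`.
#' @param cells Cell barcodes to include as columns (the plate whitelist);
#'   defaults to the barcodes present in `reads`, sorted.
#' @param genes Genes to include as rows; defaults to those present, sorted.
#' @return A [dge_matrix()].
#' @export
count_umis <- function(reads, collapse = c("hamming1", "exact"),
                       cells = NULL, genes = NULL) {
  collapse <- match.arg(collapse)
  dt <- .tagged_dt(reads)
  umi <- NULL; cell_barcode <- NULL; gene <- NULL  # NSE notes
  if (collapse == "exact") {
    agg <- dt[, list(n = length(unique(umi))), by = list(cell_barcode, gene)]
  } else {
    agg <- dt[, list(n = .hamming1_components(unique(umi))),
              by = list(cell_barcode, gene)]
  }
  .build_dge(agg, cells, genes)
}

#' @rdname count_umis
#' @export
count_reads <- function(reads, cells = NULL, genes = NULL) {
  dt <- .tagged_dt(reads)
  cell_barcode <- NULL; gene <- NULL
  agg <- dt[, list(n = .N), by = list(cell_barcode, gene)]
  .build_dge(agg, cells, genes)
}

.tagged_dt <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("cell_barcode", "umi", "gene") %in% names(reads)))
  dt <- data.table::as.data.table(
    reads[, c("cell_barcode", "umi", "gene")])
  dt <- dt[!is.na(dt$cell_barcode) & !is.na(dt$umi) & !is.na(dt$gene) &
             nzchar(dt$gene)]
  dt
}

.build_dge <- function(agg, cells, genes) {
  if (is.null(cells)) cells <- sort(unique(agg$cell_barcode))
  if (is.null(genes)) genes <- sort(unique(agg$gene))
  agg <- agg[agg$cell_barcode %in% cells & agg$gene %in% genes, ]
  m <- Matrix::sparseMatrix(
    i = match(agg$gene, genes),
    j = match(agg$cell_barcode, cells),
    x = agg$n,
    dims = c(length(genes), length(cells)),
    dimnames = list(genes, cells))
  dge_matrix(m)
}

# Number of connected components of the Hamming-distance-1 graph over a set
# of distinct equal-length UMI strings (single-linkage merge), by union-find.
.hamming1_components <- function(umis) {
  n <- length(umis)
  if (n <= 1L) return(n)
  chars <- do.call(rbind, strsplit(umis, "", fixed = TRUE))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    di <- chars[rep(i, n - i), , drop = FALSE] != chars[(i + 1L):n, , drop = FALSE]
    hits <- which(rowSums(di) <= 1L)
    for (j in hits) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Filter cells by detected gene count
#'
#' Retains cells detecting at least `min_genes` genes (count > 0); the
#' boundary is inclusive. Typical thresholds in plate-based mouse data are
#' 4000 genes for deeply sequenced cell-line experiments and 500 for
#' heterogeneous tissue.
#'
#' @param m A [dge_matrix()].
#' @param min_genes Minimum detected gene count (default 0 = keep all).
#' @return A [dge_matrix()] with the retained cells; warns (not errors) if
#'   no cell survives.
#' @export
filter_cells <- function(m, min_genes = 0L) {
  stopifnot(inherits(m, "dge_matrix"), min_genes >= 0L)
  keep <- m$cell_gene_counts >= min_genes
  if (!any(keep)) warning("all cells removed by the gene-count filter")
  dge_matrix(m$counts[, keep, drop = FALSE])
}

#' Per-cell mitochondrial count fraction
#'
#' Fraction of each cell's counts falling on genes whose name matches
#' `prefix` (default `"mt-"`, the mouse mitochondrial gene prefix). Reported
#' descriptively; no filtering decision is taken.
#'
#' @param m A [dge_matrix()].
#' @param prefix Gene-name prefix identifying mitochondrial genes
#'   (case-insensitive).
#' @return Named numeric vector of fractions, one per cell (0 for cells
#'   with zero total).
#' @export
mito_fraction <- function(m, prefix = "mt-") {
  stopifnot(inherits(m, "dge_matrix"))
  mt <- grepl(paste0("^", prefix), m$genes, ignore.case = TRUE)
  tot <- m$cell_totals
  mtc <- Matrix::colSums(m$counts[mt, , drop = FALSE])
  out <- ifelse(tot > 0, mtc / tot, 0)
  setNames(out, m$cells)
}

#' Normalize a digital expression matrix
#'
#' Scales each cell's counts to a common total (10,000 by default, or the
#' mean of per-cell totals), adds 1, and takes the natural logarithm.
#' Optionally each gene is then centred and scaled to unit variance across
#' cells. Before gene scaling, `colSums(expm1(values))` equals the scale
#' target for every cell.
#'
#' @param m A [dge_matrix()] with no zero-total cells (run [filter_cells()]
#'   first; a zero-total cell is an error pointing there).
#' @param scale_target `10000` (default) or `"mean_total"`.
#' @param scale_genes If `TRUE`, z-scale each gene across cells after the
#'   log transform; genes with zero variance are left at 0.
#' @return An object of class `normalized_matrix`: a dense genes x cells
#'   numeric matrix with attributes `scale_target`, `log_base = "natural"`,
#'   and `gene_scaled`.
#' @export
normalize_dge <- function(m, scale_target = 10000, scale_genes = FALSE) {
  stopifnot(inherits(m, "dge_matrix"))
  if (any(m$cell_totals == 0))
    stop("matrix contains zero-total cells; remove them with filter_cells()")
  target <- if (identical(scale_target, "mean_total"))
    mean(m$cell_totals) else as.numeric(scale_target)
  dense <- as.matrix(m$counts)
  scaled <- sweep(dense, 2L, m$cell_totals / target, `/`)
  vals <- log1p(scaled)
  if (scale_genes) {
    mu <- rowMeans(vals)
    s <- apply(vals, 1L, sd)
    vals <- (vals - mu) / ifelse(s > 0, s, 1)
    vals[s == 0, ] <- 0
  }
  structure(vals, scale_target = target, log_base = "natural",
            gene_scaled = scale_genes, class = c("normalized_matrix", "matrix",
                                                 "array"))
}

#' Write and read a digital expression matrix
#'
#' `write_dge()` writes the MatrixMarket triplet (`matrix.mtx`,
#' `genes.tsv`, `barcodes.tsv`) into a directory, or a dense headered TSV
#' when `dense = TRUE`. `read_dge()` reads the triplet back.
#'
#' @param m A [dge_matrix()].
#' @param dir Output (input) directory.
#' @param dense Write a single dense TSV (`matrix.tsv`) instead.
#' @return `write_dge()` returns `dir` invisibly; `read_dge()` a
#'   [dge_matrix()].
#' @export
write_dge <- function(m, dir, dense = FALSE) {
  stopifnot(inherits(m, "dge_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (dense) {
    df <- as.data.frame(as.matrix(m$counts))
    df <- cbind(gene = rownames(df), df)
    write.table(df, file.path(dir, "matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
    writeLines(m$genes, file.path(dir, "genes.tsv"))
    writeLines(m$cells, file.path(dir, "barcodes.tsv"))
  }
  invisible(dir)
}

#' @rdname write_dge
#' @export
read_dge <- function(dir) {
  mm <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(mm) <- list(genes, cells)
  dge_matrix(mm)
}

#' Read a gene-tagged read table
#'
#' Accepts the headered TSV interchange format (columns `cell_barcode`,
#' `umi`, `gene`, optional `pool`) or a minimal SAM file whose records carry
#' `XC` (cell barcode), `XM` (UMI), and `GE` (gene) tags; SAM header lines
#' and records missing any tag are skipped.
#'
#' @param path Path to a `.tsv`/`.txt` table or a `.sam` file.
#' @param format `"auto"` (by extension), `"tsv"`, or `"sam"`.
#' @return A data.frame with columns `cell_barcode`, `umi`, `gene` (and
#'   `pool` if present).
#' @export
read_gene_tagged <- function(path, format = c("auto", "tsv", "sam")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("cell_barcode", "umi", "gene") %in% names(df)))
    return(df)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  get_tag <- function(fields, tag) {
    hit <- grep(paste0("^", tag, ":Z:"), fields, value = TRUE)
    if (length(hit)) sub(paste0("^", tag, ":Z:"), "", hit[1L]) else NA_character_
  }
  recs <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    c(cell_barcode = get_tag(f, "XC"), umi = get_tag(f, "XM"),
      gene = get_tag(f, "GE"))
  })
  df <- as.data.frame(do.call(rbind, recs), stringsAsFactors = FALSE)
  df[stats::complete.cases(df), , drop = FALSE]
}
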