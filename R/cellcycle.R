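#' Rank-based Hoechst intensity bins
#'
#' Discretizes cells into `n_bins` equal-sized buckets based on the rank of
#' their Hoechst 33342 (DNA content) staining intensity. When the cell count
#' is not divisible by `n_bins`, the remainder `r` is distributed as one
#' extra cell to each of the first `r` (lowest-intensity) bins, so bin sizes
#' differ by at most 1. Ties in intensity are broken by stable input order.
#' Because only ranks are used, the assignment is invariant to any strictly
#' monotone transform of the intensities.
#'
#' @param cells A data.frame with columns `cell_barcode` and `hoechst`
#'   (non-negative intensities, arbitrary units), or a numeric vector of
#'   intensities.
#' @param n_bins Number of buckets (default 40); must not exceed the number
#'   of cells.
#' @return An integer vector of bin ids (1 = lowest intensity), named by
#'   cell barcode when available.
#' @export
hoechst_bins <- function(cells, n_bins = 40L) {
  if (is.data.frame(cells)) {
    stopifnot(all(c("cell_barcode", "hoechst") %in% names(cells)))
    x <- cells$hoechst
    nm <- cells$cell_barcode
  } else {
    x <- as.numeric(cells)
    nm <- names(cells)
  }
  n <- length(x)
  if (n_bins > n) stop("n_bins exceeds the number of cells")
  if (any(x < 0)) stop("intensities must be non-negative")
  r <- rank(x, ties.method = "first")
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bounds <- cumsum(sizes)
  bin <- findInterval(r, c(0L, bounds), left.open = TRUE)
  names(bin) <- nm
  bin
}

#' Classify within-cell-type variable genes by cell-cycle association
#'
#' For each gene two coefficients of variation are computed: `cell_cv`, the
#' CV of its (by default depth-normalized) UMI counts across cells, and
#' `bin_cv`, the CV of its bin-averaged counts across the Hoechst-intensity
#' bins. Both CV vectors are z-scaled across all genes passing the zero-mean
#' exclusion. Genes with `z_bin >= z_threshold` are called
#' `cell_cycle_associated` (their average expression tracks DNA content);
#' among the rest, genes with `z_cell - z_bin >= diff_threshold` are
#' `variable_less_associated` (cell-to-cell variability not explained by the
#' cycle); everything else is `not_variable`.
#'
#' @param matrix A [dge_matrix()] restricted to the cells of one cluster /
#'   cell type.
#' @param bins Bin assignment from [hoechst_bins()], named by or ordered as
#'   the matrix cells.
#' @param z_threshold z-score cut for the bin CV (default 2).
#' @param diff_threshold Cut on `z_cell - z_bin` (default 2).
#' @param normalize If `TRUE` (default), scale each cell's counts to the
#'   mean total before averaging, so depth differences do not masquerade as
#'   cycle signal; `FALSE` uses raw counts.
#' @return A data.frame of class `variable_gene_result`: `gene`, `mean`,
#'   `cell_cv`, `bin_cv`, `z_cell`, `z_bin`, `class`. The attribute
#'   `cv_scaling` records the mean and sd used for each z-scaling, from
#'   which the CV value corresponding to any z-threshold is
#'   `mean + z * sd`.
#' @export
classify_variable_genes <- function(matrix, bins, z_threshold = 2,
                                    diff_threshold = 2, normalize = TRUE) {
  stopifnot(inherits(matrix, "dge_matrix"))
  cells <- matrix$cells
  if (!is.null(names(bins))) {
    miss <- setdiff(cells, names(bins))
    if (length(miss)) stop("bins missing for some cells, e.g. ", miss[1L])
    bins <- bins[cells]
  } else if (length(bins) != length(cells)) {
    stop("bins must be named by cell or match the matrix cell order")
  }
  if (length(unique(bins)) < 2L) stop("need at least 2 bins")
  vals <- as.matrix(matrix$counts)
  if (normalize) {
    tot <- matrix$cell_totals
    if (any(tot == 0)) stop("zero-total cells; filter first")
    vals <- sweep(vals, 2L, mean(tot) / tot, `*`)
  }
  mu <- rowMeans(vals)
  keep <- mu > 0
  vals <- vals[keep, , drop = FALSE]
  mu <- mu[keep]

  cell_sd <- apply(vals, 1L, sd)
  cell_cv <- cell_sd / mu

  binf <- factor(bins, levels = sort(unique(bins)))
  group_means <- vapply(levels(binf), function(b)
    rowMeans(vals[, binf == b, drop = FALSE]), numeric(nrow(vals)))
  bin_mu <- rowMeans(group_means)
  bin_sd <- apply(group_means, 1L, sd)
  bin_cv <- ifelse(bin_mu > 0, bin_sd / bin_mu, 0)

  zscale <- function(x) (x - mean(x)) / sd(x)
  z_cell <- zscale(cell_cv)
  z_bin <- zscale(bin_cv)

  cls <- rep("not_variable", length(mu))
  cls[z_bin >= z_threshold] <- "cell_cycle_associated"
  cls[cls == "not_variable" &
        (z_cell - z_bin) >= diff_threshold] <- "variable_less_associated"

  out <- data.frame(gene = rownames(vals), mean = mu, cell_cv = cell_cv,
                    bin_cv = bin_cv, z_cell = z_cell, z_bin = z_bin,
                    class = cls, stringsAsFactors = FALSE, row.names = NULL)
  structure(out,
            cv_scaling = list(
              bin = c(mean = mean(bin_cv), sd = sd(bin_cv)),
              cell = c(mean = mean(cell_cv), sd = sd(cell_cv))),
            z_threshold = z_threshold, diff_threshold = diff_threshold,
            class = c("variable_gene_result", "data.frame"))
}

#' Gene counts per class across a z-threshold sweep
#'
#' Re-applies the classification of [classify_variable_genes()] at each
#' requested z-threshold (holding `diff_threshold` fixed) and tabulates the
#' gene counts per class. Cell-cycle-associated counts are nested: they can
#' only shrink as z grows. The report also emits the CV value each
#' z-threshold maps to (`mean + z * sd` of the bin-CV distribution).
#'
#' @param results A `variable_gene_result` from [classify_variable_genes()].
#' @param z_values Numeric vector of z-thresholds (default `1:4`).
#' @param diff_threshold Cut for the less-associated class (defaults to the
#'   one stored in `results`).
#' @return A data.frame with one row per z value: `z`, `bin_cv_at_z`,
#'   `cell_cycle_associated`, `variable_less_associated`, `not_variable`.
#' @export
cv_threshold_report <- function(results, z_values = 1:4,
                                diff_threshold = attr(results, "diff_threshold")) {
  stopifnot(inherits(results, "variable_gene_result"))
  sc <- attr(results, "cv_scaling")$bin
  rows <- lapply(z_values, function(z) {
    cc <- results$z_bin >= z
    vl <- !cc & (results$z_cell - results$z_bin) >= diff_threshold
    data.frame(z = z, bin_cv_at_z = unname(sc["mean"] + z * sc["sd"]),
               cell_cycle_associated = sum(cc),
               variable_less_associated = sum(vl),
               not_variable = sum(!cc & !vl))
  })
  do.call(rbind, rows)
}

#' Read a flow-cytometry metadata table
#'
#' Headered TSV with columns `cell_barcode`, `hoechst`, and optionally
#' `calcein` (logical or 0/1), `ssc`, `cluster`.
#'
#' @param path File path.
#' @return A data.frame, `calcein` coerced to logical when present.
#' @export
read_flow_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_barcode", "hoechst") %in% names(df)))
  if (any(df$hoechst < 0)) stop("hoechst intensities must be non-negative")
  if (!is.null(df$calcein)) df$calcein <- as.logical(df$calcein)
  df
}
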