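#' Deviance-based differential expression test between two cell groups
#'
#' For each gene, two count GLMs are fitted: a null model with a single mean
#' and an alternative with group-specific means, both with a per-cell
#' `log(total counts)` offset so sequencing depth is absorbed. The test
#' statistic is the difference in deviance between the two models, referred
#' to a chi-squared distribution with one degree of freedom
#' (`p = 1 - pchisq(lr, 1)`). The family is Poisson with log link by
#' default; a negative-binomial family with fixed dispersion is available.
#'
#' To filter out noise, a pseudocount is added to the averaged (depth-
#' normalized) gene expression in each group, and only genes with fold
#' change `>= fc_threshold` (or `<= 1/fc_threshold`) enter the
#' Benjamini-Hochberg correction; a gene is `significant` when its FDR is
#' below `alpha` and it passed the prefilter. Setting `pseudocount = 0`
#' reproduces the variant used when comparing against bulk RNA-seq calls.
#'
#' @param matrix A [dge_matrix()].
#' @param group_a,group_b Disjoint character vectors of cell barcodes, each
#'   of size >= 2.
#' @param pseudocount Pseudocount added to group mean expression before the
#'   fold change (default 1).
#' @param fc_threshold Fold-change prefilter (default 2).
#' @param alpha FDR threshold (default 0.05).
#' @param family `"poisson"` (default) or `"nb"`.
#' @param theta Fixed negative-binomial dispersion (size) when
#'   `family = "nb"`.
#' @param p_adjust_method Multiple-testing correction (default `"BH"`).
#' @return A data.frame of class `deg_result`, one row per gene kept
#'   (genes all-zero across both groups are excluded and listed in the
#'   `excluded_genes` attribute): `gene`, `mean_a`, `mean_b`,
#'   `fold_change`, `lr_statistic`, `p_value`, `fdr` (NA for genes failing
#'   the prefilter), `passed_prefilter`, `significant`.
#' @export
deg_deviance_test <- function(matrix, group_a, group_b, pseudocount = 1,
                              fc_threshold = 2, alpha = 0.05,
                              family = c("poisson", "nb"), theta = 10,
                              p_adjust_method = "BH") {
  family <- match.arg(family)
  stopifnot(inherits(matrix, "dge_matrix"))
  group_a <- intersect(group_a, matrix$cells)
  group_b <- intersect(group_b, matrix$cells)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 cells present in the matrix")
  cells <- c(group_a, group_b)
  grp <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  sub <- as.matrix(matrix$counts[, cells, drop = FALSE])
  tot <- matrix$cell_totals[cells]
  if (any(tot == 0)) stop("zero-total cells in the groups; filter first")
  off <- log(tot)

  nonzero <- rowSums(sub) > 0
  excluded <- rownames(sub)[!nonzero]
  sub <- sub[nonzero, , drop = FALSE]
  ngene <- nrow(sub)

  fam <- if (family == "poisson") stats::poisson() else {
    if (!requireNamespace("MASS", quietly = TRUE))
      stop("family = 'nb' requires the MASS package")
    MASS::negative.binomial(theta = theta)
  }
  ctrl <- glm.control(epsilon = 1e-12, maxit = 100L)
  lr <- numeric(ngene)
  for (g in seq_len(ngene)) {
    y <- sub[g, ]
    f0 <- glm(y ~ 1 + offset(off), family = fam, control = ctrl)
    f1 <- glm(y ~ grp + offset(off), family = fam, control = ctrl)
    lr[g] <- max(0, f0$deviance - f1$deviance)
  }
  pval <- pchisq(lr, df = 1L, lower.tail = FALSE)

  # depth-normalized group means (per mean-total scale) for the fold change
  norm <- sweep(sub, 2L, mean(tot) / tot, `*`)
  mean_a <- rowMeans(norm[, grp == "a", drop = FALSE])
  mean_b <- rowMeans(norm[, grp == "b", drop = FALSE])
  fc <- (mean_a + pseudocount) / (mean_b + pseudocount)
  pre <- fc >= fc_threshold | fc <= 1 / fc_threshold

  fdr <- rep(NA_real_, ngene)
  fdr[pre] <- p.adjust(pval[pre], method = p_adjust_method)
  sig <- pre & !is.na(fdr) & fdr < alpha

  out <- data.frame(gene = rownames(sub), mean_a = mean_a, mean_b = mean_b,
                    fold_change = fc, lr_statistic = lr, p_value = pval,
                    fdr = fdr, passed_prefilter = pre, significant = sig,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, excluded_genes = excluded,
            class = c("deg_result", "data.frame"))
}

#' Binomial cluster-marker test
#'
#' For each gene, tests whether the detection fraction (cells with count
#' > 0) inside a cluster exceeds the detection fraction outside it, using
#' the exact binomial tail `P(X >= k | n, p0)` with `p0` the outside
#' fraction. When the outside fraction is 0 but the gene is detected inside,
#' `p0` is floored at `1 / (n_outside + 1)` and the gene flagged
#' (`p0_floored`). P-values are Benjamini-Hochberg adjusted; a gene is
#' `enriched` when its adjusted p-value is below `alpha` and the inside
#' fraction exceeds the outside fraction.
#'
#' @param matrix A [dge_matrix()].
#' @param cluster,rest Disjoint cell-barcode vectors (inside and outside
#'   cells); `rest` defaults to all other cells in the matrix.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A data.frame of class `marker_result`: `gene`, `frac_in`,
#'   `frac_out`, `p_value`, `p_adjusted`, `p0_floored`, `enriched`.
#' @export
binomial_marker_test <- function(matrix, cluster, rest = NULL, alpha = 0.05) {
  stopifnot(inherits(matrix, "dge_matrix"))
  cluster <- intersect(cluster, matrix$cells)
  if (is.null(rest)) rest <- setdiff(matrix$cells, cluster)
  rest <- intersect(rest, matrix$cells)
  if (length(intersect(cluster, rest))) stop("cluster and rest must be disjoint")
  if (length(cluster) < 2L || length(rest) < 2L)
    stop("each group needs at least 2 cells")
  n_in <- length(cluster); n_out <- length(rest)
  det_in <- Matrix::rowSums(matrix$counts[, cluster, drop = FALSE] > 0)
  det_out <- Matrix::rowSums(matrix$counts[, rest, drop = FALSE] > 0)
  frac_in <- det_in / n_in
  frac_out <- det_out / n_out
  floored <- frac_out == 0 & det_in > 0
  p0 <- pmax(frac_out, ifelse(floored, 1 / (n_out + 1), 0))
  # exact upper tail P(X >= k), with P = 1 when k = 0
  pv <- pbinom(det_in - 1, size = n_in, prob = p0, lower.tail = FALSE)
  pv[det_in == 0] <- 1
  padj <- p.adjust(pv, method = "BH")
  out <- data.frame(gene = matrix$genes, frac_in = as.numeric(frac_in),
                    frac_out = as.numeric(frac_out), p_value = as.numeric(pv),
                    p_adjusted = padj, p0_floored = floored,
                    enriched = padj < alpha & frac_in > frac_out,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("marker_result", "data.frame"))
}

#' Overlap between two differential-expression gene sets
#'
#' Set algebra used when comparing single-cell calls against bulk RNA-seq
#' calls: the overlap count and the Venn partition.
#'
#' @param deg_single,deg_bulk Character vectors of gene identifiers.
#' @return A list: `overlap` (count), `both`, `single_only`, `bulk_only`
#'   (gene vectors), and `counts` (named integer vector of the partition).
#' @export
overlap_with_bulk <- function(deg_single, deg_bulk) {
  deg_single <- unique(as.character(deg_single))
  deg_bulk <- unique(as.character(deg_bulk))
  both <- intersect(deg_single, deg_bulk)
  so <- setdiff(deg_single, deg_bulk)
  bo <- setdiff(deg_bulk, deg_single)
  list(overlap = length(both), both = both, single_only = so, bulk_only = bo,
       counts = c(both = length(both), single_only = length(so),
                  bulk_only = length(bo)))
}
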