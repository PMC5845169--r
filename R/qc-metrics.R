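#' UMI conversion efficiency
#'
#' The fraction of the initial fastq reads attributed to a cell that survive
#' into the final digital expression matrix as UMI counts:
#' `efficiency = umi_sc / (fastq_sc + fastq_non_sc)`, where `fastq_sc` are
#' reads derived from the single-cell sample and `fastq_non_sc` are reads
#' from non-single-cell byproducts (adaptors, amplification byproducts,
#' empty wells). Initial reads may be attributed as an equal share of the
#' run total across cells (the default, matching how per-well read budgets
#' are quoted) or as per-cell tallies from demultiplexing.
#'
#' @param initial_reads Either a single number (total initial fastq reads,
#'   split equally across the cells of `matrix`) or a numeric vector named
#'   by cell barcode of per-cell initial read counts.
#' @param matrix A [dge_matrix()]; `umi_sc` per cell is its column total.
#' @param per_cell If `TRUE`, `initial_reads` is interpreted as per-cell
#'   counts even when unnamed (recycled in matrix cell order).
#' @return A list of class `conversion_stats`: per-cell data.frame
#'   (`cell`, `initial_reads`, `umi_sc`, `efficiency`) plus summary fields
#'   `mean_efficiency`, `sd_efficiency`, and their percentage forms
#'   `mean_percent`, `sd_percent`.
#' @export
umi_conversion_efficiency <- function(initial_reads, matrix,
                                      per_cell = length(initial_reads) > 1L) {
  stopifnot(inherits(matrix, "dge_matrix"))
  cells <- matrix$cells
  if (per_cell) {
    if (!is.null(names(initial_reads))) {
      miss <- setdiff(cells, names(initial_reads))
      if (length(miss))
        stop("per-cell initial reads missing for some cells, e.g. ", miss[1L])
      reads <- as.numeric(initial_reads[cells])
    } else {
      reads <- rep_len(as.numeric(initial_reads), length(cells))
    }
  } else {
    reads <- rep(as.numeric(initial_reads) / length(cells), length(cells))
  }
  if (any(reads <= 0)) stop("initial reads per cell must be positive")
  eff <- matrix$cell_totals / reads
  df <- data.frame(cell = cells, initial_reads = reads,
                   umi_sc = as.numeric(matrix$cell_totals),
                   efficiency = as.numeric(eff), stringsAsFactors = FALSE)
  structure(list(per_cell = df,
                 mean_efficiency = mean(eff), sd_efficiency = sd(eff),
                 mean_percent = 100 * mean(eff),
                 sd_percent = 100 * sd(eff)),
            class = "conversion_stats")
}

#' @export
print.conversion_stats <- function(x, ...) {
  cat(sprintf("UMI conversion efficiency: %.2f%% +/- %.2f%% (n = %d cells)\n",
              x$mean_percent, x$sd_percent, nrow(x$per_cell)))
  invisible(x)
}

#' ERCC reference table helpers
#'
#' Converts a spike-in concentration table to molecules per well.
#' `molecules = attomoles_per_ul * 1e-18 * N_A * volume_ul / dilution`.
#'
#' @param ref A data.frame with column `ercc_id` and either
#'   `molecules_per_well` or `attomoles_per_ul`.
#' @param volume_ul Spike-in volume added per well (microlitres).
#' @param dilution Fold dilution of the stock before addition.
#' @return The data.frame with a `molecules_per_well` column added/kept.
#' @export
ercc_molecules <- function(ref, volume_ul = 1, dilution = 1) {
  stopifnot(is.data.frame(ref), "ercc_id" %in% names(ref))
  if (!"molecules_per_well" %in% names(ref)) {
    if (!"attomoles_per_ul" %in% names(ref))
      stop("ref needs 'molecules_per_well' or 'attomoles_per_ul'")
    avogadro <- 6.02214076e23
    ref$molecules_per_well <-
      ref$attomoles_per_ul * 1e-18 * avogadro * volume_ul / dilution
  }
  if (any(ref$molecules_per_well <= 0))
    stop("input molecules must be positive")
  ref
}

.ercc_rows <- function(matrix, ref) {
  hit <- intersect(matrix$genes, ref$ercc_id)
  if (length(hit) < 1L) stop("matrix contains no ERCC species from the reference")
  list(ids = hit,
       counts = matrix$counts[hit, , drop = FALSE],
       molecules = ref$molecules_per_well[match(hit, ref$ercc_id)])
}

#' ERCC spike-in capture efficiency
#'
#' Least-squares slope, through the origin, of the detected UMI count per
#' cell against the number of input spike-in molecules per well, over ERCC
#' species. Physically the intercept is zero (zero input molecules cannot be
#' captured), hence the through-origin form. By default the per-species
#' response is the mean detected UMI count across cells; `stat = "sum"`
#' regresses summed counts against `molecules * n_cells` instead.
#'
#' @param matrix A [dge_matrix()] whose rows include `ERCC-*` genes.
#' @param reference An ERCC reference table (see [ercc_molecules()]).
#' @param stat `"mean"` (default) or `"sum"` per-species response.
#' @return A list of class `ercc_capture`: `slope` (the capture
#'   probability), `percent`, `n_species`, and the per-species table.
#' @export
ercc_capture_efficiency <- function(matrix, reference, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  stopifnot(inherits(matrix, "dge_matrix"))
  reference <- ercc_molecules(reference)
  er <- .ercc_rows(matrix, reference)
  if (length(er$ids) < 3L)
    stop("fewer than 3 ERCC species shared between matrix and reference")
  y <- Matrix::rowMeans(er$counts)
  x <- er$molecules
  if (stat == "sum") {
    y <- Matrix::rowSums(er$counts)
    x <- x * ncol(er$counts)
  }
  slope <- sum(x * y) / sum(x * x)
  tab <- data.frame(ercc_id = er$ids, input_molecules = er$molecules,
                    response = as.numeric(y), stringsAsFactors = FALSE)
  structure(list(slope = slope, percent = 100 * slope,
                 n_species = length(er$ids), stat = stat, table = tab),
            class = "ercc_capture")
}

#' @export
print.ercc_capture <- function(x, ...) {
  cat(sprintf("ERCC capture efficiency: %.2f%% (%d species, %s response)\n",
              x$percent, x$n_species, x$stat))
  invisible(x)
}

#' Spike-in copy number at 50% detection probability
#'
#' Fits a logistic regression of per-cell, per-species detection (count > 0)
#' on log10 input molecules, by maximum likelihood on the Bernoulli
#' detections, and solves the fitted curve for the molecule count at which
#' detection probability is 0.5: `m50 = 10^(-b0 / b1)`. The observed
#' per-species detection probabilities must bracket 0.5.
#'
#' @param matrix A [dge_matrix()] with `ERCC-*` rows.
#' @param reference An ERCC reference table (see [ercc_molecules()]).
#' @return A list of class `detection_curve`: `m50`, logistic coefficients
#'   `intercept` and `slope` (on log10 molecules), and the per-species
#'   `table` (`ercc_id`, `input_molecules`, `detection_probability`).
#' @export
molecules_at_half_detection <- function(matrix, reference) {
  stopifnot(inherits(matrix, "dge_matrix"))
  reference <- ercc_molecules(reference)
  er <- .ercc_rows(matrix, reference)
  ncell <- ncol(er$counts)
  det <- Matrix::rowSums(er$counts > 0)
  p <- det / ncell
  if (min(p) >= 0.5 || max(p) <= 0.5)
    stop(sprintf(
      "species detection probabilities [%.3f, %.3f] do not bracket 0.5",
      min(p), max(p)))
  fit <- glm(cbind(det, ncell - det) ~ log10(er$molecules),
             family = stats::binomial())
  b <- coef(fit)
  if (b[2L] <= 0)
    stop("fitted detection curve is not increasing in input molecules")
  m50 <- 10 ^ (-b[1L] / b[2L])
  tab <- data.frame(ercc_id = er$ids, input_molecules = er$molecules,
                    detection_probability = as.numeric(p),
                    stringsAsFactors = FALSE)
  structure(list(m50 = unname(m50), intercept = unname(b[1L]),
                 slope = unname(b[2L]), table = tab),
            class = "detection_curve")
}

#' @export
print.detection_curve <- function(x, ...) {
  cat(sprintf("spike-in copy number at 50%% detection: %.2f molecules\n",
              x$m50))
  invisible(x)
}
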