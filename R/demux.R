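#' Correct an observed cell-barcode window against a barcode set
#'
#' Decodes the first `set$length + max_dist` bases of a read against every
#' barcode in the set. The decoding distance of barcode `b` against window
#' `w` is `min_j Lev(b, w[1..j])`: the barcode must be fully consumed while
#' the window may be consumed only partially, because the UMI and transcript
#' sequence follow the barcode and an indel inside the barcode shifts them.
#' The consumed length (the minimizing `j`) locates the first UMI base.
#'
#' A set with minimum pairwise SL distance `>= 2 * max_dist + 1` guarantees
#' that at most one barcode lies within `max_dist`; the decoder still guards
#' against ties defensively and returns no decode if one occurs.
#'
#' @param observed Character vector of observed windows (each of length
#'   `set$length + max_dist` or longer; only the window prefix is used).
#' @param set A [barcode_set()].
#' @param max_dist Maximum number of correctable edits (default 2).
#' @return A data.frame with one row per window: `barcode` (corrected
#'   sequence or `NA`), `distance` (0..`max_dist` or `NA`), and
#'   `consumed_length` (observed bases consumed by the optimal alignment,
#'   `set$length` plus net indels, or `NA`).
#' @export
correct_barcode <- function(observed, set, max_dist = 2L) {
  stopifnot(inherits(set, "barcode_set"))
  if (set$min_distance < 2L * max_dist + 1L)
    stop(sprintf(
      "set min_distance (%d) < 2*max_dist+1 (%d): unambiguous decoding not guaranteed",
      set$min_distance, 2L * max_dist + 1L))
  observed <- toupper(as.character(observed))
  win_len <- set$length + max_dist
  windows <- substr(observed, 1L, win_len)
  m <- .sl_decode_cpp(windows, set$sequences, as.integer(max_dist))
  data.frame(
    barcode = ifelse(m[, 1L] > 0L, set$sequences[pmax(m[, 1L], 1L)], NA_character_),
    distance = ifelse(m[, 1L] > 0L, m[, 2L], NA_integer_),
    consumed_length = ifelse(m[, 1L] > 0L, m[, 3L], NA_integer_),
    stringsAsFactors = FALSE)
}

#' Tag reads with corrected cell barcodes and UMIs
#'
#' Applies barcode correction and UMI extraction to a stream of read
#' records. Reads whose barcode or UMI bases contain a base call below the
#' Phred quality threshold are marked `low_quality` before any correction is
#' attempted; reads with no barcode within `max_dist` edits, or too short to
#' contain a full UMI after the (indel-shifted) barcode, are
#' `uncorrectable`; everything else is `assigned`, with the UMI taken from
#' read-1 positions `[consumed_length + 1, consumed_length + umi_len]`.
#'
#' @param reads A data.frame of read records with columns `read_id`,
#'   `read1_seq`, and optionally `read1_qual` (Phred+33 string the same
#'   length as `read1_seq`), `index1_seq`, `read2_seq`.
#' @param set A [barcode_set()].
#' @param umi_len UMI length in nucleotides (default 8).
#' @param quality_threshold Minimum Phred score tolerated at any barcode or
#'   UMI base (default 10); ignored when `read1_qual` is absent.
#' @param max_dist Maximum correctable edits (default 2).
#' @return A data.frame of class `tagged_reads` with columns `read_id`,
#'   `cell_barcode`, `raw_barcode`, `correction_distance`, `umi`, `status`,
#'   plus pass-through `pool` and `read2_seq` if present in `reads`. The
#'   attribute `demux_stats` is a list with counts `assigned`,
#'   `uncorrectable`, `low_quality`, `total`, and `by_distance` (correction
#'   tallies at each distance 0..`max_dist`).
#' @export
tag_reads <- function(reads, set, umi_len = 8L, quality_threshold = 10L,
                      max_dist = 2L) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "read1_seq") %in% names(reads)))
  n <- nrow(reads)
  win_len <- set$length + max_dist
  r1 <- toupper(reads$read1_seq)

  status <- rep("assigned", n)
  low_q <- rep(FALSE, n)
  if (!is.null(reads$read1_qual) && !all(is.na(reads$read1_qual))) {
    check_len <- pmin(nchar(r1), win_len + umi_len)
    qual <- substr(reads$read1_qual, 1L, win_len + umi_len)
    minq <- vapply(qual, function(q) {
      if (is.na(q) || !nzchar(q)) return(Inf)
      min(utf8ToInt(q)) - 33L
    }, numeric(1), USE.NAMES = FALSE)
    low_q <- minq < quality_threshold
  }

  raw <- substr(r1, 1L, win_len)
  # decode only the distinct windows among reads that pass the quality gate
  dec <- data.frame(barcode = rep(NA_character_, n),
                    distance = rep(NA_integer_, n),
                    consumed_length = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  todo <- which(!low_q)
  if (length(todo)) {
    uw <- unique(raw[todo])
    ud <- correct_barcode(uw, set, max_dist = max_dist)
    idx <- match(raw[todo], uw)
    dec[todo, ] <- ud[idx, ]
  }

  umi <- rep(NA_character_, n)
  ok <- !low_q & !is.na(dec$barcode)
  if (any(ok)) {
    start <- dec$consumed_length[ok] + 1L
    end <- dec$consumed_length[ok] + umi_len
    too_short <- nchar(r1[ok]) < end
    u <- substr(r1[ok], start, end)
    u[too_short] <- NA_character_
    umi[ok] <- u
    ok[which(ok)[too_short]] <- FALSE
  }

  status[!ok] <- "uncorrectable"
  status[low_q] <- "low_quality"
  assigned <- status == "assigned"
  out <- data.frame(
    read_id = reads$read_id,
    cell_barcode = ifelse(assigned, dec$barcode, NA_character_),
    raw_barcode = raw,
    correction_distance = ifelse(assigned, dec$distance, NA_integer_),
    umi = ifelse(assigned, umi, NA_character_),
    status = status,
    stringsAsFactors = FALSE)
  for (col in c("pool", "read2_seq"))
    if (!is.null(reads[[col]])) out[[col]] <- reads[[col]]

  tal <- table(factor(out$correction_distance[assigned], levels = 0:max_dist))
  stats <- list(total = n,
                assigned = sum(assigned),
                uncorrectable = sum(status == "uncorrectable"),
                low_quality = sum(status == "low_quality"),
                by_distance = setNames(as.integer(tal), names(tal)))
  stopifnot(stats$assigned + stats$uncorrectable + stats$low_quality == n)
  structure(out, demux_stats = stats, class = c("tagged_reads", "data.frame"))
}

#' Demultiplexing statistics of a tagged read table
#' @param tagged A `tagged_reads` data.frame from [tag_reads()].
#' @return The `demux_stats` attribute (see [tag_reads()]).
#' @export
demux_stats <- function(tagged) attr(tagged, "demux_stats")

#' Split reads by pool (index) barcode
#'
#' Routes reads by their Index1 sequence, tolerating one mismatch. Pool
#' barcodes must be pairwise Hamming distance `>= 3` so that a one-mismatch
#' assignment is always unique; reads at two or more mismatches from every
#' pool go to the `"undetermined"` stream.
#'
#' @param reads A data.frame with an `index1_seq` column (or a character
#'   vector of index sequences).
#' @param pool_barcodes A data.frame with columns `pool_id` and `barcode`,
#'   or a named character vector of pool barcodes.
#' @return A factor of pool assignments (levels: pool ids plus
#'   `"undetermined"`), one per read.
#' @export
split_pools <- function(reads, pool_barcodes) {
  idx <- if (is.data.frame(reads)) reads$index1_seq else as.character(reads)
  if (is.data.frame(pool_barcodes)) {
    pools <- setNames(toupper(pool_barcodes$barcode), pool_barcodes$pool_id)
  } else {
    pools <- toupper(pool_barcodes)
    if (is.null(names(pools)))
      names(pools) <- sprintf("pool%02d", seq_along(pools))
  }
  pl <- unique(nchar(pools))
  if (length(pl) != 1L) stop("pool barcodes must have identical length")
  if (length(pools) > 1L) {
    dm <- .hamming_matrix(pools)
    if (min(dm[upper.tri(dm)]) < 3L)
      stop("pool barcodes must be pairwise Hamming distance >= 3")
  }
  idx <- substr(toupper(idx), 1L, pl)
  uidx <- unique(idx)
  d <- vapply(pools, function(p) .hamming_vec(uidx, p), integer(length(uidx)))
  d <- matrix(d, nrow = length(uidx))
  best <- apply(d, 1L, which.min)
  bestd <- d[cbind(seq_along(uidx), best)]
  lab <- ifelse(bestd <= 1L, names(pools)[best], "undetermined")
  factor(lab[match(idx, uidx)],
         levels = c(names(pools), "undetermined"))
}

.hamming_vec <- function(x, ref) {
  rc <- strsplit(ref, "", fixed = TRUE)[[1L]]
  xs <- strsplit(x, "", fixed = TRUE)
  vapply(xs, function(ch) {
    if (length(ch) != length(rc)) return(length(rc))
    sum(ch != rc)
  }, integer(1))
}

.hamming_matrix <- function(seqs) {
  n <- length(seqs)
  m <- matrix(0L, n, n)
  for (i in seq_len(n))
    m[i, ] <- .hamming_vec(seqs, seqs[i])
  m
}

#' Read paired FASTQ files into a read-record table
#'
#' Thin wrapper over `Biostrings` FASTQ readers producing the in-memory
#' read-record table consumed by [tag_reads()]. Files may be gzipped.
#'
#' @param r1,r2,i1 Paths to the read-1 FASTQ (cell barcode + UMI), and
#'   optionally the read-2 (cDNA) and Index1 (pool barcode) FASTQ files.
#' @return A data.frame with columns `read_id`, `read1_seq`, `read1_qual`,
#'   and, when given, `read2_seq` and `index1_seq`.
#' @export
read_fastq_records <- function(r1, r2 = NULL, i1 = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTQ requires the Biostrings package")
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(id = sub("\\s.*$", "", names(x)),
         seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- rd(r1)
  out <- data.frame(read_id = a$id, read1_seq = unname(a$seq),
                    read1_qual = unname(a$qual), stringsAsFactors = FALSE)
  if (!is.null(r2)) {
    b <- rd(r2)
    stopifnot(identical(a$id, b$id))
    out$read2_seq <- unname(b$seq)
  }
  if (!is.null(i1)) {
    d <- rd(i1)
    stopifnot(identical(a$id, d$id))
    out$index1_seq <- unname(d$seq)
  }
  out
}
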