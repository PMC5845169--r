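#' Sequence-Levenshtein distance between DNA barcodes
#'
#' Computes the Sequence-Levenshtein (SL) distance, an edit-distance variant
#' for barcodes embedded at the start of longer reads. The standard unit-cost
#' Levenshtein dynamic-programming matrix `D` of size
#' `(nchar(a)+1) x (nchar(b)+1)` is built, and the SL distance is the minimum
#' over its last row and last column. Because the barcode is followed by
#' further sequence, an insertion or deletion shifts the read frame, and the
#' cheapest alignment may stop before either word is fully consumed; taking
#' boundary minima models exactly that. A barcode set whose minimum pairwise
#' SL distance is `2 * e + 1` permits unique correction of up to `e` edit
#' errors (substitution, insertion, or deletion).
#'
#' `seqlev_distance()` is symmetric, satisfies `d(a, a) == 0`, and is bounded
#' above by the plain Levenshtein distance (available as
#' [levenshtein_distance()]). It is not guaranteed to satisfy the triangle
#' inequality.
#'
#' @param a,b Character vectors of DNA sequences over `{A,C,G,T}`. Recycled
#'   to a common length.
#' @return Integer vector of distances.
#' @examples
#' seqlev_distance("ACGT", "AGGT")      # 1 substitution
#' seqlev_distance("ACGTACG", "CGTACGA")
#' @export
seqlev_distance <- function(a, b) {
  pair <- .check_dna_pair(a, b)
  .sl_dist_cpp(pair$a, pair$b)
}

#' @rdname seqlev_distance
#' @export
levenshtein_distance <- function(a, b) {
  pair <- .check_dna_pair(a, b)
  .lev_dist_cpp(pair$a, pair$b)
}

.check_dna <- function(x, arg = deparse(substitute(x))) {
  x <- toupper(as.character(x))
  if (any(!nzchar(x))) stop(sprintf("'%s' contains an empty sequence", arg))
  bad <- regexpr("[^ACGT]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "'%s' contains a non-ACGT character at sequence %d, position %d",
      arg, i, bad[i]))
  }
  x
}

.check_dna_pair <- function(a, b) {
  a <- .check_dna(a, "a")
  b <- .check_dna(b, "b")
  n <- max(length(a), length(b))
  list(a = rep_len(a, n), b = rep_len(b, n))
}

#' Composition filters for candidate barcode sequences
#'
#' Filters applied to random candidate barcodes before the distance check:
#' homopolymer runs of `max_homopolymer + 1` or more bases are rejected, as
#' are sequences whose GC fraction falls outside `[gc_min, gc_max]`. Both
#' mirror common practice in barcode primer design (long homopolymers are
#' error-prone in synthesis and sequencing; extreme GC skews melting
#' temperature) and can be disabled by passing `NULL` components or using
#' `composition_filters(none = TRUE)`.
#'
#' @param max_homopolymer Longest allowed homopolymer run (default 3, i.e.
#'   runs of 4 or more identical bases are rejected). `NULL` disables.
#' @param gc_min,gc_max Allowed GC-fraction range (defaults 0.3 and 0.7).
#'   `NULL` disables.
#' @param none If `TRUE`, return a filter set that accepts everything.
#' @return An object of class `composition_filters`.
#' @export
composition_filters <- function(max_homopolymer = 3, gc_min = 0.3,
                                gc_max = 0.7, none = FALSE) {
  if (none) {
    f <- list(max_homopolymer = NULL, gc_min = NULL, gc_max = NULL)
  } else {
    f <- list(max_homopolymer = max_homopolymer, gc_min = gc_min,
              gc_max = gc_max)
  }
  structure(f, class = "composition_filters")
}

.apply_filters <- function(seqs, filters) {
  keep <- rep(TRUE, length(seqs))
  if (!is.null(filters$max_homopolymer)) {
    pat <- sprintf("([ACGT])\\1{%d,}", filters$max_homopolymer)
    keep <- keep & !grepl(pat, seqs)
  }
  if (!is.null(filters$gc_min) || !is.null(filters$gc_max)) {
    gc <- (nchar(gsub("[AT]", "", seqs))) / nchar(seqs)
    if (!is.null(filters$gc_min)) keep <- keep & gc >= filters$gc_min
    if (!is.null(filters$gc_max)) keep <- keep & gc <= filters$gc_max
  }
  keep
}

.random_kmers <- function(n, length) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(bases[sample.int(4L, n * length, replace = TRUE)],
              nrow = n, ncol = length)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Generate candidate barcodes with a guaranteed minimum SL distance
#'
#' Draws random k-mers (seeded, so reproducible), applies the composition
#' filters, and greedily accepts a candidate into the growing code iff its
#' Sequence-Levenshtein distance to every already-accepted sequence is at
#' least `min_distance`. Drawing stops when `target_count` sequences have
#' been accepted or the attempt budget is exhausted.
#'
#' @param length Barcode length in nucleotides (14 and 15 are the usual
#'   plate-format choices for 384- and 1536-well designs).
#' @param min_distance Minimum pairwise SL distance (5 guarantees correction
#'   of up to two errors).
#' @param target_count Number of sequences wanted.
#' @param filters A [composition_filters()] object.
#' @param seed Integer seed; fixes the output exactly.
#' @param max_attempts Attempt budget: total number of random draws examined
#'   before giving up (default `1e6`).
#' @return Character vector of at least `target_count` barcode sequences
#'   (exactly `target_count` unless the final chunk overshoots), with
#'   attributes `min_distance` and `length`. If the budget is exhausted
#'   first, a condition of class `umikit_capacity_error` is signalled whose
#'   `achieved` field reports the closure size reached.
#' @export
generate_candidates <- function(length, min_distance, target_count,
                                filters = composition_filters(),
                                seed = 1L, max_attempts = 1e6) {
  stopifnot(length >= 1, target_count >= 1)
  if (length < min_distance)
    stop("'length' must be >= 'min_distance'")
  accepted <- character(0)
  attempts <- 0L
  chunk <- max(1000L, min(50000L, as.integer(target_count) * 4L))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  while (length(accepted) < target_count && attempts < max_attempts) {
    n <- min(chunk, as.integer(max_attempts - attempts))
    cand <- .random_kmers(n, length)
    attempts <- attempts + n
    cand <- cand[.apply_filters(cand, filters)]
    cand <- cand[!duplicated(cand)]
    if (!length(cand)) next
    keep <- .sl_greedy_accept_cpp(accepted, cand, as.integer(min_distance),
                                  as.integer(target_count))
    accepted <- c(accepted, cand[keep])
  }
  if (length(accepted) < target_count) {
    cond <- structure(
      class = c("umikit_capacity_error", "error", "condition"),
      list(message = sprintf(
             paste0("attempt budget (%d draws) exhausted before reaching ",
                    "%d sequences; achieved %d"),
             as.integer(max_attempts), as.integer(target_count),
             length(accepted)),
           call = sys.call(-1), achieved = length(accepted),
           sequences = accepted))
    stop(cond)
  }
  structure(accepted, min_distance = as.integer(min_distance),
            length = as.integer(length))
}

#' Barcode set container
#'
#' An error-correcting DNA code: a set of equal-length sequences over
#' `{A,C,G,T}` whose minimum pairwise Sequence-Levenshtein distance meets a
#' design target. `composition_variance` is the balancing objective: the
#' variance over the four bases of the aggregate base frequencies pooled
#' over all positions and sequences (0 for a perfectly balanced set).
#'
#' @param sequences Character vector of unique, equal-length DNA sequences.
#' @param min_distance Integer design target for the minimum pairwise SL
#'   distance.
#' @return An object of class `barcode_set` with fields `sequences`,
#'   `length`, `min_distance`, and `composition_variance`.
#' @export
barcode_set <- function(sequences, min_distance) {
  sequences <- .check_dna(sequences, "sequences")
  len <- unique(nchar(sequences))
  if (length(len) != 1L)
    stop("all barcode sequences must have identical length")
  if (anyDuplicated(sequences))
    stop("barcode sequences must be unique")
  structure(
    list(sequences = sequences, length = len,
         min_distance = as.integer(min_distance),
         composition_variance = composition_variance(sequences)),
    class = "barcode_set")
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf(
    "barcode_set: %d sequences of length %d (design min SL distance %d)\n",
    length(x$sequences), x$length, x$min_distance))
  cat(sprintf("  composition variance: %.3g\n", x$composition_variance))
  invisible(x)
}

#' @export
length.barcode_set <- function(x) length(x$sequences)

#' Pooled base-composition variance of a set of sequences
#'
#' The variance (denominator 4, i.e. a population variance over the four
#' bases) of the frequencies of A, C, G, T pooled over every position of
#' every sequence. 0 means each base occupies exactly a quarter of all
#' positions.
#'
#' @param sequences Character vector of DNA sequences.
#' @return A single non-negative number.
#' @export
composition_variance <- function(sequences) {
  counts <- .base_count_matrix(sequences)
  tot <- colSums(counts)
  freq <- tot / sum(tot)
  mean((freq - mean(freq))^2)
}

.base_count_matrix <- function(sequences) {
  chars <- strsplit(sequences, "", fixed = TRUE)
  n <- length(sequences)
  out <- matrix(0L, n, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(n)) {
    tab <- table(factor(chars[[i]], levels = c("A", "C", "G", "T")))
    out[i, ] <- as.integer(tab)
  }
  out
}

#' Select a base-composition-balanced subset of candidate barcodes
#'
#' Chooses `k` of the candidate sequences so that the variance of base
#' composition (see [composition_variance()]) decreases. A seeded random
#' subset is refined by greedy exchange: at each step the in/out swap giving
#' the largest decrease in the pooled composition variance is applied, until
#' no improving swap exists (a local optimum). Subsetting cannot violate the
#' pairwise-distance invariant of the candidates.
#'
#' @param candidates Character vector of candidate barcodes (typically from
#'   [generate_candidates()]).
#' @param k Number of sequences to select (`k <= length(candidates)`).
#' @param seed Integer seed for the starting subset.
#' @param min_distance Design minimum distance recorded in the returned set;
#'   defaults to the `min_distance` attribute of `candidates`.
#' @param max_sweeps Safety bound on the number of greedy exchange steps.
#' @return A [barcode_set()] of exactly `k` sequences, sorted
#'   lexicographically (the package-wide deterministic tie-break).
#' @export
select_balanced_subset <- function(candidates, k, seed = 1L,
                                   min_distance = attr(candidates, "min_distance"),
                                   max_sweeps = 500L, n_starts = 5L) {
  n <- length(candidates)
  if (k > n) stop(sprintf("k (%d) exceeds number of candidates (%d)", k, n))
  if (is.null(min_distance))
    stop("'min_distance' must be supplied when candidates carry no attribute")
  candidates <- sort(.check_dna(candidates, "candidates"))
  counts <- .base_count_matrix(candidates)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  if (k == n) return(barcode_set(candidates, min_distance = min_distance))

  obj <- function(tot) { f <- tot / sum(tot); mean((f - mean(f))^2) }
  refine <- function(sel) {
    tot <- colSums(counts[sel, , drop = FALSE])
    in_set <- logical(n); in_set[sel] <- TRUE
    for (sweep in seq_len(max_sweeps)) {
      ins <- which(in_set); outs <- which(!in_set)
      # best objective over all single in/out swaps
      best <- list(delta = 0, i = NA, j = NA)
      cur <- obj(tot)
      for (i in ins) {
        base <- tot - counts[i, ]
        cand_tot <- sweep(counts[outs, , drop = FALSE], 2L, base, `+`)
        f <- cand_tot / rowSums(cand_tot)
        v <- rowMeans((f - rowMeans(f))^2)
        m <- which.min(v)
        if (v[m] < cur + best$delta - 1e-15) {
          best <- list(delta = v[m] - cur, i = i, j = outs[m])
        }
      }
      if (is.na(best$i) || best$delta >= -1e-15) break
      in_set[best$i] <- FALSE; in_set[best$j] <- TRUE
      tot <- tot - counts[best$i, ] + counts[best$j, ]
      if (obj(tot) <= 1e-18) break  # perfectly balanced
    }
    list(sel = which(in_set), value = obj(tot))
  }
  # greedy exchange from several seeded random starts; keep the best local
  # optimum (single-swap exchange alone can stall above the optimum)
  best <- NULL
  for (s in seq_len(n_starts)) {
    res <- refine(sort(sample.int(n, k)))
    if (is.null(best) || res$value < best$value) best <- res
    if (best$value <= 1e-18) break
  }
  barcode_set(candidates[best$sel], min_distance = min_distance)
}

#' Verify the minimum pairwise distance of a barcode set
#'
#' Exhaustively computes all pairwise Sequence-Levenshtein distances and
#' checks the set against its design minimum. Duplicated sequences show up
#' as distance 0.
#'
#' @param set A [barcode_set()], or a character vector together with
#'   `min_distance`.
#' @param min_distance Required minimum distance (taken from the set when
#'   omitted).
#' @return A list of class `barcode_verification` with fields `pass`,
#'   `min_observed`, `required`, and `pair` (the offending pair of
#'   sequences when `pass` is `FALSE`, otherwise the closest pair).
#' @export
verify_set <- function(set, min_distance = NULL) {
  if (inherits(set, "barcode_set")) {
    seqs <- set$sequences
    min_distance <- min_distance %||% set$min_distance
  } else {
    seqs <- as.character(set)
    if (is.null(min_distance)) min_distance <- attr(set, "min_distance")
    if (is.null(min_distance)) stop("'min_distance' required")
  }
  res <- .sl_min_pairwise_cpp(seqs)
  structure(list(
    pass = !is.na(res$min) && res$min >= min_distance,
    min_observed = res$min,
    required = as.integer(min_distance),
    pair = if (!is.na(res$i)) c(seqs[res$i], seqs[res$j]) else character(0)),
    class = "barcode_verification")
}

#' @export
print.barcode_verification <- function(x, ...) {
  cat(sprintf("barcode set verification: %s\n",
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  min observed pairwise SL distance: %s (required >= %d)\n",
              x$min_observed, x$required))
  if (!x$pass && length(x$pair))
    cat(sprintf("  offending pair: %s / %s\n", x$pair[1], x$pair[2]))
  invisible(x)
}

#' One-call barcode set designer
#'
#' Convenience wrapper chaining [generate_candidates()] (candidate pool of
#' `ceiling(pool_factor * n)` sequences) and [select_balanced_subset()],
#' then verifying the result with [verify_set()].
#'
#' @param length Barcode length (14 or 15 in the standard plate formats).
#' @param n Final set size (384 or 1536 in the standard plate formats).
#' @param min_distance Minimum pairwise SL distance (default 5).
#' @param seed Integer seed.
#' @param pool_factor Candidate pool size relative to `n` (default 1.15);
#'   a pool larger than `n` gives the composition balancing room to choose.
#' @param filters,max_attempts Passed to [generate_candidates()].
#' @return A verified [barcode_set()].
#' @export
design_barcode_set <- function(length, n, min_distance = 5, seed = 1L,
                               pool_factor = 1.15,
                               filters = composition_filters(),
                               max_attempts = 1e6) {
  pool <- generate_candidates(length, min_distance,
                              target_count = ceiling(pool_factor * n),
                              filters = filters, seed = seed,
                              max_attempts = max_attempts)
  set <- select_balanced_subset(pool, n, seed = seed,
                                min_distance = min_distance)
  v <- verify_set(set)
  if (!v$pass)
    stop("designed set failed verification (min observed distance ",
         v$min_observed, ")")
  set
}

#' Read and write barcode whitelists
#'
#' The whitelist format is a headered TSV with columns `well_id` and
#' `barcode` (one row per well); extra columns are tolerated and preserved
#' on reading.
#'
#' @param set A [barcode_set()] (or character vector of barcodes).
#' @param path File path.
#' @param well_ids Optional well identifiers; defaults to `well0001`, ...
#' @return `read_whitelist()` returns a data.frame with at least `well_id`
#'   and `barcode`; `write_whitelist()` returns `path` invisibly.
#' @export
write_whitelist <- function(set, path, well_ids = NULL) {
  seqs <- if (inherits(set, "barcode_set")) set$sequences else as.character(set)
  if (is.null(well_ids))
    well_ids <- sprintf("well%04d", seq_along(seqs))
  df <- data.frame(well_id = well_ids, barcode = seqs,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_whitelist
#' @export
read_whitelist <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("well_id", "barcode") %in% names(df)))
    stop("whitelist must have 'well_id' and 'barcode' columns")
  df$barcode <- .check_dna(df$barcode, "barcode")
  df
}
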