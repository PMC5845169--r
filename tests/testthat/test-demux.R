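set14 <- function() cached_design(14, 48, min_distance = 5, seed = 1)

test_that("correct_barcode decodes exact and corrupted windows", {
  set <- set14()
  bc <- set$sequences[1]
  # zero-error decode: exact barcode plus trailing bases
  r <- correct_barcode(paste0(bc, "TTTT"), set)
  expect_equal(r$barcode, bc)
  expect_equal(r$distance, 0L)
  expect_equal(r$consumed_length, set$length)
  # one deleted base: consumed length shrinks by one
  del <- paste0(substr(bc, 1, 4), substring(bc, 6), "TTTTT")
  r <- correct_barcode(del, set)
  expect_equal(r$barcode, bc)
  expect_equal(r$distance, 1L)
  expect_equal(r$consumed_length, set$length - 1L)
  # one inserted base: consumed length grows by one
  ins <- paste0(substr(bc, 1, 7), "A", substring(bc, 8), "TTT")
  r <- correct_barcode(ins, set)
  expect_equal(r$barcode, bc)
  expect_lte(r$distance, 1L)
})

test_that("windows beyond the correction radius return no decode", {
  set <- set14()
  set.seed(21)
  found <- 0L
  while (found < 20L) {
    w <- random_dna(1, set$length + 2)
    # oracle: exhaustive decoding distance (min over consumed prefixes)
    dmin <- min(vapply(set$sequences, function(b) {
      pref <- substring(w, 1, 0:nchar(w))
      min(utils::adist(b, pref))
    }, numeric(1)))
    if (dmin >= 3) {
      r <- correct_barcode(w, set)
      expect_true(is.na(r$barcode))
      expect_true(is.na(r$distance))
      expect_true(is.na(r$consumed_length))
      found <- found + 1L
    }
  }
})

test_that("decoding never returns a barcode beyond max_dist (no cross-talk)", {
  set <- set14()
  set.seed(31)
  w <- random_dna(1000, set$length + 2)
  r <- correct_barcode(w, set)
  hit <- which(!is.na(r$barcode))
  for (i in hit) {
    pref <- substring(w[i], 1, 0:nchar(w[i]))
    d_true <- min(utils::adist(r$barcode[i], pref))
    expect_lte(d_true, 2)
  }
  # and misses really have nothing within 2 edits
  miss <- which(is.na(r$barcode))
  for (i in sample(miss, min(25, length(miss)))) {
    pref <- substring(w[i], 1, 0:nchar(w[i]))
    dmin <- min(vapply(set$sequences, function(b) min(utils::adist(b, pref)),
                       numeric(1)))
    expect_gte(dmin, 3)
  }
})

test_that("round-trip: corruptions within 2 edits decode to the original", {
  set <- set14()
  set.seed(41)
  for (bc in set$sequences[1:6]) {
    e1 <- edits1(bc)
    corr <- unique(c(e1, unlist(lapply(sample(e1, 30), edits1))))
    windows <- paste0(corr, strrep("G", 6))
    windows <- substr(windows, 1, set$length + 2)
    r <- correct_barcode(windows, set)
    expect_true(all(r$barcode == bc))
    expect_true(all(r$distance <= 2))
  }
})

test_that("correct_barcode refuses a set too weak for the radius", {
  weak <- barcode_set(c("ACGTACGTAC", "ACGTACGTTT"), min_distance = 3)
  expect_error(correct_barcode("ACGTACGTACTT", weak, max_dist = 2),
               "unambiguous")
})

test_that("tag_reads assigns error-free reads at distance 0", {
  set <- set14()
  set.seed(51)
  n <- 200
  bcs <- sample(set$sequences, n, replace = TRUE)
  umis <- random_dna(n, 8)
  reads <- data.frame(read_id = sprintf("r%03d", 1:n),
                      read1_seq = paste0(bcs, umis),
                      read1_qual = strrep("I", 22),
                      stringsAsFactors = FALSE)
  tg <- tag_reads(reads, set)
  st <- demux_stats(tg)
  expect_equal(st$assigned, n)
  expect_equal(unname(st$by_distance["0"]), n)
  expect_equal(tg$cell_barcode, bcs)
  expect_equal(tg$umi, umis)
})

test_that("tag_reads corrects one injected edit per read and counts it", {
  set <- set14()
  set.seed(61)
  n <- 150
  bcs <- sample(set$sequences, n, replace = TRUE)
  umis <- random_dna(n, 8)
  # substitutions and deletions survive a 22-cycle read; use a longer read
  # so injected insertions keep their full UMI too
  mut <- vapply(bcs, function(b) {
    es <- edits1(b)
    sample(es[es != b], 1)
  }, "", USE.NAMES = FALSE)
  reads <- data.frame(read_id = sprintf("r%03d", 1:n),
                      read1_seq = paste0(mut, umis, "TT"),
                      read1_qual = strrep("I", nchar(mut) + 10),
                      stringsAsFactors = FALSE)
  tg <- tag_reads(reads, set)
  st <- demux_stats(tg)
  expect_equal(st$assigned, n)
  expect_equal(tg$cell_barcode, bcs)
  expect_true(all(tg$correction_distance <= 1))
  # oracle: the reported distance is the true decoding distance of the
  # window (an edit at the barcode/UMI boundary can legitimately decode at
  # distance 0 when the first UMI base completes the barcode)
  win <- substr(reads$read1_seq, 1, set$length + 2)
  d_oracle <- vapply(seq_len(n), function(i) {
    pref <- substring(win[i], 1, 0:nchar(win[i]))
    min(utils::adist(bcs[i], pref))
  }, numeric(1))
  expect_equal(tg$correction_distance, as.integer(d_oracle))
  expect_equal(unname(st$by_distance["1"]), sum(d_oracle == 1))
  expect_gt(mean(d_oracle == 1), 0.9)
  # UMIs are recovered except when alignment ties at the barcode/UMI
  # boundary shift the consumed length (inherent ambiguity of indel decoding)
  expect_gt(mean(tg$umi == umis), 0.9)
})

test_that("tag_reads quality gate, truncation, and stream conservation", {
  set <- set14()
  bc <- set$sequences[1]
  reads <- data.frame(
    read_id = c("ok", "lowq", "short", "junk"),
    read1_seq = c(paste0(bc, "ACGTACGT"),
                  paste0(bc, "ACGTACGT"),
                  substr(bc, 1, 10),
                  strrep("AC", 11)),
    read1_qual = c(strrep("I", 22),
                   paste0(strrep("I", 5), "#", strrep("I", 16)),  # Phred 2
                   strrep("I", 10),
                   strrep("I", 22)),
    stringsAsFactors = FALSE)
  tg <- tag_reads(reads, set)
  expect_equal(tg$status, c("assigned", "low_quality", "uncorrectable",
                            "uncorrectable"))
  st <- demux_stats(tg)
  expect_equal(st$assigned + st$uncorrectable + st$low_quality, st$total)
  # determinism: identical input -> identical output
  expect_identical(tag_reads(reads, set), tg)
})

test_that("split_pools routes by index with one-mismatch tolerance", {
  pools <- c(poolA = "ATCACG", poolB = "TAGCTT")
  idx <- c("ATCACG",            # exact
           "ATCACC",            # 1 mismatch -> poolA
           "TAGCTT",
           "ATGGCG",            # 2 mismatches -> undetermined
           "GGGGGG")
  f <- split_pools(idx, pools)
  expect_equal(as.character(f),
               c("poolA", "poolA", "poolB", "undetermined", "undetermined"))
  # oracle: brute-force Hamming scan agrees on the undetermined reads
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_true(all(vapply(c("ATGGCG", "GGGGGG"), function(x)
    min(ham(x, "ATCACG"), ham(x, "TAGCTT")), numeric(1)) >= 2))
  expect_error(split_pools(idx, c(a = "ATCACG", b = "ATCACC")),
               "Hamming distance")
})
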