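# Independent oracles used across test files. These deliberately avoid the
# package's C++ code paths: edit distances come from utils::adist(), and the
# sequence-Levenshtein value is recovered by enumerating truncations of both
# words (equivalently, the boundary minima of the DP matrix).

oracle_seqlev <- function(a, b) {
  pa <- substring(a, 1, 0:nchar(a))
  pb <- substring(b, 1, 0:nchar(b))
  min(c(utils::adist(a, pb), utils::adist(pa, b)))
}

oracle_levenshtein <- function(a, b) as.integer(utils::adist(a, b))

# all single-edit corruptions (substitution, insertion, deletion) of a string
edits1 <- function(s) {
  bases <- c("A", "C", "G", "T")
  n <- nchar(s)
  out <- character(0)
  for (i in seq_len(n)) {
    for (b in bases) {
      if (substr(s, i, i) != b)
        out <- c(out, paste0(substr(s, 1, i - 1), b, substring(s, i + 1)))
    }
    out <- c(out, paste0(substr(s, 1, i - 1), substring(s, i + 1)))  # del
  }
  for (i in seq_len(n + 1)) {
    for (b in bases)
      out <- c(out, paste0(substr(s, 1, i - 1), b, substring(s, i)))  # ins
  }
  unique(out)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

# closed-form Poisson likelihood-ratio statistic for the two-group test with
# per-cell offsets, computed from saturated-model-free log-likelihoods
oracle_poisson_lr <- function(y, grp, tot) {
  ll <- function(mu) sum(stats::dpois(y, mu, log = TRUE))
  lam0 <- sum(y) / sum(tot)
  la <- sum(y[grp == "a"]) / sum(tot[grp == "a"])
  lb <- sum(y[grp == "b"]) / sum(tot[grp == "b"])
  mu0 <- lam0 * tot
  mu1 <- ifelse(grp == "a", la, lb) * tot
  2 * (ll(mu1) - ll(mu0))
}
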