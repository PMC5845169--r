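test_that("identical groups give lr = 0, p = 1", {
  m <- toy_dge(matrix(rep(c(3, 5, 2), 4), 3, 4))
  r <- deg_deviance_test(m, c("c01", "c02"), c("c03", "c04"))
  expect_equal(r$lr_statistic, rep(0, 3), tolerance = 1e-8)
  expect_equal(r$p_value, rep(1, 3), tolerance = 1e-6)
  expect_false(any(r$significant))
})

test_that("two-group Poisson toy matches the closed-form LR statistic", {
  # counts A = {2,2,2}, B = {8,8,8}; equal per-cell totals
  counts <- rbind(gX = c(2, 2, 2, 8, 8, 8),
                  bulk = c(98, 98, 98, 92, 92, 92))  # equalizes totals at 100
  m <- toy_dge(counts, genes = rownames(counts))
  r <- deg_deviance_test(m, sprintf("c%02d", 1:3), sprintf("c%02d", 4:6))
  y <- c(2, 2, 2, 8, 8, 8)
  grp <- rep(c("a", "b"), each = 3)
  tot <- rep(100, 6)
  want <- oracle_poisson_lr(y, grp, tot)
  got <- r$lr_statistic[r$gene == "gX"]
  expect_equal(got, want, tolerance = 1e-8)
  expect_equal(r$p_value[r$gene == "gX"],
               pchisq(want, 1, lower.tail = FALSE), tolerance = 1e-8)
})

test_that("GLM deviance difference equals the Poisson LR oracle (100 instances)", {
  set.seed(16)
  for (i in 1:100) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    n <- na + nb
    grp <- rep(c("a", "b"), c(na, nb))
    lam <- runif(1, 0.5, 20)
    y <- rpois(n, lam * ifelse(grp == "a", 1, runif(1, 0.2, 5)))
    depth <- sample(50:200, n, replace = TRUE)
    counts <- rbind(g = y, rest = depth - y + 50)
    m <- toy_dge(counts, genes = c("g", "rest"),
                 cells = sprintf("c%02d", 1:n))
    r <- deg_deviance_test(m, sprintf("c%02d", 1:na),
                           sprintf("c%02d", (na + 1):n))
    tot <- colSums(counts)
    want <- oracle_poisson_lr(y, grp, tot)
    expect_equal(r$lr_statistic[r$gene == "g"], want, tolerance = 1e-8)
  }
})

test_that("lr is invariant to cell order and group relabeling", {
  set.seed(17)
  counts <- matrix(rpois(80, 6), 8, 10)
  m <- toy_dge(counts)
  a <- sprintf("c%02d", 1:5); b <- sprintf("c%02d", 6:10)
  r1 <- deg_deviance_test(m, a, b)
  r2 <- deg_deviance_test(m, b, a)
  expect_equal(r1$lr_statistic, r2$lr_statistic, tolerance = 1e-9)
  expect_equal(r1$fold_change, 1 / r2$fold_change, tolerance = 1e-9)
  perm <- sample(10)
  r3 <- deg_deviance_test(toy_dge(counts[, perm],
                                  cells = sprintf("c%02d", perm)), a, b)
  expect_equal(r1$lr_statistic, r3$lr_statistic, tolerance = 1e-9)
})

test_that("prefilter, significance invariants, and all-zero exclusion hold", {
  set.seed(18)
  counts <- rbind(matrix(rpois(100, 5), 10, 10),
                  de = c(rep(1, 5), rep(30, 5)),
                  zero = rep(0, 10))
  rn <- c(sprintf("g%02d", 1:10), "de", "zero")
  m <- toy_dge(counts, genes = rn)
  r <- deg_deviance_test(m, sprintf("c%02d", 1:5), sprintf("c%02d", 6:10))
  expect_false("zero" %in% r$gene)
  expect_equal(attr(r, "excluded_genes"), "zero")
  expect_true(all(r$lr_statistic >= 0))
  expect_true(all(r$p_value > 0 & r$p_value <= 1))
  ok <- !is.na(r$fdr)
  expect_true(all(r$fdr[ok] >= r$p_value[ok]))
  expect_true(all(r$fold_change[r$significant] >= 2 |
                    r$fold_change[r$significant] <= 0.5))
  expect_true(r[r$gene == "de", "significant"])
  # the no-pseudocount bulk-comparison variant admits more extreme FCs
  r0 <- deg_deviance_test(m, sprintf("c%02d", 1:5), sprintf("c%02d", 6:10),
                          pseudocount = 0)
  expect_gte(abs(log(r0[r0$gene == "de", "fold_change"])),
             abs(log(r[r$gene == "de", "fold_change"])))
})

test_that("negative-binomial family runs and agrees directionally", {
  set.seed(19)
  counts <- rbind(de = c(rep(2, 6), rep(20, 6)),
                  matrix(rpois(60, 8), 5, 12))
  m <- toy_dge(counts, genes = c("de", sprintf("g%d", 1:5)))
  a <- sprintf("c%02d", 1:6); b <- sprintf("c%02d", 7:12)
  rp <- deg_deviance_test(m, a, b)
  rn <- deg_deviance_test(m, a, b, family = "nb", theta = 5)
  expect_true(rn[rn$gene == "de", "lr_statistic"] > 0)
  expect_lt(rn[rn$gene == "de", "lr_statistic"],
            rp[rp$gene == "de", "lr_statistic"])  # NB is more conservative
})

test_that("binomial marker test matches the exact tail oracle", {
  # cluster of 10 cells with 9 detections; outside fraction 0.2 (4/20)
  counts <- matrix(0, 2, 30,
                   dimnames = list(c("gM", "gF"), sprintf("c%02d", 1:30)))
  counts["gM", 1:9] <- 1          # 9 of 10 cluster cells
  counts["gM", 11:14] <- 1        # 4 of 20 outside cells
  counts["gF", ] <- 1             # detected everywhere
  m <- dge_matrix(counts)
  cl <- sprintf("c%02d", 1:10)
  r <- binomial_marker_test(m, cl)
  want <- sum(dbinom(9:10, 10, 0.2))  # direct tail summation
  expect_equal(r$p_value[r$gene == "gM"], want, tolerance = 1e-12)
  expect_equal(r$frac_in[r$gene == "gM"], 0.9)
  expect_equal(r$frac_out[r$gene == "gM"], 0.2)
  # equal detection fractions: p = 1, not enriched
  expect_equal(r$p_value[r$gene == "gF"], 1, tolerance = 1e-12)
  expect_false(r$enriched[r$gene == "gF"])
})

test_that("cluster-exclusive genes are enriched with a floored null", {
  counts <- matrix(0, 1, 40, dimnames = list("gX", sprintf("c%02d", 1:40)))
  counts["gX", 1:10] <- 5  # all cluster cells, nowhere else
  m <- dge_matrix(counts)
  r <- binomial_marker_test(m, sprintf("c%02d", 1:10))
  expect_true(r$enriched)
  expect_true(r$p0_floored)
  expect_equal(r$p_value, pbinom(9, 10, 1 / 31, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("overlap_with_bulk is plain set algebra", {
  expect_equal(overlap_with_bulk(c("a", "b"), c("c", "d"))$overlap, 0)
  expect_equal(overlap_with_bulk(c("a", "b"), c("b", "a"))$overlap, 2)
  set.seed(20)
  A <- sample(letters, 12); B <- sample(letters, 15)
  r <- overlap_with_bulk(A, B)
  expect_equal(r$overlap, length(intersect(A, B)))
  expect_equal(sum(r$counts), length(union(A, B)))
})

test_that("DE sensitivity grows with cells per group on simulation", {
  # model-matched Poisson world with a power-limited effect: 100 null genes
  # at mean 1 and 100 DE genes at mean 1 vs 4 (prefilter-safe: the
  # pseudocounted fold change converges to (4+1)/(1+1) = 2.5)
  set.seed(24)
  n_per <- 40
  ng <- 100
  lam <- rbind(matrix(1, ng, 2 * n_per),
               cbind(matrix(1, ng, n_per), matrix(4, ng, n_per)))
  counts <- matrix(rpois(length(lam), lam), nrow(lam))
  counts <- rbind(counts, bulk = rpois(2 * n_per, 3000))  # stabilizes totals
  m <- toy_dge(counts, genes = c(sprintf("null%03d", 1:ng),
                                 sprintf("de%03d", 1:ng), "bulk"))
  de_genes <- sprintf("de%03d", 1:ng)
  sens <- vapply(c(3, 8, 40), function(k) {
    a <- sprintf("c%02d", 1:k)
    b <- sprintf("c%02d", n_per + (1:k))
    r <- deg_deviance_test(m, a, b)
    length(intersect(r$gene[r$significant], de_genes)) / length(de_genes)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[3], sens[1])
})
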