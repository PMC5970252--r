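test_that("exact Wilcoxon p-values match hand-enumerated tail probabilities", {
  # {1,2} vs {3,4}: rank sum 3 is one of the two extreme outcomes among
  # C(4,2) = 6 assignments, so two-sided p = 2/6
  d <- two_sample_matrix(matrix(c(1, 2)), matrix(c(3, 4)))
  expect_equal(marginal_pvalues(d, "wilcoxon_exact"), 1 / 3)

  # symmetric configuration: rank sums sit at their null expectation
  d2 <- two_sample_matrix(matrix(c(1, 4)), matrix(c(2, 3)))
  expect_equal(marginal_pvalues(d2, "wilcoxon_exact"), 1)
})

test_that("marginal p-values are columnwise and permute with the columns", {
  set.seed(11)
  d <- rand_data(6, 5, 5)
  p <- marginal_pvalues(d)
  expect_length(p, 5)
  perm <- c(3, 1, 5, 2, 4)
  dp <- two_sample_matrix(d$X1[, perm], d$X2[, perm])
  expect_identical(marginal_pvalues(dp), p[perm])
})

test_that("exact and normal-approximation p-values agree with wilcox.test", {
  set.seed(21)
  d <- rand_data(8, 7, 12)
  expect_equal(marginal_pvalues(d, "wilcoxon_exact"),
               oracle_wilcox_p(d$X1, d$X2, exact = TRUE))
  expect_equal(marginal_pvalues(d, "wilcoxon_normal"),
               oracle_wilcox_p(d$X1, d$X2, exact = FALSE), tolerance = 1e-12)

  # ties: midranks with tie-corrected variance, continuity correction off
  X1 <- matrix(sample(1:4, 24, replace = TRUE), 6)
  X2 <- matrix(sample(1:4, 20, replace = TRUE), 5)
  dt <- two_sample_matrix(X1, X2)
  expect_equal(marginal_pvalues(dt, "wilcoxon_normal"),
               suppressWarnings(oracle_wilcox_p(X1, X2, exact = FALSE)),
               tolerance = 1e-12)
  # exact request falls back to the normal approximation for tied columns
  expect_equal(marginal_pvalues(dt, "wilcoxon_exact"),
               marginal_pvalues(dt, "wilcoxon_normal"))
})

test_that("rank cache stores midranks and reproduces any labeling's statistic", {
  d <- two_sample_matrix(matrix(c(3, 1), 2), matrix(c(2, 2), 2))
  rc <- rank_cache(d)
  expect_equal(as.numeric(rc$ranks), c(4, 1, 2.5, 2.5))
  expect_true(rc$has_ties[1])

  set.seed(31)
  d2 <- rand_data(5, 6, 8)
  rc2 <- rank_cache(d2)
  expect_equal(colSums(rc2$ranks), rep(11 * 12 / 2, 8))  # n(n+1)/2 identity
  X <- rbind(d2$X1, d2$X2)
  for (i in 1:100) {
    idx <- sample(11, 5)
    w_cache <- colSums(rc2$ranks[idx, , drop = FALSE])
    w_direct <- vapply(seq_len(8), function(k) {
      sum(rank(X[, k])[idx])
    }, numeric(1))
    expect_equal(w_cache, w_direct)
  }
})

test_that("shifting one group drives its p-value to the attainable minimum", {
  set.seed(41)
  d <- rand_data(6, 6, 1)
  p0 <- marginal_pvalues(d, "wilcoxon_exact")
  dshift <- two_sample_matrix(d$X1 + 100, d$X2)
  pmin_attained <- marginal_pvalues(dshift, "wilcoxon_exact")
  expect_lt(pmin_attained, p0)
  expect_equal(pmin_attained, 2 / choose(12, 6))  # extreme two-sided tail
  expect_gt(pmin_attained, 0)
})

test_that("exact null p-values are discretely conservative", {
  set.seed(51)
  d <- rand_data(5, 5, 2000)
  p <- marginal_pvalues(d, "wilcoxon_exact")
  level <- mean(p <= 0.05)
  expect_lte(level, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("Welch t marginal handles degenerate columns and matches t.test", {
  X1 <- cbind(c(1, 1, 1, 1), rnorm(4))
  X2 <- cbind(c(1, 1, 1), rnorm(3))
  d <- two_sample_matrix(X1, X2)
  p <- marginal_pvalues(d, "t_test")
  expect_equal(p[1], 1)  # zero pooled variance: no evidence
  expect_equal(p[2], stats::t.test(X1[, 2], X2[, 2])$p.value,
               tolerance = 1e-12)
})

test_that("exact method refuses groups beyond the tabulation limit", {
  set.seed(61)
  d <- rand_data(30, 30, 2)
  expect_error(marginal_pvalues(d, "wilcoxon_exact"), "wilcoxon_normal")
  expect_silent(marginal_pvalues(d, "auto"))
})
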