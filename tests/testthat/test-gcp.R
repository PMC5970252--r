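test_that("group bin sums follow the half-open bin convention", {
  g <- group_statistic(c(0.5, 0.9), 0.2, 1)
  expect_equal(g$T, -2 * (log(0.5) + log(0.9)))  # = 1.5970154
  expect_equal(g$count, 2)

  expect_equal(group_statistic(c(0.3, 0.9), 0, 0.2)$T, 0)  # empty first bin
  expect_equal(group_statistic(exp(-2), 0, 0.5), list(T = 4, count = 1))

  # lower bound inclusive, upper bound strict
  expect_equal(group_statistic(c(0.1, 0.2), 0.1, 0.2)$count, 1)
  expect_equal(group_statistic(1, 0.2, 1)$count, 0)  # p = 1 falls in no bin
  expect_error(group_statistic(c(0, 0.5), 0, 1), "positive")
})

test_that("the empirical CDF uses the add-one denominator", {
  expect_equal(ecdf_value(c(1, 2, 3, 4), 2.5), 0.4)
  expect_equal(ecdf_value(c(1, 2, 3, 4), 0.5), 0)
  expect_equal(ecdf_value(c(1, 2, 3, 4), 4), 4 / 5)
  expect_equal(ecdf_value(c(1, 2, 3, 4), 99), 4 / 5)
  # monotone in t
  ts <- seq(0, 5, by = 0.25)
  expect_true(all(diff(ecdf_value(c(1, 2, 3, 4), ts)) >= 0))
})

test_that("adaptive maximum reduces to a single pair at S = 2 and spans 21 pairs by default", {
  set.seed(71)
  null_p <- matrix(runif(50 * 6, 0.001, 1), 50)
  p <- runif(6, 0.001, 1)

  xi2 <- c(0.05, 1)
  cdfs2 <- agcp:::build_pair_cdfs(null_p, xi2)
  a2 <- agcp_statistic(p, cdfs = cdfs2)
  expect_equal(a2$agcp, gcp_statistic(p, c(1, 2), cdfs2))

  cdfs7 <- agcp:::build_pair_cdfs(null_p, default_thresholds())
  a7 <- agcp_statistic(p, cdfs = cdfs7)
  expect_length(a7$gcp_by_pair, 21)
  expect_equal(a7$agcp, max(a7$gcp_by_pair))
  expect_true(all(a7$agcp >= a7$gcp_by_pair))
})

test_that("vectorized GCP/AGCP matches the naive reference implementation", {
  set.seed(81)
  for (i in 1:25) {
    m <- sample(3:10, 1)
    B <- sample(20:100, 1)
    P <- matrix(10^stats::runif((B + 1) * m, -5, 0), B + 1)
    xi <- sort(sample(default_thresholds(), sample(2:4, 1)))
    got <- agcp:::agcp_core(P, xi)
    want <- oracle_agcp(P, xi)
    expect_equal(got$agcp0, want$agcp0, tolerance = 1e-12)
    expect_equal(got$gcp_by_pair, want$gcp_by_pair, tolerance = 1e-12)
    expect_identical(got$pvalue, want$pvalue)
    expect_identical(got$argmax_pair, want$argmax_pair)
    # the scalar path agrees too
    cdfs <- agcp:::build_pair_cdfs(P[-1, , drop = FALSE], xi)
    sc <- agcp_statistic(P[1, ], cdfs = cdfs)
    expect_equal(sc$agcp, want$agcp0, tolerance = 1e-12)
  }
})

test_that("GCP increases weakly when an in-bin p-value shrinks", {
  set.seed(91)
  null_p <- matrix(runif(80 * 5, 0.001, 1), 80)
  cdfs <- agcp:::build_pair_cdfs(null_p, default_thresholds())
  p <- c(0.03, 0.2, 0.5, 0.7, 0.9)
  pair <- c(3, 7)  # bins [0, 0.01) and [0.01, 1)
  g0 <- gcp_statistic(p, pair, cdfs)
  p_smaller <- p
  p_smaller[3] <- 0.1  # still inside [0.01, 1)
  expect_gte(gcp_statistic(p_smaller, pair, cdfs), g0)
})

test_that("threshold sets are validated and deduplicated", {
  expect_error(agcp:::validate_thresholds(c(0.5)), "at least 2")
  expect_error(agcp:::validate_thresholds(c(0, 0.5)), "\\(0, 1\\]")
  expect_error(agcp:::validate_thresholds(c(0.5, 1.5)), "\\(0, 1\\]")
  expect_equal(agcp:::validate_thresholds(c(0.2, 0.1, 0.2)), c(0.1, 0.2))
  expect_equal(length(default_thresholds()), 7)
})
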