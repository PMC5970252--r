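test_that("exhaustive mode enumerates every labeling once", {
  set.seed(101)
  d <- rand_data(3, 3, 2)
  bank <- build_null_bank(d, scheme = permutation_scheme(mode = "exhaustive"))
  expect_equal(bank$B, choose(6, 3))
  expect_error(
    build_null_bank(d, scheme = permutation_scheme(mode = "exhaustive",
                                                   exhaustive_cap = 5)),
    "random")
})

test_that("bank rows equal direct marginal p-values on the relabeled data", {
  set.seed(111)
  d <- rand_data(4, 5, 6)
  X <- rbind(d$X1, d$X2)
  bank <- build_null_bank(d, scheme = permutation_scheme(B = 30, seed = 7))
  # regenerate the same subsets to know which rows went to group 1
  set.seed(7)
  Z <- agcp:::.random_subsets_cpp(9, 4, 30)
  for (b in sample(30, 10)) {
    idx <- which(Z[b, ] == 1)
    direct <- marginal_pvalues(
      two_sample_matrix(X[idx, , drop = FALSE], X[-idx, , drop = FALSE]))
    expect_equal(bank$P[b, ], direct)
  }
})

test_that("results are reproducible from the seed and differ across seeds", {
  set.seed(121)
  d <- rand_data(6, 6, 10, shift = 0.5)
  r1 <- agcp_test(d, B = 200, seed = 5)
  r2 <- agcp_test(d, B = 200, seed = 5)
  expect_identical(r1$statistic, r2$statistic)
  expect_identical(r1$p.value, r2$p.value)
  expect_identical(r1$gcp_by_pair, r2$gcp_by_pair)
  b1 <- build_null_bank(d, scheme = permutation_scheme(B = 50, seed = 1))
  b2 <- build_null_bank(d, scheme = permutation_scheme(B = 50, seed = 2))
  expect_false(identical(b1$P, b2$P))
})

test_that("permutation p-values live on the 1/B lattice", {
  set.seed(131)
  for (i in 1:5) {
    d <- rand_data(5, 5, 8, shift = runif(1, 0, 1))
    r <- agcp_test(d, B = 40, seed = i)
    expect_true(r$p.value %in% ((0:40) / 40))
    ra <- agcp_test(d, B = 40, seed = i, add_one = TRUE)
    expect_equal(ra$p.value, (r$p.value * 40 + 1) / 41)
  }
})

test_that("exhaustive AGCP equals brute-force enumeration bit for bit", {
  set.seed(141)
  for (i in 1:8) {
    X1 <- matrix(rnorm(6, mean = i / 4), 3, 2)
    X2 <- matrix(rnorm(6), 3, 2)
    got <- agcp_test(two_sample_matrix(X1, X2), mode = "exhaustive",
                     method = "wilcoxon_exact")
    want <- oracle_exhaustive_agcp(X1, X2, default_thresholds())
    expect_identical(got$p.value, want$pvalue)
    expect_equal(got$statistic, want$agcp0, tolerance = 1e-12)
  }
})

test_that("swapping the two groups leaves the exhaustive test invariant", {
  set.seed(151)
  d <- rand_data(3, 3, 4, shift = 0.8)
  r12 <- agcp_test(d, mode = "exhaustive")
  r21 <- agcp_test(two_sample_matrix(d$X2, d$X1), mode = "exhaustive")
  expect_identical(r12$statistic, r21$statistic)
  expect_identical(r12$p.value, r21$p.value)
})

test_that("degenerate schemes are refused", {
  expect_error(permutation_scheme(B = 0), "B must be")
  set.seed(161)
  d <- rand_data(4, 4, 3)
  expect_error(agcp_test(d, B = 0), "B must be")
})
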