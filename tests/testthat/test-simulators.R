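test_that("covariance templates match their definitions and are positive definite", {
  expect_equal(build_covariance("DS1", 2), matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(build_covariance("DS2", 4)[1, 3], 0.25)
  expect_equal(diag(build_covariance("DS3", 4)), c(1, 1, 3, 3))
  expect_equal(build_covariance("DS3", 6)[1, 2], 0.5)
  expect_error(build_covariance("DS3", 5), "even")
  for (m in c(2, 20, 100, 200)) {
    for (st in c("DS1", "DS2", "DS3")) {
      expect_silent(chol(build_covariance(st, m)))  # PD certificate
    }
  }
})

test_that("mean allocation hits the requested signal strength exactly", {
  expect_equal(sum(allocate_means(100, 0.3, 0.1, "equal",
                                  diag(100), diag(100)) != 0), 3)
  expect_equal(allocate_means(10, 0.3, 0, "equal", diag(10), diag(10)),
               numeric(10))
  # identity covariances, eta = 0.5, L = 2 equal entries:
  # c = sqrt(0.5 * sqrt(8) / 2)
  mu <- allocate_means(4, 0.5, 0.5, "equal", diag(4), diag(4))
  expect_equal(mu[1], sqrt(0.5 * sqrt(8) / 2), tolerance = 1e-12)
  expect_equal(mu[3:4], c(0, 0))

  # round trip over models, structures and allocations
  rho <- ma_coefficients(20, "FD")
  Sma <- ma_covariance(rho)
  cases <- expand.grid(gamma = c(0.1, 0.3, 0.4), eta = c(0.05, 0.2),
                       alloc = c("equal", "linear"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    for (S1 in list(build_covariance("DS1", 20), build_covariance("DS3", 20),
                    Sma)) {
      mu <- allocate_means(20, cases$gamma[i], cases$eta[i], cases$alloc[i],
                           S1, diag(20))
      expect_equal(signal_eta(mu, S1, diag(20)), cases$eta[i],
                   tolerance = 1e-10)
    }
  }
})

test_that("normal generator recovers its first two moments", {
  S <- build_covariance("DS2", 10)
  mu <- allocate_means(10, 0.5, 0.3, "equal", S, diag(10))
  d <- simulate_mvn(1e5, 2, mu, S, seed = 400)
  expect_lt(max(abs(colMeans(d$X1) - mu)), 4 * sqrt(max(diag(S)) / 1e5))
  expect_lt(max(abs(stats::cov(d$X1) - S)), 0.05)
  expect_lt(max(abs(colMeans(d$X2))), 4 / sqrt(2))  # group 2 is N(0, I)
})

test_that("t generator honors both matrix conventions and is heavy-tailed", {
  S <- build_covariance("DS1", 5)
  # covariance mode: draws have covariance S itself
  d <- simulate_mvt(4e5, 2, numeric(5), S, df = 4, seed = 401,
                    sigma_is = "covariance")
  expect_lt(max(abs(stats::cov(d$X1) - S)), 0.05)
  # scale mode (default): covariance is S * df/(df-2)
  d2 <- simulate_mvt(4e5, 2, numeric(5), S, df = 4, seed = 402)
  expect_lt(max(abs(stats::cov(d2$X1) - 2 * S)), 0.1)
  # tails heavier than normal: standardized fourth moment above 3
  x <- d2$X1[, 1]
  expect_gt(mean((x - mean(x))^4) / stats::var(x)^2, 3)
  # df -> infinity limit collapses to the normal generator's moments
  d3 <- simulate_mvt(2e5, 2, numeric(5), S, df = 1e6, seed = 403,
                     sigma_is = "covariance")
  expect_lt(max(abs(stats::cov(d3$X1) - S)), 0.05)
  expect_error(simulate_mvt(5, 5, 0, diag(1), df = 2), "df")
})

test_that("moving-average covariance matches hand convolutions", {
  # single nonzero coefficient, all-normal innovations: 4 I
  expect_equal(ma_covariance(c(2, 0, 0, 0), innovation_var = rep(1, 7)),
               4 * diag(4))
  # banded case in the normal-innovation region: sigma_{k,k+2} = rho1 rho3
  rho <- c(2, 2, 2, rep(0, 17))
  S <- ma_covariance(rho)
  expect_equal(S[15, 17], 4)          # windows entirely in the var-1 region
  expect_true(all(abs(S[abs(outer(1:20, 1:20, "-")) >= 3]) < 1e-12))
})

test_that("moving-average generator matches its analytic covariance", {
  rho <- ma_coefficients(10, "PD", seed = 55)
  S <- ma_covariance(rho)
  d <- simulate_ma(3e4, 2, numeric(10), rho, seed = 404)
  scale <- sqrt(outer(diag(S), diag(S)))  # entries are O(10-100) here
  emp <- stats::cov(d$X1)
  expect_lt(max(abs(emp - S) / scale), 0.1)
  # partial dependence: independence beyond lag 2, exactly and empirically
  far <- abs(outer(1:10, 1:10, "-")) >= 3
  expect_true(all(abs(S[far]) < 1e-12))
  expect_lt(max(abs(emp[far] / scale[far])), 0.1)
  # all-zero coefficients collapse to the mean
  d0 <- simulate_ma(3, 2, 1:4, rep(0, 4), seed = 405)
  expect_equal(d0$X1, matrix(rep(1:4, each = 3), 3), ignore_attr = TRUE)
})

test_that("generators are deterministic given a seed", {
  S <- build_covariance("DS1", 6)
  expect_identical(simulate_mvn(5, 5, numeric(6), S, seed = 9),
                   simulate_mvn(5, 5, numeric(6), S, seed = 9))
  expect_identical(simulate_mvt(5, 5, numeric(6), S, seed = 9),
                   simulate_mvt(5, 5, numeric(6), S, seed = 9))
  rho <- ma_coefficients(6, "FD")
  expect_identical(simulate_ma(5, 5, numeric(6), rho, seed = 9),
                   simulate_ma(5, 5, numeric(6), rho, seed = 9))
  expect_identical(ma_coefficients(6, "FD"), ma_coefficients(6, "FD"))
  expect_equal(sum(ma_coefficients(10, "PD") != 0), 3)
  expect_true(all(ma_coefficients(10, "FD") > 2 &
                  ma_coefficients(10, "FD") < 3))
})
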