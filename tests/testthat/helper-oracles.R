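# Independent reference implementations used as oracles: plain loops and
# stats:: functions only, no shared code with the package internals.

# Fisher bin sum by direct looping
oracle_bin_sum <- function(p, lo, hi) {
  s <- 0
  for (k in seq_along(p)) {
    if (p[k] >= lo && p[k] < hi) s <- s - 2 * log(p[k])
  }
  s
}

# naive double-loop GCP/AGCP on a (B+1) x m matrix of p-values
# (row 1 observed, rows 2..B+1 permuted)
oracle_agcp <- function(P, xi, add_one = FALSE) {
  B <- nrow(P) - 1
  S <- length(xi)
  pairs <- NULL
  for (a in seq_len(S - 1)) {
    for (b2 in (a + 1):S) pairs <- rbind(pairs, c(a, b2))
  }
  # GCP = -2 log{(B+1-c1)(B+1-c2)/(B+1)^2} decreases strictly in the integer
  # survival-count product, so maxima over pairs and comparisons between the
  # observed and permuted maxima are taken on that exact product scale
  # (distinct count pairs can tie exactly in the product; floating-point
  # logs would resolve such ties by rounding noise)
  G <- matrix(0, B + 1, nrow(pairs))
  Q <- matrix(0, B + 1, nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    s1 <- pairs[r, 1]
    s2 <- pairs[r, 2]
    T1 <- numeric(B + 1)
    T2 <- numeric(B + 1)
    for (i in seq_len(B + 1)) {
      T1[i] <- oracle_bin_sum(P[i, ], 0, xi[s1])
      T2[i] <- oracle_bin_sum(P[i, ], xi[s1], xi[s2])
    }
    for (i in seq_len(B + 1)) {
      c1 <- sum(T1[-1] <= T1[i])
      c2 <- sum(T2[-1] <= T2[i])
      G[i, r] <- -2 * (log(1 - c1 / (B + 1)) + log(1 - c2 / (B + 1)))
      Q[i, r] <- (B + 1 - c1) * (B + 1 - c2)
    }
  }
  best <- apply(Q, 1, which.min)           # smallest product = largest GCP
  qmax <- Q[cbind(seq_len(B + 1), best)]
  agcp <- G[cbind(seq_len(B + 1), best)]
  n_ge <- sum(qmax[-1] <= qmax[1])
  list(agcp0 = agcp[1],
       gcp_by_pair = G[1, ],
       argmax_pair = xi[pairs[best[1], ]],
       pvalue = if (add_one) (n_ge + 1) / (B + 1) else n_ge / B)
}

# per-column two-sided Wilcoxon p-values through stats::wilcox.test
oracle_wilcox_p <- function(X1, X2, exact) {
  vapply(seq_len(ncol(X1)), function(k) {
    stats::wilcox.test(X1[, k], X2[, k], exact = exact,
                       correct = FALSE)$p.value
  }, numeric(1))
}

# exhaustive-permutation AGCP by full enumeration: marginal p-values from
# stats::wilcox.test for every labeling, then the naive AGCP above with the
# complete labeling bank (the observed labeling is also one of the bank rows)
oracle_exhaustive_agcp <- function(X1, X2, xi) {
  n1 <- nrow(X1)
  X <- rbind(X1, X2)
  n <- nrow(X)
  labelings <- utils::combn(n, n1)
  Pbank <- t(apply(labelings, 2, function(idx) {
    oracle_wilcox_p(X[idx, , drop = FALSE], X[-idx, , drop = FALSE],
                    exact = TRUE)
  }))
  p_obs <- oracle_wilcox_p(X1, X2, exact = TRUE)
  oracle_agcp(rbind(p_obs, Pbank), xi)
}

# Chen-Qin statistic through the trace identity (the algebraic dual of the
# U-statistic form)
oracle_cq_identity <- function(X1, X2) {
  n1 <- nrow(X1)
  n2 <- nrow(X2)
  gap <- colMeans(X1) - colMeans(X2)
  sum(gap^2) - sum(diag(stats::cov(X1))) / n1 -
    sum(diag(stats::cov(X2))) / n2
}

# fresh random two-sample dataset
rand_data <- function(n1, n2, m, shift = 0) {
  two_sample_matrix(matrix(stats::rnorm(n1 * m, shift), n1),
                    matrix(stats::rnorm(n2 * m), n2))
}
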