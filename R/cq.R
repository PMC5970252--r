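# Chen-Qin high-dimensional mean test: the U-statistic version of the
# squared Euclidean mean gap, with the subject self-products removed so no
# explicit relationship between dimension and sample size is required, and
# asymptotic normal calibration through leave-out trace estimators. Serves
# as the comparator in the simulation studies.

#' Chen-Qin U-statistic
#'
#' \deqn{T_n = \frac{\sum_{i \ne j} X_{1i}'X_{1j}}{n_1(n_1-1)} +
#'       \frac{\sum_{i \ne j} X_{2i}'X_{2j}}{n_2(n_2-1)} -
#'       \frac{2\sum_{i,j} X_{1i}'X_{2j}}{n_1 n_2}}
#' an unbiased estimator of \eqn{\|\mu_1 - \mu_2\|^2}. Algebraically equal
#' to \eqn{\|\bar X_1 - \bar X_2\|^2 - \mathrm{tr}(S_1)/n_1 -
#' \mathrm{tr}(S_2)/n_2} with the unbiased sample covariances.
#'
#' @param data A [two_sample_matrix()].
#' @return The scalar statistic.
#' @export
cq_statistic <- function(data) {
  assert_two_sample(data)
  X1 <- data$X1
  X2 <- data$X2
  n1 <- data$n1
  n2 <- data$n2
  G1 <- tcrossprod(X1)
  G2 <- tcrossprod(X2)
  C12 <- X1 %*% t(X2)
  (sum(G1) - sum(diag(G1))) / (n1 * (n1 - 1)) +
    (sum(G2) - sum(diag(G2))) / (n2 * (n2 - 1)) -
    2 * sum(C12) / (n1 * n2)
}

# leave-two-out estimator of tr(Sigma^2) for one sample:
#   (n(n-1))^-1 sum_{j != k} X_j'(X_k - Xbar_(j,k)) X_k'(X_j - Xbar_(j,k))
# where Xbar_(j,k) is the sample mean without subjects j and k. Computed
# from the Gram matrix: X_j'(X_k - Xbar_(j,k)) = G_jk - (rs_j - G_jj - G_jk)/(n-2)
# with rs_j = sum_k G_jk.
trace_sigma2_hat <- function(X) {
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples per group", call. = FALSE)
  G <- tcrossprod(X)
  rs <- rowSums(G)
  A <- G - (rs - diag(G) - G) / (n - 2)
  tot <- sum(A * t(A)) - sum(diag(A)^2)
  tot / (n * (n - 1))
}

# leave-one-out estimator of tr(Sigma1 Sigma2):
#   (n1 n2)^-1 sum_{l,k} X1l'(X2k - Xbar2_(k)) X2k'(X1l - Xbar1_(l))
trace_sigma12_hat <- function(X1, X2) {
  n1 <- nrow(X1)
  n2 <- nrow(X2)
  C <- X1 %*% t(X2)
  B1 <- C - (rowSums(C) - C) / (n2 - 1)   # X1l'(X2k - Xbar2_(k))
  B2 <- C - sweep(-C, 2L, colSums(C), "+") / (n1 - 1)  # X2k'(X1l - Xbar1_(l))
  sum(B1 * B2) / (n1 * n2)
}

#' Chen-Qin two-sample mean test
#'
#' Standardizes [cq_statistic()] by the estimated null standard deviation
#' \deqn{\hat\sigma^2 = \frac{2\widehat{\mathrm{tr}}(\Sigma_1^2)}{n_1(n_1-1)}
#'  + \frac{2\widehat{\mathrm{tr}}(\Sigma_2^2)}{n_2(n_2-1)}
#'  + \frac{4\widehat{\mathrm{tr}}(\Sigma_1\Sigma_2)}{n_1 n_2}}
#' using leave-out trace estimators, and refers \eqn{z = T_n/\hat\sigma} to
#' the upper tail of the standard normal (the alternative is
#' \eqn{\|\mu_1-\mu_2\|^2 > 0}, so the test is one-sided).
#'
#' @param data A [two_sample_matrix()].
#' @param alpha Nominal level for the recorded rejection decision.
#' @return A `"cq_test"` list: `tn`, `sigma_hat`, `z`, `p.value`, `reject`,
#'   `alpha`.
#' @export
cq_test <- function(data, alpha = 0.05) {
  assert_two_sample(data)
  n1 <- data$n1
  n2 <- data$n2
  if (n1 < 4L || n2 < 4L) {
    stop("the variance estimator needs at least 4 samples per group",
         call. = FALSE)
  }
  tn <- cq_statistic(data)
  s2 <- 2 * trace_sigma2_hat(data$X1) / (n1 * (n1 - 1)) +
    2 * trace_sigma2_hat(data$X2) / (n2 * (n2 - 1)) +
    4 * trace_sigma12_hat(data$X1, data$X2) / (n1 * n2)
  if (!is.finite(s2) || s2 <= 0) {
    stop("estimated null variance is not positive (s2 = ", format(s2),
         "); the sample is too small or degenerate for the asymptotic ",
         "calibration", call. = FALSE)
  }
  z <- tn / sqrt(s2)
  p <- stats::pnorm(z, lower.tail = FALSE)
  structure(list(tn = tn, sigma_hat = sqrt(s2), z = z, p.value = p,
                 reject = p <= alpha, alpha = alpha),
            class = "cq_test")
}

#' @export
print.cq_test <- function(x, ...) {
  cat("\n\tChen-Qin high-dimensional mean test\n\n")
  cat("Tn =", format(x$tn, digits = 5),
      "  z =", format(x$z, digits = 5),
      "  p-value =", format(x$p.value, digits = 5), "\n")
  invisible(x)
}
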