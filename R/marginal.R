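# Marginal two-sample tests applied variable by variable. The global test
# only consumes the resulting p-values, so any valid univariate two-sample
# test can stand here; the Wilcoxon rank-sum test is the default because it
# is distribution-free and robust to the heavy tails common in expression
# data.

MARGINAL_METHODS <- c("auto", "wilcoxon_exact", "wilcoxon_normal", "t_test")

# exact Wilcoxon is precomputed per (n1, n2); only practical for small groups
EXACT_MAX_GROUP <- 25L

# Two-sided exact Wilcoxon p-values indexed by the Mann-Whitney count
# U = W1 - n1(n1+1)/2 in 0..n1*n2. p(u) = min(1, 2 * min(P(U <= u), P(U >= u))).
# Built from pwilcox so values agree bitwise with stats::wilcox.test.
wilcox_exact_ptable <- function(n1, n2) {
  u <- 0:(n1 * n2)
  lower <- stats::pwilcox(u, n1, n2)
  upper <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

# Normal-approximation analogue, tabulated over the attainable tie-free
# rank sums (U = 0..n1*n2): no ties means a single null standard deviation
# shared by all columns, so the p-value is a function of U alone.
wilcox_normal_ptable <- function(n1, n2) {
  n <- n1 + n2
  u <- 0:(n1 * n2)
  w <- u + n1 * (n1 + 1) / 2
  z <- (w - n1 * (n + 1) / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

# memoised across calls: identical sample sizes recur for every column,
# permutation and replicate; each entry holds the p-values and the matching
# Fisher terms -2 log p so both come from one lookup
.ptable_env <- new.env(parent = emptyenv())
wilcox_tables_cached <- function(n1, n2, exact) {
  key <- paste0(if (exact) "e" else "n", n1, "_", n2)
  tab <- .ptable_env[[key]]
  if (is.null(tab)) {
    p <- if (exact) wilcox_exact_ptable(n1, n2)
         else wilcox_normal_ptable(n1, n2)
    tab <- list(p = p, l = -2 * log(p))
    .ptable_env[[key]] <- tab
  }
  tab
}

#' Pooled per-column midrank cache
#'
#' Computes the pooled midranks of every column once. Permuting group labels
#' does not change pooled ranks, so the same cache serves the observed
#' labeling and every permutation: the Wilcoxon rank-sum statistic for any
#' labeling is just a row-subset sum of this matrix.
#'
#' @param data A [two_sample_matrix()].
#' @return A `"rank_cache"` list: `ranks` (n x m midranks), `has_ties`
#'   (per-column flag), `sd` (tie-corrected null standard deviation of the
#'   group-1 rank sum), `mean` (its null mean), plus the group sizes.
#' @examples
#' d <- two_sample_matrix(matrix(c(3, 1), 2), matrix(c(2, 2), 2))
#' rank_cache(d)$ranks
#' @export
rank_cache <- function(data) {
  assert_two_sample(data)
  X <- pooled_matrix(data)
  n <- nrow(X)
  m <- ncol(X)
  n1 <- data$n1
  n2 <- data$n2
  info <- .col_rank_info_cpp(X)    # midranks + tie diagnostics per column
  R <- info$ranks
  has_ties <- info$has_ties
  tie_term <- info$tie_term
  sd_w <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
  structure(
    list(ranks = R, n1 = n1, n2 = n2, n = n, m = m,
         has_ties = has_ties, sd = sd_w, mean = n1 * (n + 1) / 2),
    class = "rank_cache"
  )
}

# p-values (and their Fisher terms -2 log p) from a matrix of group-1 rank
# sums, one row per labeling. Tie-free columns have integer rank sums, so
# both quantities are table lookups (exact null, or its normal
# approximation); columns with ties use the tie-corrected normal
# approximation column by column (no continuity correction).
ranksum_pvalues <- function(rc, W, exact) {
  if (!is.matrix(W)) W <- matrix(W, nrow = 1L)
  P <- matrix(NA_real_, nrow(W), ncol(W))
  L <- matrix(NA_real_, nrow(W), ncol(W))
  free <- !rc$has_ties
  if (any(free)) {
    tab <- wilcox_tables_cached(rc$n1, rc$n2, exact)
    U <- W[, free, drop = FALSE] - rc$n1 * (rc$n1 + 1) / 2
    idx <- as.integer(round(U)) + 1L
    P[, free] <- tab$p[idx]
    L[, free] <- tab$l[idx]
  }
  if (any(!free)) {
    j <- which(!free)
    Z <- sweep(W[, j, drop = FALSE] - rc$mean, 2L, rc$sd[j], "/")
    Pj <- 2 * stats::pnorm(-abs(Z))
    # degenerate column (all pooled values equal): no evidence
    Pj[, rc$sd[j] == 0] <- 1
    Pj <- pmax(Pj, .Machine$double.xmin)
    P[, j] <- Pj
    L[, j] <- -2 * log(Pj)
  }
  list(P = P, L = L)
}

resolve_method <- function(method, n1, n2) {
  method <- match.arg(method, MARGINAL_METHODS)
  if (method == "auto") {
    method <- if (min(n1, n2) <= EXACT_MAX_GROUP) "wilcoxon_exact"
              else "wilcoxon_normal"
  }
  if (method == "wilcoxon_exact" && min(n1, n2) > EXACT_MAX_GROUP) {
    stop("wilcoxon_exact is only supported for min(n1, n2) <= ",
         EXACT_MAX_GROUP, "; use 'wilcoxon_normal'", call. = FALSE)
  }
  method
}

# Welch t-test p-values for a set of labelings described by a 0/1 indicator
# matrix Z (rows = labelings, 1 = group 1). Vectorised through the sufficient
# statistics Z %*% X and Z %*% X^2.
welch_pvalues <- function(X, Z, n1, n2) {
  tot <- colSums(X)
  tot2 <- colSums(X^2)
  S1 <- Z %*% X
  Q1 <- Z %*% (X^2)
  m1 <- S1 / n1
  m2 <- sweep(-S1, 2L, tot, "+") / n2
  v1 <- (Q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (sweep(-Q1, 2L, tot2, "+") - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0)
  v2 <- pmax(v2, 0)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  P <- 2 * stats::pt(-abs(tstat), df)
  P[se2 == 0] <- 1                  # zero pooled variance: flag as no evidence
  pmax(P, .Machine$double.xmin)
}

#' Marginal two-sample p-values
#'
#' Applies a univariate two-sample test to each column of the data and
#' returns the vector of two-sided p-values \eqn{p_1, \dots, p_m}. These are
#' the raw material of the group-combined statistics: every p-value is
#' strictly positive so that \eqn{\ln p_k} is always finite.
#'
#' Methods:
#' \describe{
#'   \item{`wilcoxon_exact`}{Exact rank-sum null (two-sided tail
#'     probabilities of the hypergeometric-rank distribution); only for
#'     `min(n1, n2) <= 25`. Columns with ties fall back automatically to the
#'     tie-corrected normal approximation with midranks.}
#'   \item{`wilcoxon_normal`}{Normal approximation with midranks and
#'     tie-corrected variance, no continuity correction.}
#'   \item{`t_test`}{Welch two-sample t-test; a column with zero pooled
#'     variance yields p = 1.}
#'   \item{`auto`}{`wilcoxon_exact` when `min(n1, n2) <= 25`, else
#'     `wilcoxon_normal`.}
#' }
#'
#' @param data A [two_sample_matrix()].
#' @param method One of `"auto"`, `"wilcoxon_exact"`, `"wilcoxon_normal"`,
#'   `"t_test"`.
#' @return Numeric vector of length `m` with entries in (0, 1].
#' @examples
#' d <- two_sample_matrix(matrix(c(1, 2)), matrix(c(3, 4)))
#' marginal_pvalues(d, "wilcoxon_exact")  # 1/3
#' @export
marginal_pvalues <- function(data, method = "auto") {
  assert_two_sample(data)
  method <- resolve_method(method, data$n1, data$n2)
  if (method == "t_test") {
    Z <- matrix(0, 1L, data$n)
    Z[1L, seq_len(data$n1)] <- 1
    p <- welch_pvalues(pooled_matrix(data), Z, data$n1, data$n2)
  } else {
    rc <- rank_cache(data)
    W <- matrix(colSums(rc$ranks[seq_len(data$n1), , drop = FALSE]),
                nrow = 1L)
    p <- ranksum_pvalues(rc, W, exact = method == "wilcoxon_exact")$P
  }
  as.numeric(p)
}
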