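# Group-combined p-value (GCP) statistics and their adaptive maximum (AGCP).
#
# For an ordered threshold pair (xi_{s1}, xi_{s2}) the marginal p-values are
# split into three groups: p < xi_{s1}, xi_{s1} <= p < xi_{s2}, and the rest
# (discarded). Each retained group is Fisher-combined, the two sums are
# mapped through -2 log(1 - F) using their null CDFs, and added:
#
#   GCP(xi_{s1}, xi_{s2}) = -2 log{1 - F_{s1}(T1)} - 2 log{1 - F_{s2}(T2)},
#   T1 = -2 sum_k log(p_k) I(p_k < xi_{s1}),
#   T2 = -2 sum_k log(p_k) I(xi_{s1} <= p_k < xi_{s2}).
#
# AGCP maximizes GCP over all ordered pairs from a candidate threshold set.

#' Default threshold set
#'
#' The recommended candidate thresholds for the adaptive test:
#' `{0.0001, 0.001, 0.01, 0.05, 0.1, 0.2, 1}`, giving `choose(7, 2) = 21`
#' ordered pairs. Values above 0.2 rarely carry signal but inflate the
#' variance of Fisher sums, hence 0.2 is the largest "real" cut-point; the
#' sentinel 1 lets the second group absorb everything up to (but excluding)
#' p = 1.
#'
#' @return Numeric vector of 7 thresholds.
#' @export
default_thresholds <- function() c(0.0001, 0.001, 0.01, 0.05, 0.1, 0.2, 1)

validate_thresholds <- function(xi) {
  xi <- sort(unique(as.numeric(xi)))
  if (length(xi) < 2L) stop("need at least 2 distinct thresholds",
                            call. = FALSE)
  if (any(xi <= 0) || any(xi > 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  xi
}

# all ordered pairs s1 < s2, in lexicographic order (ties in the adaptive
# maximum are broken toward the first pair in this order)
threshold_pairs <- function(xi) {
  S <- length(xi)
  do.call(rbind, lapply(seq_len(S - 1L),
                        function(a) cbind(s1 = a, s2 = (a + 1L):S)))
}

#' Fisher bin sum of marginal p-values
#'
#' Computes \eqn{T = -2 \sum_k \ln(p_k)} over the p-values falling in a
#' threshold bin. The lower bound is inclusive and the upper bound strict;
#' `lo = 0` is the sentinel for the first group, `p < hi`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param lo Lower bin edge (0 for the first group).
#' @param hi Upper bin edge, strict.
#' @return List with `T` (nonnegative; 0 for an empty bin) and `count`.
#' @examples
#' group_statistic(c(0.5, 0.9), 0.2, 1)  # -2*(log(0.5) + log(0.9))
#' @export
group_statistic <- function(p, lo, hi) {
  if (any(p <= 0)) stop("p-values must be strictly positive", call. = FALSE)
  if (lo < 0 || hi <= lo || hi > 1) {
    stop("need 0 <= lo < hi <= 1", call. = FALSE)
  }
  sel <- if (lo <= 0) p < hi else p >= lo & p < hi
  list(T = -2 * sum(log(p[sel])), count = sum(sel))
}

#' Empirical CDF of a permutation null sample
#'
#' Evaluates \eqn{\hat F(t) = \#\{b : T^{(b)} \le t\} / (B + 1)}. The `B + 1`
#' denominator keeps \eqn{1 - \hat F} bounded away from zero so the
#' \eqn{-2\log(1-\hat F)} transform stays finite; it is applied identically
#' to observed and permuted statistics, preserving exchangeability.
#'
#' @param sorted_null Ascending numeric vector of B null values.
#' @param t Evaluation points (vectorised).
#' @return Values in `[0, B/(B+1)]`, nondecreasing in `t`.
#' @examples
#' ecdf_value(c(1, 2, 3, 4), 2.5)  # 0.4
#' @export
ecdf_value <- function(sorted_null, t) {
  findInterval(t, sorted_null) / (length(sorted_null) + 1)
}

# Per-row Fisher sums over the elementary bins [xi_{s-1}, xi_s) (xi_0 = 0).
# Bin sums for any threshold pair are built by adding elementary sums left to
# right: purely nonnegative accumulation, so rows whose p-values agree inside
# a bin produce bitwise-identical sums regardless of what sits outside it
# (a cumulant-difference shortcut would lose that through cancellation and
# make exact permutation ties implementation-dependent).
elementary_bin_sums <- function(P, xi) {
  if (!is.matrix(P)) P <- matrix(P, nrow = 1L)
  if (any(P <= 0)) stop("p-values must be strictly positive", call. = FALSE)
  L <- -2 * log(P)
  S <- length(xi)
  D <- matrix(0, nrow(P), S)
  lo <- 0
  for (s in seq_len(S)) {
    D[, s] <- rowSums(L * (P >= lo & P < xi[s]))
    lo <- xi[s]
  }
  D
}

# left-to-right sum of elementary bins a..b (columns of D)
bin_range_sum <- function(D, a, b) {
  out <- D[, a]
  s <- a
  while (s < b) {
    s <- s + 1L
    out <- out + D[, s]
  }
  out
}

# Null-CDF tables for every ordered threshold pair, from a B x m matrix of
# permuted marginal p-values. Stored sorted so lookups are binary searches.
build_pair_cdfs <- function(null_p, xi) {
  xi <- validate_thresholds(xi)
  if (!is.matrix(null_p)) null_p <- matrix(null_p, nrow = 1L)
  pairs <- threshold_pairs(xi)
  D <- elementary_bin_sums(null_p, xi)
  tabs <- lapply(seq_len(nrow(pairs)), function(r) {
    s1 <- pairs[r, 1L]
    s2 <- pairs[r, 2L]
    list(T1 = sort(bin_range_sum(D, 1L, s1)),
         T2 = sort(bin_range_sum(D, s1 + 1L, s2)))
  })
  structure(list(xi = xi, pairs = pairs, tables = tabs, B = nrow(null_p)),
            class = "pair_cdfs")
}

pair_index <- function(cdfs, s1, s2) {
  r <- which(cdfs$pairs[, 1L] == s1 & cdfs$pairs[, 2L] == s2)
  if (length(r) != 1L) {
    stop("threshold pair (", s1, ", ", s2, ") not present in the CDF table",
         call. = FALSE)
  }
  r
}

#' GCP statistic for one threshold pair
#'
#' @param p Numeric vector of marginal p-values in (0, 1].
#' @param pair Integer pair `c(s1, s2)` with `s1 < s2`, indexing the
#'   threshold set used to build `cdfs`.
#' @param cdfs Null-CDF tables built from a permutation bank (see
#'   [build_null_bank()]).
#' @return The nonnegative, finite GCP value.
#' @export
gcp_statistic <- function(p, pair, cdfs) {
  stopifnot(inherits(cdfs, "pair_cdfs"), length(pair) == 2L,
            pair[1L] < pair[2L])
  r <- pair_index(cdfs, pair[1L], pair[2L])
  xi <- cdfs$xi
  t1 <- group_statistic(p, 0, xi[pair[1L]])$T
  t2 <- group_statistic(p, xi[pair[1L]], xi[pair[2L]])$T
  f1 <- ecdf_value(cdfs$tables[[r]]$T1, t1)
  f2 <- ecdf_value(cdfs$tables[[r]]$T2, t2)
  -2 * (log1p(-f1) + log1p(-f2))
}

#' Adaptive maximum of GCP over all ordered threshold pairs
#'
#' @inheritParams gcp_statistic
#' @param thresholds Candidate threshold set (defaults to the set used to
#'   build `cdfs`).
#' @return List with `agcp` (the maximum), `argmax_pair` (thresholds
#'   attaining it; ties go to the lexicographically first pair) and
#'   `gcp_by_pair`.
#' @export
agcp_statistic <- function(p, thresholds = NULL, cdfs) {
  stopifnot(inherits(cdfs, "pair_cdfs"))
  xi <- if (is.null(thresholds)) cdfs$xi else validate_thresholds(thresholds)
  if (!isTRUE(all.equal(xi, cdfs$xi))) {
    stop("thresholds do not match the ones the CDF tables were built for",
         call. = FALSE)
  }
  g <- vapply(seq_len(nrow(cdfs$pairs)),
              function(r) gcp_statistic(p, cdfs$pairs[r, ], cdfs),
              numeric(1))
  best <- which.max(g)
  list(agcp = g[best],
       argmax_pair = xi[cdfs$pairs[best, ]],
       gcp_by_pair = g)
}

# Fast path used by the permutation engine: takes the observed p-vector as
# row 1 and the B permuted vectors below it, and computes GCP for every row
# and pair at once (compiled kernel). Row 1 is excluded from the null CDFs;
# the (B+1) ECDF convention matches ecdf_value(). The kernel accumulates bin
# sums in the same left-to-right elementary-bin order as the scalar path, so
# exact permutation ties behave identically in both.
agcp_core <- function(P, xi, add_one = FALSE, L = NULL) {
  xi <- validate_thresholds(xi)
  if (!is.matrix(P)) P <- matrix(P, nrow = 1L)
  if (nrow(P) < 2L) stop("need at least one permutation row", call. = FALSE)
  if (is.null(L)) L <- -2 * log(P)
  agcp_core_from(.agcp_core_cpp(P, L, xi, isTRUE(add_one)), xi)
}

# annotate the raw kernel output with the threshold-pair bookkeeping
agcp_core_from <- function(out, xi) {
  pairs <- threshold_pairs(xi)
  list(agcp0 = out$agcp0,
       agcp_null = out$agcp_null,
       gcp_by_pair = out$gcp_by_pair,
       pairs = pairs,
       argmax_pair = xi[pairs[out$argmax, ]],
       pvalue = out$pvalue)
}
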