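# One-layer permutation calibration of the adaptive statistic. A single bank
# of B label permutations supplies both the null CDFs of the bin sums and
# the null distribution of the maximized statistic, avoiding the nested
# (two-layer) resampling a naive calibration of an adaptive maximum would
# require.

#' Permutation scheme
#'
#' @param B Number of permutations (ignored for `mode = "exhaustive"`, where
#'   every n1-subset of the pooled samples is enumerated).
#' @param mode `"random"` draws B uniform n1-subsets of the pooled rows
#'   independently, with replacement from the labeling space (the identity
#'   labeling may recur); `"exhaustive"` enumerates all `choose(n, n1)`
#'   labelings.
#' @param seed Optional integer; when given, the subset draws are
#'   reproducible from it. `NULL` uses the current RNG stream.
#' @param exhaustive_cap Safety cap on `choose(n, n1)` for exhaustive mode.
#' @return A `"permutation_scheme"` list.
#' @export
permutation_scheme <- function(B = 10000L, mode = c("random", "exhaustive"),
                               seed = NULL, exhaustive_cap = 1e5) {
  mode <- match.arg(mode)
  B <- as.integer(B)
  if (mode == "random" && B < 1L) stop("B must be >= 1", call. = FALSE)
  structure(list(B = B, mode = mode, seed = seed,
                 exhaustive_cap = exhaustive_cap),
            class = "permutation_scheme")
}

# 0/1 indicator matrix (one row per labeling, 1 = assigned to group 1),
# always with the observed labeling (rows 1..n1) as the first row; the
# remaining rows are the permutation bank.
labeling_matrix <- function(n, n1, scheme) {
  if (scheme$mode == "exhaustive") {
    n_lab <- choose(n, n1)
    if (n_lab > scheme$exhaustive_cap) {
      stop("choose(", n, ", ", n1, ") = ", n_lab,
           " exceeds the exhaustive cap; use mode = 'random'", call. = FALSE)
    }
    idx <- utils::combn(n, n1)
    B <- ncol(idx)
    Z <- matrix(0, B, n)
    Z[cbind(rep(seq_len(B), each = n1), as.vector(idx))] <- 1
  } else {
    if (!is.null(scheme$seed)) set.seed(as.integer(scheme$seed))
    Z <- .random_subsets_cpp(n, n1, scheme$B)
  }
  obs <- matrix(0, 1L, n)
  obs[1L, seq_len(n1)] <- 1
  rbind(obs, Z)
}

# Full engine dispatch: rank-sum data with no ties anywhere go through the
# fused lookup kernel (rank sums map to p-values, Fisher terms and bins by
# integer tables); anything else materializes the p-value rows first.
agcp_engine <- function(data, method, xi, Z, add_one) {
  if (method != "t_test") {
    rc <- rank_cache(data)
    W <- Z %*% rc$ranks
    if (!any(rc$has_ties)) {
      tab <- wilcox_tables_cached(rc$n1, rc$n2, method == "wilcoxon_exact")
      bin <- as.integer(rowSums(outer(tab$p, xi, ">=")))
      offset <- rc$n1 * (rc$n1 + 1) / 2
      core <- agcp_core_from(
        .agcp_ranksum_cpp(W, offset, bin, tab$l, length(xi), add_one), xi)
      u_obs <- as.integer(round(W[1L, ] - offset)) + 1L
      return(list(core = core, marginal_p = tab$p[u_obs]))
    }
    pv <- ranksum_pvalues(rc, W, exact = method == "wilcoxon_exact")
  } else {
    P <- welch_pvalues(pooled_matrix(data), Z, data$n1, data$n2)
    pv <- list(P = P, L = -2 * log(P))
  }
  core <- agcp_core(pv$P, xi, add_one = add_one, L = pv$L)
  list(core = core, marginal_p = as.numeric(pv$P[1L, ]))
}

# marginal p-values (and Fisher terms -2 log p) for every labeling row of Z
# (first row = observed)
pvalue_rows <- function(data, method, Z) {
  method <- resolve_method(method, data$n1, data$n2)
  if (method == "t_test") {
    P <- welch_pvalues(pooled_matrix(data), Z, data$n1, data$n2)
    list(P = P, L = -2 * log(P))
  } else {
    rc <- rank_cache(data)
    W <- Z %*% rc$ranks
    ranksum_pvalues(rc, W, exact = method == "wilcoxon_exact")
  }
}

#' Bank of permuted marginal p-values
#'
#' Runs Steps 1-2 of the one-layer algorithm: relabels the pooled samples B
#' times (preserving group sizes) and computes the full vector of marginal
#' p-values for each relabeled dataset. Pooled midranks are computed once
#' and reused for every permutation, since relabeling does not change them.
#'
#' @param data A [two_sample_matrix()].
#' @param method Marginal test, see [marginal_pvalues()].
#' @param scheme A [permutation_scheme()].
#' @return A `"null_pvalue_bank"` list with `P` (B x m matrix of p-values,
#'   row b from the b-th permuted dataset), `observed` (p-values of the
#'   original labeling), `B`, `method` and `scheme`.
#' @export
build_null_bank <- function(data, method = "auto",
                            scheme = permutation_scheme()) {
  assert_two_sample(data)
  stopifnot(inherits(scheme, "permutation_scheme"))
  Z <- labeling_matrix(data$n, data$n1, scheme)
  pv <- pvalue_rows(data, method, Z)$P
  structure(
    list(P = pv[-1L, , drop = FALSE], observed = as.numeric(pv[1L, ]),
         B = nrow(pv) - 1L, method = resolve_method(method, data$n1, data$n2),
         scheme = scheme),
    class = "null_pvalue_bank"
  )
}

#' Adaptive group-combined p-value test
#'
#' The full one-layer permutation test for the high-dimensional two-sample
#' location problem. Marginal p-values are computed for the observed
#' labeling and for B group-size-preserving relabelings; the relabeled
#' p-value vectors provide empirical null CDFs for every threshold pair; the
#' adaptive maximum statistic is evaluated for the observed and all permuted
#' vectors against those same CDFs; and the permutation p-value is
#' `#\{AGCP_b >= AGCP_0\} / B` over the B permutations.
#'
#' @param data A [two_sample_matrix()], or a pair of matrices via `X2`.
#' @param thresholds Candidate threshold set in (0, 1]; defaults to
#'   [default_thresholds()].
#' @param method Marginal test, see [marginal_pvalues()].
#' @param B Number of permutations (when `scheme` is not supplied).
#' @param mode `"random"` or `"exhaustive"` (when `scheme` is not supplied).
#' @param seed Optional integer seed for the permutation draws; `NULL` uses
#'   the current RNG stream.
#' @param scheme A [permutation_scheme()] overriding `B`/`mode`/`seed`.
#' @param add_one When `TRUE`, report the smoothed estimator
#'   `(count + 1)/(B + 1)` instead of the raw `count/B` (which can be 0).
#' @param X2 Optional group-2 matrix when `data` is a plain matrix.
#' @return An `"agcp_test"` object: `statistic` (observed AGCP), `p.value`,
#'   `argmax_pair`, `gcp_by_pair` (named by threshold pair), `marginal_p`
#'   (observed marginal p-values), `B`, `method`, `thresholds`, `mode`.
#' @examples
#' set.seed(1)
#' d <- two_sample_matrix(matrix(rnorm(5 * 20), 5),
#'                        matrix(rnorm(5 * 20, 1), 5))
#' agcp_test(d, B = 200, seed = 7)
#' @export
agcp_test <- function(data, thresholds = default_thresholds(),
                      method = "auto", B = 10000L,
                      mode = c("random", "exhaustive"), seed = NULL,
                      scheme = NULL, add_one = FALSE, X2 = NULL) {
  if (!is_two_sample(data)) data <- two_sample_matrix(data, X2)
  if (is.null(scheme)) {
    scheme <- permutation_scheme(B = B, mode = match.arg(mode), seed = seed)
  }
  xi <- validate_thresholds(thresholds)
  method <- resolve_method(method, data$n1, data$n2)
  Z <- labeling_matrix(data$n, data$n1, scheme)
  eng <- agcp_engine(data, method, xi, Z, add_one)
  core <- eng$core
  pair_names <- apply(core$pairs, 1L,
                      function(pr) paste0("(", xi[pr[1L]], ",", xi[pr[2L]], ")"))
  structure(
    list(statistic = core$agcp0,
         p.value = core$pvalue,
         argmax_pair = core$argmax_pair,
         gcp_by_pair = stats::setNames(core$gcp_by_pair, pair_names),
         marginal_p = eng$marginal_p,
         agcp_null = core$agcp_null,
         B = nrow(Z) - 1L,
         method = method,
         thresholds = xi,
         mode = scheme$mode,
         add_one = add_one),
    class = "agcp_test"
  )
}

#' @export
print.agcp_test <- function(x, ...) {
  cat("\n\tAdaptive group-combined p-value (AGCP) permutation test\n\n")
  cat("marginal test:", x$method, "   variables:", length(x$marginal_p), "\n")
  cat("AGCP =", format(x$statistic, digits = 5),
      "  attained at thresholds (",
      paste(format(x$argmax_pair), collapse = ", "), ")\n")
  cat("permutations:", x$B, paste0("(", x$mode, ")"),
      "  p-value =", format(x$p.value, digits = 5), "\n")
  invisible(x)
}
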