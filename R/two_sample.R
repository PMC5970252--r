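#' Two-sample data container
#'
#' Bundles the two groups of a high-dimensional two-sample location problem
#' into a validated object. Rows are samples (subjects, arrays), columns are
#' variables (genes, probes); both groups must observe the same variables.
#'
#' @param X1 Numeric matrix, `n1` samples by `m` variables (group 1).
#' @param X2 Numeric matrix, `n2` samples by `m` variables (group 2).
#' @return An object of class `"two_sample_matrix"` with elements `X1`, `X2`,
#'   `n1`, `n2`, `n = n1 + n2` and `m`.
#' @examples
#' d <- two_sample_matrix(matrix(rnorm(20), 4), matrix(rnorm(25), 5))
#' d$m
#' @export
two_sample_matrix <- function(X1, X2) {
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  storage.mode(X1) <- "double"
  storage.mode(X2) <- "double"
  if (ncol(X1) != ncol(X2)) {
    stop("X1 and X2 must have the same number of columns (variables); got ",
         ncol(X1), " and ", ncol(X2), call. = FALSE)
  }
  if (ncol(X1) < 1L) stop("at least one variable is required", call. = FALSE)
  if (nrow(X1) < 2L || nrow(X2) < 2L) {
    stop("each group needs at least 2 samples; got n1 = ", nrow(X1),
         ", n2 = ", nrow(X2), call. = FALSE)
  }
  if (!all(is.finite(X1)) || !all(is.finite(X2))) {
    stop("all entries must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  structure(
    list(X1 = X1, X2 = X2,
         n1 = nrow(X1), n2 = nrow(X2),
         n = nrow(X1) + nrow(X2), m = ncol(X1)),
    class = "two_sample_matrix"
  )
}

#' @export
print.two_sample_matrix <- function(x, ...) {
  cat("Two-sample data: n1 =", x$n1, ", n2 =", x$n2,
      ", m =", x$m, "variables\n")
  invisible(x)
}

# pooled n x m matrix, group 1 rows first
pooled_matrix <- function(data) rbind(data$X1, data$X2)

is_two_sample <- function(x) inherits(x, "two_sample_matrix")

assert_two_sample <- function(x) {
  if (!is_two_sample(x)) {
    stop("expected a 'two_sample_matrix' object; see two_sample_matrix()",
         call. = FALSE)
  }
  invisible(x)
}
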