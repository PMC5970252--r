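# Synthetic two-sample generators used in the simulation studies: three
# data models (multivariate normal, multivariate t with 4 df, moving-average
# processes with mixed Gamma/normal innovations) crossed with structured
# covariances, and sparse mean shifts whose magnitude is calibrated through
# a signal-to-noise parameter eta so power is comparable across dimensions
# and covariance structures.

#' Structured covariance matrices
#'
#' Three standard dependence templates for the group-1 covariance:
#' \describe{
#'   \item{DS1}{compound symmetry: unit variances, all off-diagonals 0.5.}
#'   \item{DS2}{geometric decay: \eqn{\sigma_{u,v} = 0.5^{|u-v|}}.}
#'   \item{DS3}{geometric decay off the diagonal with a two-block
#'     heterogeneous diagonal: variance 1 for the first m/2 variables, 3 for
#'     the rest (m must be even).}
#'   \item{identity}{the m x m identity.}
#' }
#'
#' @param structure One of `"DS1"`, `"DS2"`, `"DS3"`, `"identity"`.
#' @param m Dimension (even for DS3).
#' @return An m x m symmetric positive-definite matrix.
#' @examples
#' build_covariance("DS1", 3)
#' @export
build_covariance <- function(structure = c("DS1", "DS2", "DS3", "identity"),
                             m) {
  structure <- match.arg(structure)
  m <- as.integer(m)
  if (m < 2L && structure != "identity") {
    stop("m must be at least 2", call. = FALSE)
  }
  if (structure == "identity") return(diag(m))
  if (structure == "DS1") {
    S <- matrix(0.5, m, m)
    diag(S) <- 1
    return(S)
  }
  S <- 0.5^abs(outer(seq_len(m), seq_len(m), "-"))
  if (structure == "DS3") {
    if (m %% 2L != 0L) stop("DS3 requires an even dimension m", call. = FALSE)
    diag(S) <- rep(c(1, 3), each = m %/% 2L)
  }
  S
}

#' Sparse mean vector calibrated to a signal strength
#'
#' Places `L = floor(m^gamma)` nonzero entries at the first L coordinates of
#' the group-1 mean, either all equal (`"equal"`) or linearly increasing
#' (`"linear"`), and scales them so that
#' \deqn{\eta = \|\mu_1\|^2 / \sqrt{\mathrm{tr}(\Sigma_1^2) +
#'       \mathrm{tr}(\Sigma_2^2)}}
#' holds exactly (group 2 is centred at zero).
#'
#' @param m Dimension.
#' @param gamma Sparsity exponent in \[0, 1).
#' @param eta Nonnegative signal strength.
#' @param allocation `"equal"` or `"linear"`.
#' @param Sigma1,Sigma2 Covariance matrices entering the calibration.
#' @return Numeric mean vector of length m.
#' @examples
#' allocate_means(4, 0.5, 0.5, "equal", diag(4), diag(4))
#' @export
allocate_means <- function(m, gamma, eta, allocation = c("equal", "linear"),
                           Sigma1, Sigma2) {
  allocation <- match.arg(allocation)
  if (eta < 0) stop("eta must be nonnegative", call. = FALSE)
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)", call. = FALSE)
  L <- max(1L, floor(m^gamma))
  denom <- sqrt(sum(Sigma1 * Sigma1) + sum(Sigma2 * Sigma2))
  w <- if (allocation == "equal") rep(1, L) else seq_len(L)
  cc <- sqrt(eta * denom / sum(w^2))
  mu <- numeric(m)
  mu[seq_len(L)] <- cc * w
  mu
}

#' Signal strength of a mean shift
#'
#' The calibration functional \eqn{\eta = \|\mu_1 - \mu_2\|^2 /
#' \sqrt{\mathrm{tr}(\Sigma_1^2) + \mathrm{tr}(\Sigma_2^2)}}.
#'
#' @param mu1,mu2 Mean vectors (`mu2` defaults to zero).
#' @param Sigma1,Sigma2 Covariance matrices.
#' @return Nonnegative scalar.
#' @export
signal_eta <- function(mu1, Sigma1, Sigma2, mu2 = 0) {
  sum((mu1 - mu2)^2) / sqrt(sum(Sigma1 * Sigma1) + sum(Sigma2 * Sigma2))
}

#' Multivariate normal two-sample generator
#'
#' Group 1 is drawn from \eqn{N(\mu_1, \Sigma_1)}, group 2 from
#' \eqn{N(0, I)}.
#'
#' @param n1,n2 Group sizes.
#' @param mu1 Group-1 mean vector (length m).
#' @param Sigma1 Group-1 covariance (m x m positive definite).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A [two_sample_matrix()].
#' @export
simulate_mvn <- function(n1, n2, mu1, Sigma1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- length(mu1)
  R <- chol(Sigma1)
  X1 <- sweep(matrix(stats::rnorm(n1 * m), n1, m) %*% R, 2L, mu1, "+")
  X2 <- matrix(stats::rnorm(n2 * m), n2, m)
  two_sample_matrix(X1, X2)
}

#' Multivariate t two-sample generator
#'
#' Both groups are multivariate t with `df` degrees of freedom; group 1 is
#' centred at `mu1` with matrix parameter `Sigma1`, group 2 at zero with the
#' identity. By default `Sigma1` is the *scale* matrix of the t draws (the
#' usual multivariate-t parameterization, with covariance
#' `Sigma1 * df / (df - 2)`); set `sigma_is = "covariance"` to rescale so
#' the draws have covariance exactly `Sigma1`.
#'
#' @inheritParams simulate_mvn
#' @param df Degrees of freedom (> 2 so the covariance exists).
#' @param sigma_is `"scale"` (default) or `"covariance"`.
#' @return A [two_sample_matrix()].
#' @export
simulate_mvt <- function(n1, n2, mu1, Sigma1, df = 4, seed = NULL,
                         sigma_is = c("scale", "covariance")) {
  sigma_is <- match.arg(sigma_is)
  if (df <= 2) stop("df must exceed 2 for the covariance to exist",
                    call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- length(mu1)
  fac <- if (sigma_is == "covariance") (df - 2) / df else 1
  R1 <- chol(Sigma1 * fac)
  draw <- function(nn, Rchol, mu) {
    G <- matrix(stats::rnorm(nn * m), nn, m) %*% Rchol
    W <- stats::rchisq(nn, df)
    sweep(G / sqrt(W / df), 2L, mu, "+")
  }
  X1 <- draw(n1, R1, mu1)
  X2 <- draw(n2, diag(m) * sqrt(fac), rep(0, m))
  two_sample_matrix(X1, X2)
}

#' Moving-average coefficient vector
#'
#' Draws the MA coefficients \eqn{\rho_1, \dots, \rho_m} once, to be frozen
#' across all replicates of a study. `"FD"` (full dependence) draws every
#' coefficient from U(2, 3); `"PD"` (partial dependence) draws the first
#' three from U(2, 3) and zeroes the rest, so variables further than 2
#' positions apart are independent.
#'
#' @param m Dimension.
#' @param dependence `"FD"` or `"PD"`.
#' @param seed Integer seed fixing the draw (default 101).
#' @return Numeric vector of length m.
#' @export
ma_coefficients <- function(m, dependence = c("FD", "PD"), seed = 101L) {
  dependence <- match.arg(dependence)
  set.seed(as.integer(seed))
  rho <- stats::runif(m, 2, 3)
  if (dependence == "PD" && m > 3L) rho[4:m] <- 0
  rho
}

# innovation variances: the first m/2 innovations are centred Gamma(4, 1)
# (variance 4), the remaining ones standard normal (variance 1); a subject's
# innovation vector has length 2m - 1 because the MA window slides across it
ma_innovation_var <- function(m) {
  n_gamma <- m %/% 2L
  c(rep(4, n_gamma), rep(1, 2L * m - 1L - n_gamma))
}

# weight matrix R with R[j, k] = rho[j - k + 1]: X = Z %*% R for an
# innovation row vector Z of length 2m - 1
ma_weight_matrix <- function(rho) {
  m <- length(rho)
  R <- matrix(0, 2L * m - 1L, m)
  for (k in seq_len(m)) R[k:(k + m - 1L), k] <- rho
  R
}

#' Analytic covariance of the moving-average model
#'
#' The MA process \eqn{X_k = \sum_l \rho_l Z_{k+l-1} + \mu_k} with
#' independent innovations gives
#' \eqn{\sigma_{k_1,k_2} = \sum_j \rho_{j-k_1+1}\,\rho_{j-k_2+1}\,
#' \mathrm{Var}(Z_j)}, summing over the innovation indices covered by both
#' windows. Needed to evaluate the eta calibration under the MA model.
#'
#' @param rho Coefficient vector (see [ma_coefficients()]).
#' @param innovation_var Optional vector of innovation variances of length
#'   `2 * m - 1`; defaults to the mixed Gamma/normal profile (4 for the
#'   first `m/2` innovations, 1 for the rest).
#' @return An m x m covariance matrix.
#' @export
ma_covariance <- function(rho, innovation_var = NULL) {
  m <- length(rho)
  v <- if (is.null(innovation_var)) ma_innovation_var(m) else innovation_var
  stopifnot(length(v) == 2L * m - 1L)
  R <- ma_weight_matrix(rho)
  crossprod(R, R * v)
}

#' Moving-average two-sample generator
#'
#' Each subject gets an independent innovation vector \eqn{Z} of length
#' `2m - 1`: the first `m/2` entries are centred Gamma(4, 1) (mean 0,
#' variance 4), the rest standard normal. The observed vector is
#' \eqn{X_k = \sum_l \rho_l Z_{k+l-1} + \mu_{ik}}; both groups share the
#' same coefficients, group 2 is centred at zero.
#'
#' @inheritParams simulate_mvn
#' @param rho Coefficient vector (see [ma_coefficients()]); its length sets
#'   the dimension and must equal `length(mu1)`.
#' @return A [two_sample_matrix()].
#' @export
simulate_ma <- function(n1, n2, mu1, rho, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- length(rho)
  stopifnot(length(mu1) == m)
  R <- ma_weight_matrix(rho)
  n_gamma <- m %/% 2L
  n_norm <- 2L * m - 1L - n_gamma
  draw <- function(nn, mu) {
    Z <- cbind(
      matrix(stats::rgamma(nn * n_gamma, shape = 4, rate = 1) - 4,
             nn, n_gamma),
      matrix(stats::rnorm(nn * n_norm), nn, n_norm)
    )
    sweep(Z %*% R, 2L, mu, "+")
  }
  X1 <- draw(n1, mu1)
  X2 <- draw(n2, rep(0, m))
  two_sample_matrix(X1, X2)
}
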