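# Simulation-study orchestration: type-I-error and power experiments over a
# grid of (model, n, m, covariance structure, sparsity, signal strength,
# allocation), with replicate-level seeding so results are reproducible
# regardless of execution order.

STUDY_MODELS <- c("mvn", "mvt", "ma")

#' Simulation study configuration
#'
#' Describes one cell of a type-I-error or power experiment. `gamma = NULL`
#' or `eta = 0` selects the null configuration (`mu1 = mu2 = 0`); otherwise
#' the group-1 mean has `floor(m^gamma)` nonzero entries calibrated so the
#' signal strength functional equals `eta` (see [allocate_means()]).
#'
#' @param model `"mvn"`, `"mvt"` (4 df) or `"ma"`.
#' @param n Per-group sample size (`n1 = n2 = n`).
#' @param m Dimension.
#' @param structure `"DS1"`, `"DS2"`, `"DS3"` or `"identity"` for
#'   `mvn`/`mvt`; `"FD"` or `"PD"` for `ma`.
#' @param gamma Sparsity exponent, or `NULL` for the null configuration.
#' @param eta Signal strength (0 for the null configuration).
#' @param allocation `"equal"` or `"linear"` nonzero mean entries.
#' @param reps Monte-Carlo replicates.
#' @param B Permutations per replicate for the AGCP test.
#' @param alpha Nominal level.
#' @param seed Master seed; replicate r uses a stream derived from
#'   `(seed, r)`.
#' @param tests Character subset of `c("agcp", "cq")`.
#' @param method Marginal test for AGCP (see [marginal_pvalues()]).
#' @param mvt_df Degrees of freedom for the `mvt` model.
#' @param sigma_is `"scale"` (default) or `"covariance"` interpretation of
#'   the matrix parameter under `mvt` (see [simulate_mvt()]).
#' @param ma_seed Seed freezing the MA coefficients across replicates.
#' @return A validated `"study_config"` list.
#' @export
study_config <- function(model = c("mvn", "mvt", "ma"), n, m,
                         structure = "DS1", gamma = NULL, eta = 0,
                         allocation = "equal", reps = 1000L, B = 10000L,
                         alpha = 0.05, seed = 1L, tests = c("agcp", "cq"),
                         method = "auto", mvt_df = 4,
                         sigma_is = "scale", ma_seed = 101L) {
  model <- match.arg(model)
  allowed <- if (model == "ma") c("FD", "PD")
             else c("DS1", "DS2", "DS3", "identity")
  if (!structure %in% allowed) {
    stop("structure '", structure, "' is not valid for model '", model,
         "' (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  tests <- match.arg(tests, several.ok = TRUE)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  cfg <- list(model = model, n = as.integer(n), m = as.integer(m),
              structure = structure, gamma = gamma, eta = eta,
              allocation = allocation, reps = as.integer(reps),
              B = as.integer(B), alpha = alpha, seed = as.integer(seed),
              tests = tests, method = method, mvt_df = mvt_df,
              sigma_is = sigma_is, ma_seed = as.integer(ma_seed))
  class(cfg) <- "study_config"
  cfg
}

# deterministic replicate-level seed below 2^31, keyed by (master, r)
replicate_seed <- function(master, r) {
  as.integer((as.numeric(master) %% 65011 * 33013 +
              as.numeric(r) * 69621) %% 2147483587 + 1)
}

# resolve the fixed (per-study) ingredients: covariances, mean vector, and a
# data-generating closure
study_generator <- function(cfg) {
  m <- cfg$m
  null_mode <- is.null(cfg$gamma) || cfg$eta == 0
  if (cfg$model == "ma") {
    rho <- ma_coefficients(m, cfg$structure, seed = cfg$ma_seed)
    Sigma <- ma_covariance(rho)
    mu1 <- if (null_mode) numeric(m) else {
      allocate_means(m, cfg$gamma, cfg$eta, cfg$allocation, Sigma, Sigma)
    }
    gen <- function() simulate_ma(cfg$n, cfg$n, mu1, rho)
  } else {
    Sigma1 <- build_covariance(cfg$structure, m)
    Sigma2 <- diag(m)
    mu1 <- if (null_mode) numeric(m) else {
      allocate_means(m, cfg$gamma, cfg$eta, cfg$allocation, Sigma1, Sigma2)
    }
    gen <- if (cfg$model == "mvn") {
      function() simulate_mvn(cfg$n, cfg$n, mu1, Sigma1)
    } else {
      function() simulate_mvt(cfg$n, cfg$n, mu1, Sigma1, df = cfg$mvt_df,
                              sigma_is = cfg$sigma_is)
    }
  }
  list(gen = gen, mu1 = mu1, null_mode = null_mode)
}

#' Run a simulation study cell
#'
#' Generates `reps` independent datasets under the configured model, applies
#' each registered test, and tabulates rejection rates at the nominal level
#' (rejecting when the p-value is less than or equal to `alpha`, since the
#' permutation p-values live on a lattice that includes 0). Replicate r
#' reseeds the RNG from `(seed, r)`, so the result is independent of
#' execution order; a failing replicate is recorded and excluded with a
#' warning.
#'
#' @param config A [study_config()].
#' @return A data frame with one row per test: the configuration fields,
#'   `rejections`, `reps_completed`, `rate` and the binomial Monte-Carlo
#'   standard error `se`.
#' @examples
#' cfg <- study_config("mvn", n = 5, m = 10, structure = "identity",
#'                     reps = 3, B = 50, tests = "agcp", seed = 1)
#' run_study(cfg)
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  st <- study_generator(config)
  tests <- config$tests
  rej <- stats::setNames(integer(length(tests)), tests)
  done <- stats::setNames(integer(length(tests)), tests)
  for (r in seq_len(config$reps)) {
    set.seed(replicate_seed(config$seed, r))
    dat <- st$gen()
    for (tname in tests) {
      res <- tryCatch({
        if (tname == "agcp") {
          out <- agcp_test(dat, method = config$method, B = config$B)
          out$p.value <= config$alpha
        } else {
          cq_test(dat, alpha = config$alpha)$reject
        }
      }, error = function(e) {
        warning("replicate ", r, " failed for test '", tname, "': ",
                conditionMessage(e), call. = FALSE)
        NA
      })
      if (!is.na(res)) {
        done[tname] <- done[tname] + 1L
        rej[tname] <- rej[tname] + as.integer(res)
      }
    }
  }
  rate <- ifelse(done > 0, rej / done, NA_real_)
  data.frame(
    model = config$model, n = config$n, m = config$m,
    structure = config$structure,
    gamma = ifelse(is.null(config$gamma), NA_real_, config$gamma),
    eta = config$eta, allocation = config$allocation,
    B = config$B, alpha = config$alpha, seed = config$seed,
    test = tests,
    rejections = as.integer(rej), reps_completed = as.integer(done),
    rate = rate, se = sqrt(rate * (1 - rate) / pmax(done, 1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Read study configurations from a YAML or JSON file
#'
#' The file holds either a single configuration mapping or a list of them
#' under the top-level key `studies`. Keys mirror the arguments of
#' [study_config()]; unknown keys raise an error naming the offenders.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of [study_config()] objects.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- if (!is.null(raw$studies)) raw$studies else list(raw)
  known <- names(formals(study_config))
  lapply(entries, function(e) {
    # YAML 1.1 reads the bare key `n` as a boolean; map it back
    names(e)[names(e) == "FALSE"] <- "n"
    bad <- setdiff(names(e), known)
    if (length(bad) > 0) {
      stop("unknown config keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    do.call(study_config, e)
  })
}
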