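# File-format surface: reading delimited expression matrices and group
# labels, running the test on them, and writing reports and study tables.
# Orientation of microarray exports varies, so the reader takes an explicit
# flag; missing values fail loudly unless dropping is requested.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited numeric expression matrix
#'
#' Expects a header row and an ID first column. Non-numeric data cells and
#' (by default) missing values produce structured errors naming the
#' offending rows/columns.
#'
#' @param path TSV (default) or CSV file.
#' @param orientation `"samples"` if rows are samples (default), or
#'   `"variables"` if rows are variables/genes, in which case the matrix is
#'   transposed on read.
#' @param na_action `"fail"` (default) or `"drop"` (drop variables with any
#'   missing value).
#' @return A numeric matrix, samples in rows, with dimnames.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples", "variables"),
                                   na_action = c("fail", "drop")) {
  orientation <- match.arg(orientation)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                          row.names = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  non_num <- !vapply(df, is.numeric, logical(1))
  if (any(non_num)) {
    stop("non-numeric cells in column(s): ",
         paste(utils::head(names(df)[non_num], 5), collapse = ", "),
         call. = FALSE)
  }
  M <- as.matrix(df)
  if (orientation == "variables") M <- t(M)
  if (anyNA(M)) {
    if (na_action == "fail") {
      bad <- which(apply(M, 2L, anyNA))
      stop("missing values in variable(s): ",
           paste(utils::head(colnames(M)[bad], 5), collapse = ", "),
           "; use na_action = 'drop' to discard them", call. = FALSE)
    }
    M <- M[, !apply(M, 2L, anyNA), drop = FALSE]
  }
  M
}

#' Read a two-column sample-to-group label file
#'
#' First column sample ID, second column group label, with a header row.
#' Exactly two distinct groups with at least two samples each are required
#' downstream; this reader only parses.
#'
#' @param path TSV or CSV file.
#' @return A named character vector: `names` are sample IDs, values groups.
#' @export
read_group_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("label file needs two columns: sample ID and group", call. = FALSE)
  }
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

# align a labelled matrix into a two_sample_matrix; group order follows the
# sorted unique labels
split_by_labels <- function(M, labels) {
  missing_ids <- setdiff(rownames(M), names(labels))
  if (length(missing_ids) > 0) {
    stop("sample(s) without a group label: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  lab <- labels[rownames(M)]
  groups <- sort(unique(lab))
  if (length(groups) != 2L) {
    stop("need exactly 2 distinct groups, found ", length(groups), ": ",
         paste(utils::head(groups, 5), collapse = ", "), call. = FALSE)
  }
  sizes <- table(lab)
  if (any(sizes < 2L)) {
    stop("each group needs at least 2 samples (got ",
         paste(sizes, collapse = " and "), ")", call. = FALSE)
  }
  two_sample_matrix(M[lab == groups[1L], , drop = FALSE],
                    M[lab == groups[2L], , drop = FALSE])
}

#' Run the AGCP test on delimited files
#'
#' Reads an expression matrix and a group-label file, runs [agcp_test()],
#' and optionally writes a JSON report plus a TSV of marginal p-values.
#'
#' @param matrix_path,labels_path Input files (see
#'   [read_expression_matrix()], [read_group_labels()]).
#' @param thresholds,B,method,seed Passed to [agcp_test()].
#' @param orientation,na_action Passed to [read_expression_matrix()].
#' @param out Optional output path prefix: writes `<out>.json` (global
#'   p-value, observed statistic, argmax threshold pair, per-pair GCPs) and
#'   `<out>_marginal.tsv` (per-variable p-values).
#' @return The `"agcp_test"` object, invisibly when `out` is given.
#' @export
agcp_test_files <- function(matrix_path, labels_path,
                            thresholds = default_thresholds(), B = 10000L,
                            method = "auto", seed = NULL,
                            orientation = "samples", na_action = "fail",
                            out = NULL) {
  M <- read_expression_matrix(matrix_path, orientation, na_action)
  labels <- read_group_labels(labels_path)
  data <- split_by_labels(M, labels)
  res <- agcp_test(data, thresholds = thresholds, method = method, B = B,
                   seed = seed)
  if (!is.null(out)) {
    report <- list(
      statistic = res$statistic,
      p_value = res$p.value,
      argmax_pair = res$argmax_pair,
      B = res$B,
      method = res$method,
      thresholds = res$thresholds,
      gcp_by_pair = as.list(res$gcp_by_pair),
      n1 = data$n1, n2 = data$n2, m = data$m,
      marginal_p_range = range(res$marginal_p)
    )
    jsonlite::write_json(report, paste0(out, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    utils::write.table(
      data.frame(variable = colnames(M), p = res$marginal_p),
      paste0(out, "_marginal.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    return(invisible(res))
  }
  res
}

#' Write the packaged synthetic demonstration dataset
#'
#' Generates a small two-group expression-style fixture: `2 * n_per_group`
#' samples by `m` standard-normal variables, with the first `n_shift`
#' variables shifted by `delta` in group 2. Written as `matrix.tsv` and
#' `labels.tsv` under `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param n_per_group,m,n_shift,delta Shape and signal of the fixture.
#' @param seed Integer seed.
#' @return Named character vector with the two file paths.
#' @export
write_demo_fixture <- function(dir, n_per_group = 10L, m = 30L,
                               n_shift = 5L, delta = 2, seed = 2024L) {
  if (n_shift > m) stop("n_shift cannot exceed m", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  n <- 2L * n_per_group
  M <- matrix(stats::rnorm(n * m), n, m)
  if (n_shift > 0) {
    M[(n_per_group + 1L):n, seq_len(n_shift)] <-
      M[(n_per_group + 1L):n, seq_len(n_shift)] + delta
  }
  rownames(M) <- sprintf("sample%02d", seq_len(n))
  colnames(M) <- sprintf("gene%03d", seq_len(m))
  mat_path <- file.path(dir, "matrix.tsv")
  lab_path <- file.path(dir, "labels.tsv")
  utils::write.table(data.frame(sample = rownames(M), M,
                                check.names = FALSE),
                     mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = rownames(M),
               group = rep(c("A", "B"), each = n_per_group)),
    lab_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  c(matrix = mat_path, labels = lab_path)
}

#' Run configured studies and write tidy result tables
#'
#' Reads one or more [study_config()]s from a YAML/JSON file, runs each, and
#' writes a single tidy TSV (one row per configuration x test) under
#' `out_dir`. Numbers are written at full precision so a write/read
#' round-trip is exact.
#'
#' @param config_path YAML or JSON configuration file (see
#'   [read_study_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The combined results data frame, invisibly.
#' @export
run_study_file <- function(config_path, out_dir) {
  cfgs <- read_study_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- do.call(rbind, lapply(cfgs, run_study))
  out <- file.path(out_dir, "study_results.tsv")
  write_result_table(results, out)
  invisible(results)
}

# full-precision TSV so round-trips preserve every value
write_result_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) format(x, digits = 17,
                                                 scientific = TRUE,
                                                 trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
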