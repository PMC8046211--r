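#' Clustered positive-response data
#'
#' Container for observations grouped in `m` clusters, each row carrying a
#' positive response `y` (to be modelled on the log scale), a numeric
#' fixed-effects design row, and a known positive heteroscedasticity weight
#' `w` (the error variance of an observation is `sigma^2 / w`).
#'
#' Cluster labels are kept as given (opaque strings); internally clusters are
#' indexed 1..m in order of first appearance, so results do not depend on the
#' lexicographic order of the labels.
#'
#' @param cluster vector of cluster labels, one per observation.
#' @param y positive numeric response on the original scale.
#' @param X numeric design matrix (n x p); include an all-ones column if an
#'   intercept is wanted. A plain vector is treated as a single column.
#' @param w optional known positive weights; defaults to 1 for every row.
#'
#' @return An object of class `clustered_data`: a list with elements
#'   `cluster` (labels as character), `cluster_index` (integer 1..m in
#'   first-appearance order), `levels` (the m labels), `y`, `X`, `w`,
#'   `n`, `m`, and `n_i` (named cluster sizes).
#' @export
clustered_data <- function(cluster, y, X, w = NULL) {
  if (is.null(dim(X))) X <- matrix(as.numeric(X), ncol = 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (n == 0L) validation_error("no observations")
  if (length(cluster) != n || nrow(X) != n) {
    validation_error("cluster, y and X must have one entry per observation")
  }
  if (is.null(w)) w <- rep(1, n)
  if (length(w) == 1L) w <- rep(w, n)
  if (length(w) != n) validation_error("weights must have one entry per observation")
  cluster <- as.character(cluster)
  y <- as.numeric(y)
  w <- as.numeric(w)
  if (anyNA(cluster)) validation_error("missing cluster label")
  bad <- which(!is.finite(y) | y <= 0)
  if (length(bad)) {
    validation_error(sprintf("response must be positive and finite (log undefined): first offending row %d (y = %s)",
                             bad[1], format(y[bad[1]])))
  }
  bad <- which(!is.finite(w) | w <= 0)
  if (length(bad)) {
    validation_error(sprintf("weights must be positive and finite: first offending row %d (w = %s)",
                             bad[1], format(w[bad[1]])))
  }
  if (anyNA(X) || any(!is.finite(X))) {
    validation_error("design matrix contains missing or non-finite entries")
  }
  levels <- unique(cluster)
  idx <- match(cluster, levels)
  n_i <- tabulate(idx, nbins = length(levels))
  names(n_i) <- levels
  structure(
    list(cluster = cluster, cluster_index = idx, levels = levels,
         y = y, X = X, w = w, n = n, m = length(levels), n_i = n_i),
    class = "clustered_data"
  )
}

#' @export
print.clustered_data <- function(x, ...) {
  cat(sprintf("clustered_data: %d observations in %d clusters, %d design column(s)\n",
              x$n, x$m, ncol(x$X)))
  cat(sprintf("  cluster sizes: min %d, max %d; weights: min %.4g, max %.4g\n",
              min(x$n_i), max(x$n_i), min(x$w), max(x$w)))
  invisible(x)
}

#' Read clustered data from a delimited text file
#'
#' Reads a comma-delimited file with a mandatory header row (decimal point,
#' no imputation: any empty cell is an error) into a [clustered_data] object.
#'
#' @param path path to a CSV file.
#' @param cluster,response,weight column names holding the cluster label, the
#'   positive response, and (optionally) the known variance weight. When
#'   `weight` is `NULL`, all weights default to 1.
#' @param covariates character vector of design-column names, in order. When
#'   `NULL`, every column other than the cluster/response/weight columns is
#'   used, in file order.
#' @return A [clustered_data] object; row order is preserved.
#' @export
read_clustered <- function(path, cluster = "cluster", response = "y",
                           covariates = NULL, weight = NULL) {
  if (!file.exists(path)) config_error(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = NA,
                    stringsAsFactors = FALSE),
    error = function(e) validation_error(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0L) validation_error(sprintf("empty file: %s", path))
  need <- c(cluster, response, covariates, weight)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    config_error(sprintf("column(s) not found in %s: %s", path,
                         paste(missing_cols, collapse = ", ")))
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(df), c(cluster, response, weight))
  }
  if (length(covariates) == 0L) config_error("no covariate columns mapped")
  num_cols <- c(response, covariates, weight)
  for (cn in num_cols) {
    v <- df[[cn]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) {
      validation_error(sprintf("column '%s' has a missing or non-numeric value at row %d",
                               cn, which(is.na(v))[1]))
    }
    df[[cn]] <- v
  }
  X <- as.matrix(df[, covariates, drop = FALSE])
  clustered_data(cluster = df[[cluster]], y = df[[response]], X = X,
                 w = if (is.null(weight)) NULL else df[[weight]])
}

#' Write data with original-scale prediction columns
#'
#' Writes the observations back to CSV (columns `cluster`, `y`, the design
#' columns, `weight`) plus one `pred_<method>` column per supplied
#' prediction, in the canonical method order of [correction_methods()].
#' Numbers are printed with 17 significant digits so that a write/read
#' round trip reproduces the values exactly.
#'
#' @param data a [clustered_data] object.
#' @param preds a single prediction object from [predict_rim()], a named list
#'   of them (names = method labels), or `NULL`/empty list to echo the data.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(data, preds, path) {
  stopifnot(inherits(data, "clustered_data"))
  if (inherits(preds, "rim_prediction")) {
    preds <- stats::setNames(list(preds), attr(preds, "method"))
  }
  if (is.null(preds)) preds <- list()
  for (p in preds) {
    if (nrow(p) != data$n) {
      validation_error("predictions are not aligned with the data rows")
    }
  }
  ord <- intersect(correction_methods(), names(preds))
  extra <- setdiff(names(preds), correction_methods())
  ord <- c(ord, extra)
  fmt <- function(v) sprintf("%.17g", v)
  out <- data.frame(cluster = data$cluster, y = fmt(data$y),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(data$X))) out[[colnames(data$X)[j]]] <- fmt(data$X[, j])
  out[["weight"]] <- fmt(data$w)
  for (mth in ord) out[[paste0("pred_", mth)]] <- fmt(preds[[mth]]$pred)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
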