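#' Canonical correction-method labels
#'
#' The six original-scale prediction estimators for a log-scale
#' random-intercept model, in canonical order:
#' \describe{
#'   \item{`naive`}{`exp(x'beta + gamma_i)` — the exponentiated fitted
#'     value, which underestimates `E[Y]` by Jensen's inequality.}
#'   \item{`marginal`}{`exp(x'beta) exp(sigma_gamma^2/2) exp(sigma^2/(2w))`
#'     — marginal expectation, no BLUP.}
#'   \item{`error_only`}{naive times the error factor `exp(sigma^2/(2w))`.}
#'   \item{`conditional`}{naive times `exp(v_i/2)` times the error factor,
#'     with `v_i = Var(gamma_i | log Y)` from [conditional_variance()].}
#'   \item{`smearing_global`}{naive times `exp(v_i/2)` times the global
#'     smearing factor `mean(exp(residuals))` over all n observations.}
#'   \item{`smearing_cluster`}{naive times `exp(v_i/2)` times the
#'     within-cluster smearing factor `mean(exp(residuals_i))`.}
#' }
#'
#' @return Character vector of the six labels.
#' @export
correction_methods <- function() {
  c("naive", "marginal", "error_only", "conditional",
    "smearing_global", "smearing_cluster")
}

#' Log-normal correction for ordinary (weighted) regression
#'
#' For a regression of `log(y)` on `X` with homoscedastic errors
#' `N(0, sigma^2)` — or heteroscedastic `N(0, sigma^2/w)` with known
#' weights — the original-scale conditional mean is
#' `exp(x'beta) exp(sigma^2 / (2 w))`.
#'
#' @param X0 design rows for the points to predict (matrix or vector).
#' @param beta fitted coefficients.
#' @param sigma2 estimated error variance (>= 0).
#' @param w optional positive weights (recycled); 1 when absent.
#' @return Vector of original-scale predictions.
#' @export
ols_log_correction <- function(X0, beta, sigma2, w = NULL) {
  if (is.null(dim(X0))) X0 <- matrix(X0, ncol = length(beta))
  if (sigma2 < 0) validation_error("sigma2 must be non-negative")
  if (is.null(w)) w <- 1
  if (any(w <= 0)) validation_error("weights must be positive")
  as.numeric(exp(X0 %*% beta) * exp(0.5 * sigma2 / w))
}

#' Duan's smearing estimator for ordinary regression
#'
#' Nonparametric retransformation: `exp(x0'beta) * mean(exp(residuals))`,
#' using the empirical distribution of the log-scale residuals instead of a
#' normality assumption.
#'
#' @param X0 design rows for the points to predict.
#' @param beta fitted coefficients.
#' @param residuals log-scale residuals from the same fit.
#' @return Vector of original-scale predictions.
#' @export
duan_smearing <- function(X0, beta, residuals) {
  if (length(residuals) == 0L) validation_error("empty residual vector")
  if (is.null(dim(X0))) X0 <- matrix(X0, ncol = length(beta))
  as.numeric(exp(X0 %*% beta)) * mean(exp(residuals))
}

#' Conditional variance of a random intercept given the sample
#'
#' `v_i = Var(gamma_i | log Y) = sigma_gamma^2 * (1 - sigma_gamma^2 /
#' (sigma_gamma^2 + sigma^2 / sum_j w_ij))`, equivalently the precision form
#' `1 / (1/sigma_gamma^2 + sum_w/sigma^2)`. Decreasing in `sum_w`, bounded
#' by `[0, sigma_gamma^2]`.
#'
#' @param sigma_gamma2 random-intercept variance (>= 0).
#' @param sigma2 error variance (> 0).
#' @param sum_w per-cluster sum of weights (vectorized).
#' @return `v_i`, one value per element of `sum_w`.
#' @export
conditional_variance <- function(sigma_gamma2, sigma2, sum_w) {
  if (sigma_gamma2 < 0 || sigma2 < 0) {
    validation_error("need sigma_gamma2 >= 0 and sigma2 >= 0")
  }
  if (sigma_gamma2 == 0) return(rep(0, length(sum_w)))
  sigma_gamma2 * (1 - sigma_gamma2 / (sigma_gamma2 + sigma2 / sum_w))
}

#' Original-scale predictions from a fitted random-intercept model
#'
#' Applies one of the six correction methods (see [correction_methods()])
#' to a [fit_rim()] fit. Every prediction decomposes exactly as
#' `exp(eta) * re_factor * err_factor`, where `eta` is the log-scale linear
#' predictor (including the BLUP except for `marginal`), `re_factor` the
#' random-effect correction and `err_factor` the error correction; the three
#' parts are returned alongside the prediction.
#'
#' For clusters unseen at fit time the BLUP is 0 and the conditional
#' variance reverts to the prior `sigma_gamma^2` (new-cluster mode, with a
#' message); smearing factors always come from the training residuals, the
#' cluster variant falling back to the global factor for a new cluster.
#'
#' @param fit a `rim_fit` object.
#' @param data data to predict for (a [clustered_data] object); defaults to
#'   the training data.
#' @param method one of [correction_methods()].
#' @return A data frame of class `rim_prediction` with columns `cluster`,
#'   `eta`, `re_factor`, `err_factor`, `pred`, and attribute `method`.
#' @export
predict_rim <- function(fit, data = NULL, method = "conditional") {
  stopifnot(inherits(fit, "rim_fit"))
  if (is.null(data)) data <- fit$data
  stopifnot(inherits(data, "clustered_data"))
  if (!identical(ncol(data$X), ncol(fit$data$X))) {
    validation_error("prediction design has a different number of columns than at fit time")
  }
  if (length(method) != 1L || !(method %in% correction_methods())) {
    config_error(sprintf("unknown correction method '%s' (choose from: %s)",
                         paste(method, collapse = ","),
                         paste(correction_methods(), collapse = ", ")))
  }
  s2 <- fit$sigma2
  g2 <- fit$sigma_gamma2
  pos <- match(data$cluster, names(fit$gamma))
  new_cluster <- is.na(pos)
  if (any(new_cluster)) {
    message(sprintf("%d observation(s) belong to clusters unseen at fit time; using gamma = 0 with prior variance",
                    sum(new_cluster)))
  }
  gam <- ifelse(new_cluster, 0, fit$gamma[pos])
  v <- ifelse(new_cluster, g2, conditional_variance(g2, s2, fit$sum_w)[pos])
  xb <- as.numeric(data$X %*% fit$beta)
  err <- exp(0.5 * s2 / data$w)
  eta <- xb + gam
  re <- rep(1, data$n)
  if (method == "naive") {
    err <- rep(1, data$n)
  } else if (method == "marginal") {
    eta <- xb
    re <- rep(exp(0.5 * g2), data$n)
  } else if (method == "error_only") {
    # re factor stays 1
  } else if (method == "conditional") {
    re <- exp(0.5 * v)
  } else if (method == "smearing_global") {
    re <- exp(0.5 * v)
    err <- rep(mean(exp(fit$residuals)), data$n)
  } else if (method == "smearing_cluster") {
    re <- exp(0.5 * v)
    sm_global <- mean(exp(fit$residuals))
    sm <- rowsum(exp(fit$residuals), fit$data$cluster_index)[, 1] /
      as.numeric(fit$data$n_i)
    err <- ifelse(new_cluster, sm_global, sm[pos])
  }
  out <- data.frame(cluster = data$cluster, eta = eta, re_factor = re,
                    err_factor = err, pred = exp(eta) * re * err,
                    stringsAsFactors = FALSE)
  structure(out, method = method, class = c("rim_prediction", "data.frame"))
}

#' @export
#' @rdname predict_rim
#' @param object,... S3 method arguments (`predict(fit, ...)` forwards to
#'   `predict_rim`).
predict.rim_fit <- function(object, data = NULL, method = "conditional", ...) {
  predict_rim(object, data = data, method = method)
}

#' All-methods convenience wrapper
#'
#' @param fit a `rim_fit` object.
#' @param data data to predict for; defaults to the training data.
#' @param methods subset of [correction_methods()].
#' @return Named list of `rim_prediction` objects, in canonical order.
#' @export
predict_rim_all <- function(fit, data = NULL, methods = correction_methods()) {
  methods <- intersect(correction_methods(), methods)
  stats::setNames(lapply(methods, function(mm) predict_rim(fit, data, mm)), methods)
}
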