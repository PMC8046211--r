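#' Fit a heteroscedastic random-intercept model on the log scale
#'
#' Fits `log(y_ij) = x_ij' beta + gamma_i + eps_ij` with
#' `gamma_i ~ N(0, sigma_gamma^2)` i.i.d. and independent errors
#' `eps_ij ~ N(0, sigma^2 / w_ij)`, the weights `w_ij > 0` being known
#' constants. Estimation maximizes the Gaussian (restricted) log-likelihood
#' of `log(y) ~ N(X beta, V)` with block-diagonal
#' `V_i = sigma_gamma^2 11' + sigma^2 diag(1/w_i)` over
#' `(log sigma^2, log sigma_gamma^2)`; `beta` is profiled out as the GLS
#' solution at each candidate, and all per-cluster algebra uses the
#' rank-one Woodbury identity, so the cost is linear in n.
#'
#' @param data a [clustered_data] object; the design must have full column
#'   rank.
#' @param method `"REML"` (default) or `"ML"`.
#' @param tol convergence tolerance passed to the optimizer (on the
#'   deviance scale).
#' @param maxit maximum optimizer iterations.
#' @param var_floor lower floor for both variance components; an estimate at
#'   the floor is flagged as a boundary solution.
#'
#' @return An object of class `rim_fit`: list with `beta` (named length-p),
#'   `sigma2`, `sigma_gamma2`, `gamma` (named length-m BLUPs),
#'   `residuals` (log-scale, `log y - X beta - gamma_cluster`),
#'   `fitted_log`, `loglik`, `method`, `convergence` (list with `status`
#'   one of `"converged"`, `"boundary"`, and optimizer details),
#'   per-cluster weight sums `sum_w`, and the training `data`.
#' @seealso [predict_rim()], [blup_rim()], [lrt_random_effect()]
#' @export
fit_rim <- function(data, method = c("REML", "ML"), tol = 1e-9,
                    maxit = 500L, var_floor = 1e-10) {
  stopifnot(inherits(data, "clustered_data"))
  method <- match.arg(method)
  if (tol <= 0) config_error("tolerance must be positive")
  if (var_floor < 0) config_error("variance floor must be non-negative")
  X <- data$X
  p <- ncol(X)
  if (qr(X)$rank < p) model_error("design matrix is rank deficient")
  z <- log(data$y)
  idx <- data$cluster_index
  w <- data$w
  n <- data$n
  m <- data$m

  prof <- function(ls2, lg2) rim_profile(exp(ls2), exp(lg2), z, X, w, idx, n, m, p, method)
  nll <- function(par) {
    v <- prof(par[1], par[2])
    if (!is.finite(v$nll)) 1e10 else v$nll
  }

  # moment-style start: weighted OLS residual variance split between levels
  b0 <- stats::lm.wfit(X, z, w)$coefficients
  r0 <- z - X %*% b0
  cl_means <- rowsum(r0, idx)[, 1] / data$n_i
  g2_0 <- max(stats::var(cl_means), var_floor * 10)
  s2_0 <- max(sum(w * (r0 - cl_means[idx])^2) / n, var_floor * 10)
  start <- c(log(s2_0), log(g2_0))
  lo <- log(max(var_floor, 1e-300))

  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(lo, lo), upper = c(30, 30),
                      control = list(maxit = maxit, factr = tol / .Machine$double.eps))
  # fallback restart: coarse grid + Nelder-Mead, keep the better optimum
  if (opt$convergence != 0 || !is.finite(opt$value)) {
    grid <- as.matrix(expand.grid(ls2 = log(s2_0) + seq(-4, 4, by = 2),
                                  lg2 = log(g2_0) + seq(-6, 4, by = 2)))
    vals <- apply(grid, 1, nll)
    opt2 <- stats::optim(grid[which.min(vals), ], nll, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = tol))
    opt2$par <- pmax(opt2$par, lo)
    if (is.finite(opt2$value) && (!is.finite(opt$value) || opt2$value < opt$value)) opt <- opt2
    if (!is.finite(opt$value)) {
      convergence_error("random-intercept fit failed to converge",
                        last_par = exp(opt$par), optim_status = opt$convergence)
    }
  }

  s2 <- max(exp(opt$par[1]), var_floor)
  g2 <- max(exp(opt$par[2]), var_floor)
  sol <- rim_profile(s2, g2, z, X, w, idx, n, m, p, method)
  beta <- stats::setNames(sol$beta, colnames(X))
  gamma <- blup_gamma(z - X %*% beta, w, idx, m, s2, g2)
  names(gamma) <- data$levels
  res <- as.numeric(z - X %*% beta - gamma[idx])
  boundary <- (g2 <= var_floor * 1.000001) || (s2 <= var_floor * 1.000001)
  structure(
    list(beta = beta, sigma2 = s2, sigma_gamma2 = g2,
         gamma = gamma, residuals = res,
         fitted_log = as.numeric(X %*% beta + gamma[idx]),
         loglik = -sol$nll, method = method,
         convergence = list(status = if (boundary) "boundary" else "converged",
                            optim = opt$convergence, counts = opt$counts),
         sum_w = rowsum(w, idx)[, 1], var_floor = var_floor, data = data),
    class = "rim_fit"
  )
}

# Profiled negative log-likelihood and GLS beta at fixed (sigma2, sigma_gamma2).
# Woodbury per cluster: V_i^{-1} = W/s2 - (k_i/s2) w_i w_i', k_i = g2/(s2 + g2 a_i),
# a_i = sum_j w_ij;  log det V_i = sum_j log(s2/w_ij) + log1p(g2 a_i / s2).
rim_profile <- function(s2, g2, z, X, w, idx, n, m, p, method) {
  if (!is.finite(s2) || s2 <= 0) return(list(nll = Inf, beta = rep(NA_real_, p)))
  a <- rowsum(w, idx)[, 1]
  k <- g2 / (s2 + g2 * a)
  wX <- X * w
  swX <- rowsum(wX, idx)                       # m x p: X_i' w_i
  swz <- rowsum(w * z, idx)[, 1]               # m: w_i' z_i
  XtVX <- (crossprod(X, wX) - crossprod(swX * k, swX)) / s2
  XtVz <- (crossprod(wX, z) - crossprod(swX, k * swz)) / s2
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(list(nll = Inf, beta = rep(NA_real_, p)))
  beta <- backsolve(ch, forwardsolve(t(ch), XtVz))
  r <- as.numeric(z - X %*% beta)
  swr <- rowsum(w * r, idx)[, 1]
  quad <- (sum(w * r^2) - sum(k * swr^2)) / s2
  logdetV <- n * log(s2) - sum(log(w)) + sum(log1p(g2 * a / s2))
  nll <- 0.5 * (n * log(2 * pi) + logdetV + quad)
  if (method == "REML") {
    nll <- nll + 0.5 * (2 * sum(log(diag(ch))) - p * log(2 * pi))
  }
  list(nll = nll, beta = as.numeric(beta))
}

# Closed-form BLUP given residuals r = log y - X beta:
# gamma_i = g2 * sum_j(w_ij r_ij) / (g2 * sum_j w_ij + s2)
blup_gamma <- function(r, w, idx, m, s2, g2) {
  a <- rowsum(w, idx)[, 1]
  swr <- rowsum(as.numeric(r) * w, idx)[, 1]
  as.numeric(g2 * swr / (g2 * a + s2))
}

#' Best linear unbiased predictors of the random intercepts
#'
#' Computes `gamma_i = E[gamma_i | log Y]` for every cluster from a fitted
#' state (`beta`, `sigma2`, `sigma_gamma2`) and the data, via the shrinkage
#' closed form `sigma_gamma^2 * sum_j(w_ij r_ij) / (sigma_gamma^2 *
#' sum_j w_ij + sigma^2)` with `r_ij = log y_ij - x_ij' beta`. This equals
#' `sigma_gamma^2 1' V_i^{-1} (log y_i - X_i beta)` computed by dense
#' inversion.
#'
#' @param data a [clustered_data] object.
#' @param beta fixed-effects vector.
#' @param sigma2,sigma_gamma2 variance components (error, random intercept).
#' @return Named length-m vector of BLUPs, in first-appearance cluster order.
#' @export
blup_rim <- function(data, beta, sigma2, sigma_gamma2) {
  stopifnot(inherits(data, "clustered_data"))
  if (sigma_gamma2 == 0) {
    return(stats::setNames(numeric(data$m), data$levels))
  }
  r <- log(data$y) - data$X %*% beta
  g <- blup_gamma(r, data$w, data$cluster_index, data$m, sigma2, sigma_gamma2)
  stats::setNames(g, data$levels)
}

# ML fit of the no-random-effect weighted regression, and its log-likelihood.
wls_loglik_ml <- function(data) {
  z <- log(data$y)
  fit <- stats::lm.wfit(data$X, z, data$w)
  r <- z - data$X %*% fit$coefficients
  s2 <- sum(data$w * r^2) / data$n
  ll <- -0.5 * (data$n * log(2 * pi) + data$n * log(s2) - sum(log(data$w)) + data$n)
  list(loglik = ll, sigma2 = s2, beta = fit$coefficients)
}

#' Likelihood-ratio test for the random intercept
#'
#' Compares the ML fits of the random-intercept model and of the weighted
#' regression without random effect. Because the null value
#' `sigma_gamma^2 = 0` sits on the boundary of the parameter space, the
#' statistic's null distribution is the mixture `0.5 chi^2_0 + 0.5 chi^2_1`,
#' so the p-value is half the `chi^2_1` upper tail (and 0.5 at statistic 0).
#'
#' @param data a [clustered_data] object.
#' @param ... passed to [fit_rim()] (besides `method`, which is forced to ML
#'   on both sides so the likelihoods are comparable).
#' @return list with `statistic`, `p_value`, and the two log-likelihoods.
#' @export
lrt_random_effect <- function(data, ...) {
  fit1 <- fit_rim(data, method = "ML", ...)
  fit0 <- wls_loglik_ml(data)
  stat <- 2 * (fit1$loglik - fit0$loglik)
  if (stat < 0) {
    if (stat < -1e-6) {
      warning(sprintf("negative LRT statistic (%.3g) clipped to 0", stat))
    }
    stat <- 0
  }
  p <- if (stat == 0) 0.5 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p,
       loglik_rim = fit1$loglik, loglik_null = fit0$loglik)
}

#' @export
print.rim_fit <- function(x, ...) {
  cat(sprintf("Heteroscedastic random-intercept model (log scale), %s fit\n", x$method))
  cat(sprintf("  %d observations, %d clusters; status: %s\n",
              x$data$n, x$data$m, x$convergence$status))
  cat("  fixed effects:\n")
  print(round(x$beta, 6))
  cat(sprintf("  sigma^2 = %.6g   sigma_gamma^2 = %.6g   logLik = %.4f\n",
              x$sigma2, x$sigma_gamma2, x$loglik))
  invisible(x)
}

#' @export
logLik.rim_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 2, class = "logLik")
}

#' @export
coef.rim_fit <- function(object, ...) object$beta

#' Write / read a fitted-model artifact
#'
#' Plain-text key-value serialization of a [fit_rim()] result (fixed
#' effects, variance components, per-cluster BLUPs, fit metadata, and a
#' light checksum of the training data) — inspectable and diff-able.
#'
#' @param fit a `rim_fit` object.
#' @param path artifact path.
#' @return `path` invisibly (write); a list with the stored quantities (read).
#' @export
write_rim_artifact <- function(fit, path) {
  stopifnot(inherits(fit, "rim_fit"))
  num <- function(v) sprintf("%.17g", v)
  lines <- c(
    "format\trimcorrect-fit-1",
    paste0("method\t", fit$method),
    paste0("loglik\t", num(fit$loglik)),
    paste0("sigma2\t", num(fit$sigma2)),
    paste0("sigma_gamma2\t", num(fit$sigma_gamma2)),
    paste0("status\t", fit$convergence$status),
    paste0("n\t", fit$data$n),
    paste0("m\t", fit$data$m),
    paste0("data_checksum\t", num(sum(log(fit$data$y)) + sum(fit$data$w))),
    paste0("beta\t", names(fit$beta), "\t", num(fit$beta)),
    paste0("gamma\t", names(fit$gamma), "\t", num(fit$gamma)),
    paste0("sum_w\t", names(fit$sum_w), "\t", num(fit$sum_w))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rim_artifact
#' @param path artifact path.
#' @export
read_rim_artifact <- function(path) {
  if (!file.exists(path)) config_error(sprintf("artifact not found: %s", path))
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  key <- vapply(fields, `[`, "", 1)
  if (!identical(fields[[1]][2], "rimcorrect-fit-1")) {
    validation_error("not a rimcorrect fit artifact")
  }
  get1 <- function(k) fields[[which(key == k)[1]]][2]
  getv <- function(k) {
    rows <- fields[key == k]
    stats::setNames(as.numeric(vapply(rows, `[`, "", 3)),
                    vapply(rows, `[`, "", 2))
  }
  list(method = get1("method"), loglik = as.numeric(get1("loglik")),
       sigma2 = as.numeric(get1("sigma2")),
       sigma_gamma2 = as.numeric(get1("sigma_gamma2")),
       status = get1("status"), n = as.integer(get1("n")),
       m = as.integer(get1("m")), beta = getv("beta"),
       gamma = getv("gamma"), sum_w = getv("sum_w"))
}
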