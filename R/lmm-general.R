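#' Per-cluster components of a linear mixed model
#'
#' Bundles the quantities needed for original-scale correction in a general
#' LMM on the log scale: the random-effects design rows `U` (n x q, aligned
#' with the observations), the cluster labels, the q x q random-effects
#' covariance `D`, and the error covariance — diagonal `sigma2 / w` by
#' default, or explicit per-cluster matrices `Sigma`.
#'
#' @param U numeric matrix (n x q) of random-effects design rows (a vector is
#'   one column).
#' @param cluster cluster label per observation.
#' @param D q x q symmetric positive-semidefinite covariance of the random
#'   effects (a scalar for q = 1).
#' @param sigma2 error variance (used when `Sigma` is `NULL`).
#' @param w optional positive weights (error variance `sigma2 / w`); 1 when
#'   absent.
#' @param Sigma optional list of per-cluster error covariance matrices, in
#'   first-appearance cluster order; overrides `sigma2`/`w`.
#' @param gamma matrix (m x q) of BLUPs, one row per cluster, or `NULL` to
#'   compute them later with [blup_lmm()].
#' @return An object of class `lmm_components`.
#' @export
lmm_components <- function(U, cluster, D, sigma2 = NULL, w = NULL,
                           Sigma = NULL, gamma = NULL) {
  if (is.null(dim(U))) U <- matrix(as.numeric(U), ncol = 1L)
  U <- as.matrix(U)
  q <- ncol(U)
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D)))) validation_error("D must be symmetric")
  if (any(eigen(D, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
    validation_error("D must be positive semi-definite")
  }
  if (!all(dim(D) == q)) validation_error("D must be q x q with q = ncol(U)")
  cluster <- as.character(cluster)
  if (length(cluster) != nrow(U)) {
    validation_error("cluster must have one label per row of U")
  }
  levels <- unique(cluster)
  idx <- match(cluster, levels)
  n_i <- tabulate(idx, nbins = length(levels))
  if (is.null(Sigma)) {
    if (is.null(sigma2) || sigma2 < 0) {
      validation_error("sigma2 >= 0 is required when Sigma is not given")
    }
    if (is.null(w)) w <- rep(1, nrow(U))
    if (any(w <= 0)) validation_error("weights must be positive")
    Sigma <- lapply(seq_along(levels), function(i) {
      diag(sigma2 / w[idx == i], nrow = n_i[i])
    })
  } else {
    if (length(Sigma) != length(levels)) {
      validation_error("Sigma must have one matrix per cluster")
    }
    for (i in seq_along(Sigma)) {
      S <- as.matrix(Sigma[[i]])
      if (!all(dim(S) == n_i[i]) || !isTRUE(all.equal(S, t(S)))) {
        validation_error(sprintf("Sigma[[%d]] must be symmetric %d x %d", i, n_i[i], n_i[i]))
      }
      Sigma[[i]] <- S
    }
  }
  if (!is.null(gamma)) {
    gamma <- as.matrix(gamma)
    if (nrow(gamma) != length(levels) || ncol(gamma) != q) {
      validation_error("gamma must be m x q")
    }
    rownames(gamma) <- levels
  }
  structure(
    list(U = U, cluster = cluster, cluster_index = idx, levels = levels,
         n_i = stats::setNames(n_i, levels), q = q, D = D,
         sigma2 = sigma2, w = w, Sigma = Sigma, gamma = gamma),
    class = "lmm_components"
  )
}

#' Conditional covariance of a cluster's random effects given the sample
#'
#' `Var(gamma_i | log Y) = D - D U_i' (U_i D U_i' + Sigma_i)^{-1} U_i D`,
#' symmetric and positive semi-definite, and never larger than `D` in the
#' Loewner order. For q = 1 with an all-ones `U_i` and diagonal
#' `Sigma_i = sigma2/w` this reduces to the scalar
#' [conditional_variance()].
#'
#' @param components an [lmm_components] object.
#' @param i cluster index (1..m, first-appearance order) or label.
#' @return q x q matrix.
#' @export
conditional_cov_lmm <- function(components, i) {
  stopifnot(inherits(components, "lmm_components"))
  if (is.character(i)) i <- match(i, components$levels)
  if (is.na(i) || i < 1 || i > length(components$levels)) {
    validation_error("unknown cluster")
  }
  Ui <- components$U[components$cluster_index == i, , drop = FALSE]
  D <- components$D
  if (all(D == 0)) return(D)
  M <- Ui %*% D %*% t(Ui) + components$Sigma[[i]]
  sol <- tryCatch(solve(M, Ui %*% D),
                  error = function(e) model_error("singular marginal covariance in cluster"))
  V <- D - D %*% t(Ui) %*% sol
  (V + t(V)) / 2
}

#' Multivariate BLUPs for a general LMM
#'
#' `gamma_i = D U_i' (U_i D U_i' + Sigma_i)^{-1} (log y_i - X_i beta)`,
#' the best linear predictor of each cluster's random-effects vector.
#'
#' @param components an [lmm_components] object.
#' @param resid log-scale marginal residuals `log y - X beta`, aligned with
#'   the rows of `U`.
#' @return m x q matrix of BLUPs (rows = clusters).
#' @export
blup_lmm <- function(components, resid) {
  stopifnot(inherits(components, "lmm_components"))
  if (length(resid) != nrow(components$U)) {
    validation_error("residuals are not aligned with U")
  }
  D <- components$D
  out <- matrix(0, length(components$levels), components$q,
                dimnames = list(components$levels, NULL))
  if (all(D == 0)) return(out)
  for (i in seq_along(components$levels)) {
    sel <- components$cluster_index == i
    Ui <- components$U[sel, , drop = FALSE]
    M <- Ui %*% D %*% t(Ui) + components$Sigma[[i]]
    out[i, ] <- as.numeric(D %*% t(Ui) %*% solve(M, resid[sel]))
  }
  out
}

#' Corrected original-scale predictions for a general LMM
#'
#' For `log(Y_ij) = x_ij' beta + u_ij' gamma_i + eps_ij`, the corrected
#' predictor is `exp(x'beta + u'gamma_i) * exp(u' Var(gamma_i|log Y) u / 2)
#' * exp(sigma2 / (2 w))`. With q = 1 and an intercept-only `U` this equals
#' [predict_rim()] with the `conditional` method.
#'
#' @param beta fixed-effects vector.
#' @param components an [lmm_components] object (with `gamma` set, or
#'   computable via `resid`).
#' @param X fixed-effects design rows aligned with `components$U`.
#' @param resid optional log-scale marginal residuals used to compute the
#'   BLUPs when `components$gamma` is `NULL`.
#' @return A data frame of class `rim_prediction` with columns `cluster`,
#'   `eta`, `re_factor`, `err_factor`, `pred` (method `"conditional_lmm"`).
#' @export
predict_lmm <- function(beta, components, X, resid = NULL) {
  stopifnot(inherits(components, "lmm_components"))
  if (is.null(dim(X))) X <- matrix(X, ncol = length(beta))
  if (nrow(X) != nrow(components$U)) {
    validation_error("X is not aligned with the components")
  }
  gamma <- components$gamma
  if (is.null(gamma)) {
    if (is.null(resid)) validation_error("need gamma in the components or resid to compute it")
    gamma <- blup_lmm(components, resid)
  }
  n <- nrow(X)
  idx <- components$cluster_index
  V <- lapply(seq_along(components$levels),
              function(i) conditional_cov_lmm(components, i))
  ug <- rowSums(components$U * gamma[idx, , drop = FALSE])
  qf <- vapply(seq_len(n), function(r) {
    u <- components$U[r, ]
    as.numeric(u %*% V[[idx[r]]] %*% u)
  }, 0)
  err_var <- vapply(seq_len(n), function(r) {
    sel <- which(idx == idx[r])
    components$Sigma[[idx[r]]][which(sel == r), which(sel == r)]
  }, 0)
  eta <- as.numeric(X %*% beta) + ug
  out <- data.frame(cluster = components$cluster, eta = eta,
                    re_factor = exp(0.5 * qf), err_factor = exp(0.5 * err_var),
                    stringsAsFactors = FALSE)
  out$pred <- exp(out$eta) * out$re_factor * out$err_factor
  structure(out, method = "conditional_lmm",
            class = c("rim_prediction", "data.frame"))
}

#' Transformations for back-prediction
#'
#' Builds a forward/inverse transform pair: the logarithm, a Box-Cox
#' transform with user-supplied `lambda` (`g(y) = (y^lambda - 1)/lambda`,
#' inverse `(lambda z + 1)^(1/lambda)`, undefined where
#' `lambda z + 1 <= 0`), or a user-supplied pair. The pair is checked to
#' round-trip (`g(g_inv(z)) = z`) on a probe grid to 1e-8.
#'
#' @param type `"log"`, `"boxcox"`, or `"custom"`.
#' @param lambda Box-Cox parameter (required for `"boxcox"`; `lambda = 0` is
#'   the logarithm).
#' @param g,g_inv forward and inverse maps for `"custom"`.
#' @param probe grid of transformed-scale values used for the round-trip
#'   check.
#' @return list with `g`, `g_inv`, `name`.
#' @export
make_transform <- function(type = c("log", "boxcox", "custom"), lambda = NULL,
                           g = NULL, g_inv = NULL,
                           probe = seq(-2, 2, length.out = 21)) {
  type <- match.arg(type)
  if (type == "log") {
    tr <- list(g = log, g_inv = exp, name = "log")
  } else if (type == "boxcox") {
    if (is.null(lambda)) config_error("boxcox transform needs lambda")
    if (lambda == 0) {
      tr <- list(g = log, g_inv = exp, name = "boxcox(0)")
    } else {
      force(lambda)
      tr <- list(
        g = function(y) (y^lambda - 1) / lambda,
        g_inv = function(z) {
          arg <- lambda * z + 1
          out <- rep(NaN, length(z))
          ok <- arg > 0
          out[ok] <- arg[ok]^(1 / lambda)
          out
        },
        name = sprintf("boxcox(%g)", lambda)
      )
    }
  } else {
    if (is.null(g) || is.null(g_inv)) config_error("custom transform needs g and g_inv")
    tr <- list(g = g, g_inv = g_inv, name = "custom")
  }
  z <- probe
  back <- suppressWarnings(tr$g(tr$g_inv(z)))  # NaN outside the domain is expected
  ok <- is.finite(back)
  if (!any(ok) || max(abs(back[ok] - z[ok])) > 1e-8) {
    validation_error("transform pair does not round-trip on the probe grid")
  }
  tr
}

#' Monte-Carlo back-transformation for a general transform
#'
#' For an invertible transform `g` applied to the response, approximates the
#' original-scale conditional mean per observation by simulation: draw
#' `z_l ~ N(u'gamma_i, u' Var(gamma_i | g(Y)) u)` for `l = 1..L` and average
#' `g_inv(x'beta + z_l + e)`, where the error term `e` is, by
#' `error_mode`, drawn from `N(0, sigma2/w)` per draw
#' (`"draw"`, the default — for `g = exp` this reproduces the closed-form
#' corrected predictor), the fitted residual (`"residual"`), or zero
#' (`"zero"`).
#'
#' @param beta fixed-effects vector.
#' @param components an [lmm_components] object with `gamma` set (or supply
#'   `resid`).
#' @param X fixed-effects design rows aligned with `components$U`.
#' @param transform a pair from [make_transform()].
#' @param L number of Monte-Carlo draws (>= 1).
#' @param seed integer seed; draws are reproducible given the seed.
#' @param error_mode `"draw"`, `"residual"`, or `"zero"`.
#' @param resid log-scale residuals; required for `error_mode = "residual"`
#'   and used for BLUPs when `components$gamma` is `NULL`.
#' @return Numeric vector of predictions with attributes `mc_se` (per
#'   observation Monte-Carlo standard error) and `undefined` (logical; TRUE
#'   where the inverse transform was undefined for some draws — such
#'   observations return `NaN`).
#' @export
mc_backtransform <- function(beta, components, X, transform, L = 10000L,
                             seed = 1L, error_mode = c("draw", "residual", "zero"),
                             resid = NULL) {
  stopifnot(inherits(components, "lmm_components"))
  error_mode <- match.arg(error_mode)
  if (L < 1) config_error("L must be >= 1")
  if (is.null(dim(X))) X <- matrix(X, ncol = length(beta))
  gamma <- components$gamma
  if (is.null(gamma)) {
    if (is.null(resid)) validation_error("need gamma in the components or resid to compute it")
    gamma <- blup_lmm(components, resid)
  }
  if (error_mode == "residual" && is.null(resid)) {
    validation_error("error_mode = 'residual' needs resid")
  }
  n <- nrow(X)
  idx <- components$cluster_index
  V <- lapply(seq_along(components$levels),
              function(i) conditional_cov_lmm(components, i))
  xb <- as.numeric(X %*% beta)
  ug <- rowSums(components$U * gamma[idx, , drop = FALSE])
  pred <- numeric(n)
  mcse <- numeric(n)
  undefined <- logical(n)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(n)) {
    u <- components$U[r, ]
    sd_z <- sqrt(max(as.numeric(u %*% V[[idx[r]]] %*% u), 0))
    zl <- stats::rnorm(L, mean = ug[r], sd = sd_z)
    e <- if (error_mode == "draw") {
      sel <- which(idx == idx[r])
      ev <- components$Sigma[[idx[r]]][which(sel == r), which(sel == r)]
      stats::rnorm(L, 0, sqrt(ev))
    } else if (error_mode == "residual") {
      rep(resid[r], L)
    } else {
      rep(0, L)
    }
    vals <- transform$g_inv(xb[r] + zl + e)
    if (anyNA(vals) || any(!is.finite(vals))) {
      undefined[r] <- TRUE
      pred[r] <- NaN
      mcse[r] <- NaN
    } else {
      pred[r] <- mean(vals)
      mcse[r] <- stats::sd(vals) / sqrt(L)
    }
  }
  structure(pred, mc_se = mcse, undefined = undefined)
}

#' Extract LMM components from a fitted model
#'
#' Adapter from fitted model objects to [lmm_components()]: the package's
#' own [fit_rim()] fits (q = 1, intercept-only design) and `lme4::lmer`
#' fits with a single grouping factor (estimation of `D` and `sigma^2` for
#' general LMMs is delegated to lme4; the corrections themselves are always
#' computed here).
#'
#' @param object a fitted model.
#' @param ... unused.
#' @return list with `beta`, `components` (an `lmm_components` with `gamma`
#'   filled in), `X`, and `resid` (log-scale marginal residuals).
#' @export
as_lmm_components <- function(object, ...) UseMethod("as_lmm_components")

#' @rdname as_lmm_components
#' @export
as_lmm_components.rim_fit <- function(object, ...) {
  d <- object$data
  comp <- lmm_components(U = rep(1, d$n), cluster = d$cluster,
                         D = matrix(object$sigma_gamma2, 1, 1),
                         sigma2 = object$sigma2, w = d$w,
                         gamma = matrix(object$gamma, ncol = 1))
  list(beta = object$beta, components = comp, X = d$X,
       resid = as.numeric(log(d$y) - d$X %*% object$beta))
}

#' @rdname as_lmm_components
#' @export
as_lmm_components.merMod <- function(object, ...) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    config_error("the lme4 package is required for this adapter")
  }
  fl <- lme4::getME(object, "flist")
  if (length(fl) != 1L) config_error("only a single grouping factor is supported")
  cluster <- as.character(fl[[1]])
  U <- lme4::getME(object, "mmList")[[1]]
  vc <- lme4::VarCorr(object)[[1]]
  D <- matrix(as.numeric(vc), nrow(vc), ncol(vc))
  sigma2 <- stats::sigma(object)^2
  pw <- stats::weights(object)
  if (length(pw) == 0L) pw <- rep(1, length(cluster))
  gamma <- as.matrix(lme4::ranef(object)[[1]])
  gamma <- gamma[unique(cluster), , drop = FALSE]
  X <- lme4::getME(object, "X")
  beta <- lme4::fixef(object)
  comp <- lmm_components(U = U, cluster = cluster, D = D, sigma2 = sigma2,
                         w = pw, gamma = gamma)
  y <- stats::model.response(stats::model.frame(object))
  list(beta = beta, components = comp, X = X,
       resid = as.numeric(y - X %*% beta))
}
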