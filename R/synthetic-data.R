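# Deterministic per-replicate seeds: O(1) state, order-independent, < 2^31.
derive_seeds <- function(master, n) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(2147483646L, n)
}

#' Simulation scenario configuration
#'
#' Describes one clustered-data generating scenario. The defaults are the
#' reference study conditions: p = 3 covariates (intercept plus two
#' independent U(0,1) columns), `beta = (0.8, 1.3, -0.7)`, the indexed
#' heteroscedasticity weight rule `w_ij = (i+1)/10 + j/1000`, and variance
#' components 0.2. Balanced designs use a scalar `n_i`; unbalanced designs
#' pass a length-m vector (the reference unbalanced designs are
#' `n_i = 11..50` with m = 40 and `n_i = 11..90` with m = 80, i.e.
#' `n_i = 10 + i`).
#'
#' @param m number of clusters.
#' @param n_i cluster size (scalar, recycled) or length-m vector.
#' @param beta fixed-effects vector (first entry is the intercept).
#' @param sigma2 error variance (log scale).
#' @param sigma_gamma2 random-intercept variance.
#' @param family `"lognormal"` (log-scale Gaussian RIM) or `"gamma"`
#'   (gamma GLMM with log link, shape `alpha * w_ij`).
#' @param alpha gamma shape multiplier (only used for `family = "gamma"`).
#' @param weights weight rule: `"indexed"` (`w_ij = (i+1)/10 + j/1000`),
#'   `"unit"`, `"cluster_size"` (`w_ij = n_i`), or `"covariate"` (second
#'   design column shifted to be >= 0.1).
#' @param seed master seed; per-replicate seeds are derived from it and the
#'   replicate index, so any table cell is reproducible in isolation.
#' @param fixed_x if TRUE, covariates are drawn once (from the master seed)
#'   and shared across replicates; by default they are redrawn each
#'   replicate.
#' @param label optional scenario label used in study tables.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(m = 50, n_i = 10, beta = c(0.8, 1.3, -0.7),
                            sigma2 = 0.2, sigma_gamma2 = 0.2,
                            family = c("lognormal", "gamma"), alpha = 1,
                            weights = c("indexed", "unit", "cluster_size", "covariate"),
                            seed = 1L, fixed_x = FALSE, label = NULL) {
  family <- match.arg(family)
  weights <- match.arg(weights)
  if (length(n_i) == 1L) n_i <- rep(as.integer(n_i), m)
  n_i <- as.integer(n_i)
  if (length(n_i) != m || any(n_i < 1)) {
    validation_error("n_i must be a scalar or a length-m vector of sizes >= 1")
  }
  if (sigma2 <= 0 || sigma_gamma2 <= 0) {
    validation_error("generating variances must be positive")
  }
  if (alpha <= 0) validation_error("alpha must be positive")
  if (is.null(label)) {
    design <- if (length(unique(n_i)) == 1L) {
      sprintf("m=%d,n_i=%d", m, n_i[1])
    } else {
      sprintf("m=%d,n_i=%d..%d", m, min(n_i), max(n_i))
    }
    label <- sprintf("%s,%s,s2=%g,sg2=%g%s", family, design, sigma2, sigma_gamma2,
                     if (family == "gamma") sprintf(",alpha=%g", alpha) else "")
  }
  structure(list(m = m, n_i = n_i, beta = beta, p = length(beta),
                 sigma2 = sigma2, sigma_gamma2 = sigma_gamma2,
                 family = family, alpha = alpha, weights = weights,
                 seed = as.integer(seed), fixed_x = fixed_x, label = label),
            class = "scenario_config")
}

# Design skeleton shared by the generators: cluster ids, X, weights.
generate_design <- function(cfg) {
  n <- sum(cfg$n_i)
  cl_i <- rep(seq_len(cfg$m), cfg$n_i)
  j_in <- sequence(cfg$n_i)
  X <- cbind(1, matrix(stats::runif(n * (cfg$p - 1)), n, cfg$p - 1))
  colnames(X) <- paste0("x", seq_len(cfg$p))
  w <- switch(cfg$weights,
    indexed = (cl_i + 1) / 10 + j_in / 1000,
    unit = rep(1, n),
    cluster_size = as.numeric(cfg$n_i[cl_i]),
    covariate = {
      v <- X[, 2]
      if (any(v <= 0)) v <- v - min(v) + 0.1
      v
    })
  list(cluster = paste0("c", cl_i), cl_i = cl_i, X = X, w = w, n = n)
}

#' Generate clustered log-normal data from the random-intercept model
#'
#' Draws `gamma_i ~ N(0, sigma_gamma^2)`, `eps_ij = sigma * w_ij^{-1/2} z_ij`
#' with standard-normal `z_ij`, and returns
#' `y = exp(X beta + gamma + eps)` as a [clustered_data] object. The true
#' effects are attached for recovery checks.
#'
#' @param cfg a [scenario_config()] with `family = "lognormal"`.
#' @param replicate replicate index (>= 1); together with the master seed it
#'   determines the dataset bit-for-bit.
#' @return [clustered_data] with attribute `truth`: list with `gamma`
#'   (length m), `eps` (length n), `eta` (`X beta`), `seed`.
#' @export
generate_lognormal <- function(cfg, replicate = 1L) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$family != "lognormal") config_error("cfg$family must be 'lognormal'")
  seeds <- derive_seeds(cfg$seed, replicate + 1L)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  if (cfg$fixed_x) {
    set.seed(seeds[1])
    des <- generate_design(cfg)
    set.seed(seeds[replicate + 1L])
  } else {
    set.seed(seeds[replicate + 1L])
    des <- generate_design(cfg)
  }
  gamma <- stats::rnorm(cfg$m, 0, sqrt(cfg$sigma_gamma2))
  eps <- sqrt(cfg$sigma2) * des$w^(-0.5) * stats::rnorm(des$n)
  eta <- as.numeric(des$X %*% cfg$beta)
  y <- exp(eta + gamma[des$cl_i] + eps)
  out <- clustered_data(des$cluster, y, des$X, des$w)
  attr(out, "truth") <- list(gamma = gamma, eps = eps, eta = eta,
                             seed = seeds[replicate + 1L])
  out
}

#' Generate clustered gamma data with log link
#'
#' Draws `gamma_i ~ N(0, sigma_gamma^2)` and
#' `y_ij ~ Gamma(shape = alpha w_ij, scale = exp(x'beta + gamma_i) /
#' (alpha w_ij))`, so that `E[y_ij | gamma_i] = exp(x'beta + gamma_i)`
#' exactly. Used to probe the log-scale model under misspecification.
#'
#' @inheritParams generate_lognormal
#' @return [clustered_data] with attribute `truth`: list with `gamma`,
#'   `eta`, `seed`.
#' @export
generate_gamma <- function(cfg, replicate = 1L) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$family != "gamma") config_error("cfg$family must be 'gamma'")
  seeds <- derive_seeds(cfg$seed, replicate + 1L)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  if (cfg$fixed_x) {
    set.seed(seeds[1])
    des <- generate_design(cfg)
    set.seed(seeds[replicate + 1L])
  } else {
    set.seed(seeds[replicate + 1L])
    des <- generate_design(cfg)
  }
  gamma <- stats::rnorm(cfg$m, 0, sqrt(cfg$sigma_gamma2))
  eta <- as.numeric(des$X %*% cfg$beta)
  mu <- exp(eta + gamma[des$cl_i])
  shape <- cfg$alpha * des$w
  y <- stats::rgamma(des$n, shape = shape, scale = mu / shape)
  out <- clustered_data(des$cluster, y, des$X, des$w)
  attr(out, "truth") <- list(gamma = gamma, eta = eta,
                             seed = seeds[replicate + 1L])
  out
}

#' Generate data mimicking a large income-style survey
#'
#' Log-normal random-intercept data with n = 2000 observations in 20
#' clusters of sizes 62..138 (`n_i = 58 + 4i`), an intercept near 9 (so the
#' response lives on an income-like scale), an integer covariate in 1..15
#' (a count such as the number of light bulbs in a household) and one
#' U(0,1) covariate. Heteroscedasticity weights are either the cluster size
#' or the count covariate (shifted to be >= 0.1 if necessary).
#'
#' @param weight_source `"cluster_size"` or `"covariate"`.
#' @param sigma error standard deviation (reference values 0.15, 0.594, 1.2).
#' @param sigma_gamma random-intercept standard deviation (reference values
#'   0.079, 0.32, 1.28).
#' @param seed master seed.
#' @param replicate replicate index.
#' @param beta fixed effects; default `(9.1, 0.014, -0.1)`.
#' @return [clustered_data] with attributes `truth` (as in
#'   [generate_lognormal()]) and `config` (the generating
#'   [scenario_config()]).
#' @export
generate_mimic <- function(weight_source = c("cluster_size", "covariate"),
                           sigma = 0.594, sigma_gamma = 0.079, seed = 1L,
                           replicate = 1L, beta = c(9.1, 0.014, -0.1)) {
  weight_source <- match.arg(weight_source)
  cfg <- scenario_config(m = 20, n_i = 58 + 4 * (1:20), beta = beta,
                         sigma2 = sigma^2, sigma_gamma2 = sigma_gamma^2,
                         family = "lognormal", weights = weight_source,
                         seed = seed,
                         label = sprintf("mimic,%s,sigma=%g,sigma_gamma=%g",
                                         weight_source, sigma, sigma_gamma))
  seeds <- derive_seeds(cfg$seed, replicate + 1L)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seeds[replicate + 1L])
  n <- sum(cfg$n_i)
  cl_i <- rep(seq_len(cfg$m), cfg$n_i)
  X <- cbind(1, sample(1:15, n, replace = TRUE), stats::runif(n))
  colnames(X) <- c("x1", "bulbs", "x3")
  w <- if (weight_source == "cluster_size") {
    as.numeric(cfg$n_i[cl_i])
  } else {
    v <- X[, 2]
    if (any(v <= 0)) validation_error("covariate weights need a positive covariate")
    v
  }
  gamma <- stats::rnorm(cfg$m, 0, sigma_gamma)
  eps <- sigma * w^(-0.5) * stats::rnorm(n)
  eta <- as.numeric(X %*% cfg$beta)
  y <- exp(eta + gamma[cl_i] + eps)
  out <- clustered_data(paste0("c", cl_i), y, X, w)
  attr(out, "truth") <- list(gamma = gamma, eps = eps, eta = eta,
                             seed = seeds[replicate + 1L])
  attr(out, "config") <- cfg
  out
}

#' Generate one replicate of any scenario
#'
#' Dispatches on `cfg$family`.
#'
#' @inheritParams generate_lognormal
#' @return [clustered_data] with a `truth` attribute.
#' @export
generate_scenario <- function(cfg, replicate = 1L) {
  switch(cfg$family,
         lognormal = generate_lognormal(cfg, replicate),
         gamma = generate_gamma(cfg, replicate))
}
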