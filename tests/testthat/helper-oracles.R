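# Independent dense-matrix oracles and small data builders used across the
# suite. Everything here deliberately uses naive O(n^3) linear algebra so it
# shares no code path with the package internals.

make_toy <- function(m = 5, n_i = 4, p = 2, seed = 1, w = NULL,
                     sigma2 = 0.3, sigma_gamma2 = 0.25,
                     beta = seq_len(p) / p) {
  set.seed(seed)
  if (length(n_i) == 1L) n_i <- rep(n_i, m)
  n <- sum(n_i)
  cl <- rep(paste0("k", seq_len(m)), n_i)
  X <- cbind(1, matrix(runif(n * (p - 1)), n, p - 1))
  if (is.null(w)) w <- runif(n, 0.5, 3)
  gam <- rnorm(m, 0, sqrt(sigma_gamma2))
  eps <- rnorm(n, 0, sqrt(sigma2 / w))
  y <- exp(as.numeric(X %*% beta) + rep(gam, n_i) + eps)
  clustered_data(cl, y, X, w)
}

# Dense marginal covariance of log(y): block-diagonal
# V_i = sigma_gamma2 * 11' + sigma2 * diag(1/w_i)
dense_V <- function(data, sigma2, sigma_gamma2) {
  n <- data$n
  V <- matrix(0, n, n)
  for (i in seq_len(data$m)) {
    sel <- which(data$cluster_index == i)
    V[sel, sel] <- sigma_gamma2
  }
  diag(V) <- diag(V) + sigma2 / data$w
  V
}

# Exact multivariate-normal log-likelihood at (beta profiled by dense GLS,
# sigma2, sigma_gamma2); ML convention.
dense_loglik_ml <- function(data, sigma2, sigma_gamma2) {
  V <- dense_V(data, sigma2, sigma_gamma2)
  Vi <- solve(V)
  z <- log(data$y)
  X <- data$X
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% z)
  r <- z - X %*% beta
  as.numeric(-0.5 * (data$n * log(2 * pi) + determinant(V)$modulus +
                       t(r) %*% Vi %*% r))
}

# BLUP by explicit dense inversion: gamma_i = g2 * 1' V_i^{-1} (z_i - X_i b)
dense_blup <- function(data, beta, sigma2, sigma_gamma2) {
  z <- log(data$y)
  r <- z - data$X %*% beta
  out <- numeric(data$m)
  for (i in seq_len(data$m)) {
    sel <- which(data$cluster_index == i)
    ni <- length(sel)
    Vi <- sigma_gamma2 * matrix(1, ni, ni) + diag(sigma2 / data$w[sel], ni)
    out[i] <- sigma_gamma2 * sum(solve(Vi, r[sel]))
  }
  names(out) <- data$levels
  out
}

# Joint-Gaussian conditioning oracle for the general LMM: build the stacked
# covariance of (gamma_i, log Y) over the FULL sample and condition directly.
joint_conditional_cov <- function(comp, i) {
  n <- nrow(comp$U)
  q <- comp$q
  # Cov(log Y) dense over all clusters
  V <- matrix(0, n, n)
  C <- matrix(0, q, n)   # Cov(gamma_i, log Y)
  for (k in seq_along(comp$levels)) {
    sel <- which(comp$cluster_index == k)
    Uk <- comp$U[sel, , drop = FALSE]
    V[sel, sel] <- Uk %*% comp$D %*% t(Uk) + comp$Sigma[[k]]
    if (k == i) C[, sel] <- comp$D %*% t(Uk)
  }
  comp$D - C %*% solve(V, t(C))
}
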