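test_that("q = 1 conditional covariance reduces to the scalar conditional variance", {
  set.seed(6)
  for (k in 1:50) {
    ni <- sample(1:8, 1)
    w <- runif(ni, 0.2, 4)
    g2 <- runif(1, 0.01, 1)
    s2 <- runif(1, 0.01, 1)
    comp <- lmm_components(U = rep(1, ni), cluster = rep("a", ni),
                           D = g2, sigma2 = s2, w = w)
    V <- conditional_cov_lmm(comp, 1)
    expect_lt(abs(V[1, 1] - conditional_variance(g2, s2, sum(w))), 1e-10)
  }
})

test_that("zero random-effects covariance gives a zero conditional covariance", {
  comp <- lmm_components(U = cbind(1, 1:3), cluster = rep("a", 3),
                         D = matrix(0, 2, 2), sigma2 = 0.5)
  expect_equal(conditional_cov_lmm(comp, 1), matrix(0, 2, 2))
})

test_that("intercept+slope case matches the expanded two-effect formula", {
  set.seed(14)
  for (k in 1:10) {
    ni <- sample(3:9, 1)
    u <- runif(ni, -1, 2)
    sg1 <- runif(1, 0.05, 0.8); sg2 <- runif(1, 0.05, 0.8)
    rho <- runif(1, -0.8, 0.8)
    s12 <- rho * sqrt(sg1 * sg2)
    D <- matrix(c(sg1, s12, s12, sg2), 2)
    w <- runif(ni, 0.3, 3)
    s2 <- runif(1, 0.05, 1)
    comp <- lmm_components(U = cbind(1, u), cluster = rep("a", ni),
                           D = D, sigma2 = s2, w = w)
    got <- conditional_cov_lmm(comp, 1)
    # term-by-term expansion: D - A [sg1 11' + s12(u1' + 1u') + sg2 uu' + Sigma]^-1 A'
    ones <- rep(1, ni)
    M <- sg1 * tcrossprod(ones) + s12 * (tcrossprod(u, ones) + tcrossprod(ones, u)) +
      sg2 * tcrossprod(u) + diag(s2 / w, ni)
    A_t <- cbind(sg1 * ones + s12 * u, s12 * ones + sg2 * u)  # n_i x 2 = A'
    oracle <- D - t(A_t) %*% solve(M) %*% A_t
    expect_lt(max(abs(got - oracle)), 1e-10)
  }
})

test_that("conditional covariance agrees with direct joint-Gaussian conditioning", {
  set.seed(26)
  for (k in 1:5) {
    q <- sample(1:3, 1)
    m <- 3
    n_i <- sample(3:7, m, replace = TRUE)
    L <- matrix(rnorm(q * q), q)
    D <- crossprod(L) + diag(1e-3, q)
    U <- matrix(rnorm(sum(n_i) * q), ncol = q)
    U[, 1] <- 1
    comp <- lmm_components(U = U, cluster = rep(paste0("c", 1:m), n_i),
                           D = D, sigma2 = 0.4, w = runif(sum(n_i), 0.5, 2))
    for (i in 1:m) {
      expect_lt(max(abs(conditional_cov_lmm(comp, i) - joint_conditional_cov(comp, i))),
                1e-9)
      # Loewner order: D - Var(gamma_i | data) is PSD
      ev <- eigen(D - conditional_cov_lmm(comp, i), symmetric = TRUE)$values
      expect_gte(min(ev), -1e-10)
    }
  }
})

test_that("the intercept-only LMM predictor equals the RIM conditional predictor", {
  d <- make_toy(m = 6, n_i = 5, seed = 33)
  fit <- fit_rim(d)
  st <- as_lmm_components(fit)
  got <- predict_lmm(st$beta, st$components, st$X)
  want <- predict_rim(fit, d, "conditional")
  expect_equal(got$pred, want$pred, tolerance = 1e-12)
})

test_that("degenerate LMM with no random variation returns the bare exponential", {
  X <- cbind(1, c(0.1, 0.5, 0.9))
  comp <- lmm_components(U = rep(1, 3), cluster = rep("a", 3),
                         D = matrix(0, 1, 1), sigma2 = 0,
                         gamma = matrix(0, 1, 1))
  p <- predict_lmm(c(0.3, 1.1), comp, X)
  expect_equal(p$pred, as.numeric(exp(X %*% c(0.3, 1.1))))
  # quadratic form is PSD, so the random-effect factor is never below 1
  d <- make_toy(m = 5, n_i = 4, seed = 3)
  st <- as_lmm_components(fit_rim(d))
  expect_true(all(predict_lmm(st$beta, st$components, st$X)$re_factor >= 1))
})

test_that("lme4 adapter reproduces corrections for an intercept+slope model", {
  skip_if_not_installed("lme4")
  set.seed(52)
  m <- 15; n_i <- 12; n <- m * n_i
  cl <- rep(paste0("g", 1:m), each = n_i)
  u <- runif(n)
  G <- cbind(rnorm(m, 0, 0.4), rnorm(m, 0, 0.3))
  z <- 1 + 0.8 * u + G[rep(1:m, each = n_i), 1] +
    G[rep(1:m, each = n_i), 2] * u + rnorm(n, 0, 0.3)
  lf <- lme4::lmer(z ~ u + (1 + u | cl),
                   data = data.frame(z = z, u = u, cl = cl))
  st <- as_lmm_components(lf)
  expect_equal(st$components$q, 2L)
  p <- predict_lmm(st$beta, st$components, st$X)
  # BLUP route inside the package agrees with lme4's own BLUPs
  own <- blup_lmm(st$components, st$resid)
  expect_equal(unname(own), unname(st$components$gamma), tolerance = 1e-4)
  expect_true(all(p$pred > 0) && all(p$re_factor >= 1))
})

test_that("transform pairs round-trip and broken pairs are rejected", {
  tr <- make_transform("boxcox", lambda = 0.5)
  y <- c(0.1, 1, 5, 20)
  expect_equal(tr$g_inv(tr$g(y)), y, tolerance = 1e-12)
  expect_equal(make_transform("boxcox", lambda = 0)$g, log)
  expect_error(make_transform("custom", g = log, g_inv = sqrt),
               class = "rimcorrect_validation_error")
})

test_that("Monte-Carlo back-transform is seed-deterministic and hits the closed form", {
  d <- make_toy(m = 4, n_i = 5, seed = 44)
  fit <- fit_rim(d)
  st <- as_lmm_components(fit)
  tr <- make_transform("log")

  a <- mc_backtransform(st$beta, st$components, st$X, tr, L = 1, seed = 99)
  b <- mc_backtransform(st$beta, st$components, st$X, tr, L = 1, seed = 99)
  expect_identical(as.numeric(a), as.numeric(b))

  p <- mc_backtransform(st$beta, st$components, st$X, tr, L = 20000, seed = 5)
  closed <- predict_lmm(st$beta, st$components, st$X)$pred
  expect_true(all(abs(as.numeric(p) - closed) <= 4 * attr(p, "mc_se")))

  # convergence at the Monte-Carlo rate: a larger L gets closer on average
  p2 <- mc_backtransform(st$beta, st$components, st$X, tr, L = 80000, seed = 5)
  expect_lt(mean(abs(as.numeric(p2) - closed)), mean(abs(as.numeric(p) - closed)))
})

test_that("undefined inverse transforms are flagged, zero-variance mode is exact", {
  X <- cbind(1, c(0.2, 0.8))
  comp <- lmm_components(U = rep(1, 2), cluster = c("a", "a"),
                         D = matrix(0, 1, 1), sigma2 = 0,
                         gamma = matrix(0, 1, 1))
  tr <- make_transform("boxcox", lambda = 2)
  beta <- c(-5, 0)  # lambda*z + 1 < 0 for every draw
  p <- mc_backtransform(beta, comp, X, tr, L = 10, seed = 1, error_mode = "zero")
  expect_true(all(attr(p, "undefined")))
  expect_true(all(is.nan(as.numeric(p))))

  trlog <- make_transform("log")
  p0 <- mc_backtransform(c(0.4, 1), comp, X, trlog, L = 3, seed = 1,
                         error_mode = "zero")
  expect_identical(as.numeric(p0), as.numeric(exp(X %*% c(0.4, 1))))
})
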