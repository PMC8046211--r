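test_that("ML optimum dominates a dense brute-force grid on a tiny instance", {
  d <- make_toy(m = 3, n_i = 2, p = 1, seed = 5)
  fit <- fit_rim(d, method = "ML")
  grid <- expand.grid(ls2 = seq(-4, 1, length.out = 25),
                      lg2 = seq(-6, 1, length.out = 25))
  grid_ll <- mapply(function(a, b) dense_loglik_ml(d, exp(a), exp(b)),
                    grid$ls2, grid$lg2)
  expect_gte(fit$loglik, max(grid_ll) - 1e-6)
  # and the reported loglik is attained at the reported variances
  expect_equal(fit$loglik, dense_loglik_ml(d, fit$sigma2, fit$sigma_gamma2),
               tolerance = 1e-8)
})

test_that("REML estimates agree with lme4 and nlme on the same model", {
  skip_if_not_installed("lme4")
  skip_if_not_installed("nlme")
  d <- make_toy(m = 20, n_i = 8, p = 3, seed = 9)
  fit <- fit_rim(d, method = "REML")
  df <- data.frame(z = log(d$y), x2 = d$X[, 2], x3 = d$X[, 3],
                   cl = d$cluster, w = d$w, vw = 1 / d$w)

  lf <- lme4::lmer(z ~ x2 + x3 + (1 | cl), data = df, weights = w, REML = TRUE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
  expect_equal(fit$sigma2, stats::sigma(lf)^2, tolerance = 1e-4)
  expect_equal(fit$sigma_gamma2, as.numeric(lme4::VarCorr(lf)$cl), tolerance = 1e-4)
  expect_equal(unname(fit$gamma),
               lme4::ranef(lf)$cl[names(fit$gamma), 1], tolerance = 1e-5)

  nf <- nlme::lme(z ~ x2 + x3, random = ~ 1 | cl, data = df,
                  weights = nlme::varFixed(~vw), method = "REML")
  expect_equal(unname(fit$beta), unname(nlme::fixef(nf)), tolerance = 1e-5)
  expect_equal(fit$sigma2, nf$sigma^2, tolerance = 1e-4)
})

test_that("fit is invariant to permuting clusters and rows within clusters", {
  d <- make_toy(m = 8, n_i = 5, seed = 21)
  fit <- fit_rim(d)
  set.seed(1)
  perm <- sample(d$n)
  d2 <- clustered_data(d$cluster[perm], d$y[perm], d$X[perm, ], d$w[perm])
  fit2 <- fit_rim(d2)
  expect_equal(fit$sigma2, fit2$sigma2, tolerance = 1e-7)
  expect_equal(fit$sigma_gamma2, fit2$sigma_gamma2, tolerance = 1e-7)
  expect_equal(unname(fit$beta), unname(fit2$beta), tolerance = 1e-7)
  expect_equal(fit$gamma[d$levels], fit2$gamma[d$levels], tolerance = 1e-7)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-7)
})

test_that("profile identity: beta equals GLS recomputed from the fitted variances", {
  d <- make_toy(m = 6, n_i = 4, seed = 13)
  fit <- fit_rim(d)
  V <- dense_V(d, fit$sigma2, fit$sigma_gamma2)
  Vi <- solve(V)
  b <- solve(t(d$X) %*% Vi %*% d$X, t(d$X) %*% Vi %*% log(d$y))
  expect_equal(unname(fit$beta), as.numeric(b), tolerance = 1e-8)
})

test_that("degenerate data pushes the random-effect variance to the boundary", {
  set.seed(2)
  m <- 10; n_i <- 6; n <- m * n_i
  X <- cbind(1, runif(n))
  # no cluster effect at all, tiny noise
  y <- exp(as.numeric(X %*% c(0.5, 1)) + rnorm(n, 0, 1e-4))
  d <- clustered_data(rep(paste0("c", 1:m), each = n_i), y, X)
  fit <- fit_rim(d)
  expect_lt(fit$sigma_gamma2, 1e-6)
  # rank-deficient designs are refused
  d2 <- clustered_data(d$cluster, d$y, cbind(1, X[, 2], X[, 2]))
  expect_error(fit_rim(d2), class = "rimcorrect_model_error")
})

test_that("BLUP shrinkage formula matches dense inversion and its closed forms", {
  # sigma_gamma2 = 0: all BLUPs vanish
  d <- make_toy(m = 4, n_i = 3, seed = 31)
  expect_equal(unname(blup_rim(d, c(0.5, 1), sigma2 = 0.3, sigma_gamma2 = 0)),
               rep(0, 4))

  # single cluster, single observation, w = 1: r * g2 / (g2 + s2)
  d1 <- clustered_data("a", exp(1.3), matrix(1), w = 1)
  r <- 1.3 - 0.2
  expect_equal(unname(blup_rim(d1, 0.2, sigma2 = 0.5, sigma_gamma2 = 0.3)),
               r * 0.3 / (0.3 + 0.5), tolerance = 1e-12)

  # random instances: closed form vs dense inversion to 1e-10
  for (seed in 1:5) {
    di <- make_toy(m = 5, n_i = sample(2:6, 5, replace = TRUE), seed = seed)
    beta <- c(0.4, 0.9)
    g <- blup_rim(di, beta, sigma2 = 0.35, sigma_gamma2 = 0.15)
    go <- dense_blup(di, beta, 0.35, 0.15)
    expect_lt(max(abs(g - go)), 1e-10)
  }
})

test_that("boundary LRT halves the chi-square tail", {
  # statistic 2.706 corresponds to p ~ 0.05 under the 0.5*chi2_0 + 0.5*chi2_1 mixture
  expect_equal(0.5 * pchisq(2.706, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)

  d <- make_toy(m = 15, n_i = 6, seed = 17, sigma_gamma2 = 0.5)
  out <- lrt_random_effect(d)
  expect_equal(out$statistic, 2 * (out$loglik_rim - out$loglik_null))
  expect_equal(out$p_value, 0.5 * pchisq(out$statistic, 1, lower.tail = FALSE))
  expect_gte(out$statistic, 0)

  # no cluster effect: statistic collapses and p sits at the mixture mass 0.5
  set.seed(4)
  X <- cbind(1, runif(40))
  y <- exp(as.numeric(X %*% c(1, 0.5)) + rnorm(40, 0, 0.2))
  d0 <- clustered_data(rep(letters[1:8], each = 5), y, X)
  out0 <- lrt_random_effect(d0)
  if (out0$statistic == 0) expect_equal(out0$p_value, 0.5)
  expect_lte(out0$p_value, 0.5)
})

test_that("LRT rejects a genuine random effect in nearly every replicate", {
  cfg <- scenario_config(m = 50, n_i = 20, sigma2 = 0.2, sigma_gamma2 = 0.4,
                         seed = 42)
  rej <- 0L
  for (r in 1:100) {
    d <- generate_lognormal(cfg, r)
    if (lrt_random_effect(d)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej, 95L)
})

test_that("fit artifact round-trips through its plain-text form", {
  d <- make_toy(m = 5, n_i = 4, seed = 23)
  fit <- fit_rim(d)
  f <- withr::local_tempfile()
  write_rim_artifact(fit, f)
  art <- read_rim_artifact(f)
  expect_identical(art$beta, fit$beta)
  expect_identical(art$gamma, fit$gamma)
  expect_identical(art$sigma2, fit$sigma2)
  expect_identical(art$sigma_gamma2, fit$sigma_gamma2)
  expect_identical(art$method, fit$method)
})
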