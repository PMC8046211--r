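# rimcorrect

Corrected original-scale predictions from random-intercept and linear mixed
models fitted on the logarithmic scale.

## The problem

Positive, right-skewed, clustered responses — income of individuals nested
in states, expenditures of patients nested in hospitals — are commonly
modelled with a random-intercept model (RIM) on the log scale, possibly
with known heteroscedasticity weights:

    log(Y_ij) = x_ij' β + γ_i + ε_ij,
    γ_i ~ N(0, σ_γ²),   ε_ij ~ N(0, σ² / w_ij)

Predictions are usually wanted on the original scale, and the common
practice of exponentiating the fitted value, `exp(x'β̂ + γ̂_i)`,
systematically **underestimates** `E[Y_ij]`: each Gaussian term on the log
scale contributes a multiplicative factor `exp(variance/2)` on the original
scale. `rimcorrect` fits the heteroscedastic RIM and provides the full
family of corrected predictors:

* the error-term factor `exp(σ̂² w⁻¹ / 2)`;
* the random-intercept factor `exp(v_i / 2)`, where
  `v_i = Var(γ_i | log Y) = σ_γ² (1 − σ_γ² / (σ_γ² + σ² / Σ_j w_ij))`
  is the conditional (posterior) variance of the cluster's intercept given
  the sample — the key quantity that makes the BLUP-based predictor
  correct rather than merely less wrong;
* nonparametric smearing factors (global and per-cluster means of
  exponentiated residuals) for when log-scale normality of the errors is
  doubtful;
* the generalization to any linear mixed model via
  `Var(γ_i | log Y) = D − D U_i'(U_i D U_i' + Σ_i)⁻¹ U_i D`, and a
  seed-reproducible Monte-Carlo back-transformation for invertible
  transformations other than the logarithm (e.g. Box-Cox).

It also ships the synthetic-data generators (log-normal RIM, gamma GLMM
with log link, and an income-survey-like mimic design) and the replication
harness that scores all methods by original-scale mean squared error.

For whom: analysts predicting monetary or other log-modelled outcomes from
clustered data, and small-area-estimation workflows built on nested-error
models.

## Worked example

```r
library(rimcorrect)

cfg <- scenario_config(m = 50, n_i = 10, seed = 7)   # 50 clusters of 10
d   <- generate_lognormal(cfg, replicate = 1)
fit <- fit_rim(d)                                    # REML by default
fit
#> Heteroscedastic random-intercept model (log scale), REML fit
#>   500 observations, 50 clusters; status: converged
#>   fixed effects:
#>        x1        x2        x3
#>  0.733910  1.289701 -0.646858
#>   sigma^2 = 0.178626   sigma_gamma^2 = 0.223455   logLik = -179.4665

p <- predict_rim(fit, method = "conditional")
head(p, 3)
#>   cluster       eta re_factor err_factor     pred
#> 1      c1 1.2130510  1.031784   1.559465 5.412351
#> 2      c1 1.4337410  1.031784   1.556038 6.734031
#> 3      c1 0.1706863  1.031784   1.552653 1.900166
```

The generating values were β = (0.8, 1.3, −0.7), σ² = σ_γ² = 0.2; the fit
recovers them. Each prediction decomposes exactly into
`exp(eta) * re_factor * err_factor`: row 1's naive prediction
`exp(1.213) = 3.36` is inflated by ~3.2% for the cluster-intercept
uncertainty and ~56% for the error term (its weight is small, so its error
variance is large), giving 5.41. Corrections matter:

```r
mse(d$y, predict_rim(fit, method = "naive")$pred)   # 2.20668
mse(d$y, p$pred)                                    # 2.119232

lrt_random_effect(d)   # boundary LRT: statistic 549.01, p ~ 1e-121
```

A command-line interface wrapping the same functions (verbs `fit`,
`predict`, `predict-lmm`, `simulate`, `evaluate`) is installed at
`inst/cli/rimcorrect`.

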