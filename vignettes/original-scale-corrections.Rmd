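---
title: "Correcting original-scale predictions from log-scale mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting original-scale predictions from log-scale mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rimcorrect)
```

## The model and the problem

Income, expenditures, and many other positive, right-skewed responses are
routinely modelled on the logarithmic scale. When observations are nested in
clusters (households in states, patients in hospitals), the working model is
a random-intercept model (RIM) with, possibly, known heteroscedasticity
weights:

$$\log(Y_{ij}) = \mathbf{x}_{ij}'\boldsymbol\beta + \gamma_i + \epsilon_{ij},
\qquad \gamma_i \sim N(0, \sigma_\gamma^2), \quad
\epsilon_{ij} \sim N(0, \sigma^2 w_{ij}^{-1}),$$

for clusters $i = 1,\dots,m$ and observations $j = 1,\dots,n_i$, with the
weights $w_{ij} > 0$ treated as known constants. Interest, however, is in
predictions of $Y_{ij}$ on the *original* scale. Simply exponentiating the
fitted value, $\exp(\mathbf{x}'\hat\beta + \hat\gamma_i)$, underestimates
$E[Y_{ij}]$: by Jensen's inequality the expectation of a log-normal variable
exceeds the exponential of its log-scale mean. Each Gaussian term on the log
scale contributes a multiplicative correction factor
$\exp(\tfrac12 \cdot \text{variance})$ on the original scale, and because
the RIM has two random terms there are two factors — one for the error, one
for the random intercept.

## The six estimators

`predict_rim()` implements the six estimators, labelled by
`correction_methods()`:

| label | estimator |
|---|---|
| `naive` | $\exp(\mathbf{x}'\hat\beta + \hat\gamma_i)$ |
| `marginal` | $\exp(\mathbf{x}'\hat\beta)\,e^{\hat\sigma_\gamma^2/2}\,e^{\hat\sigma^2 w^{-1}/2}$ |
| `error_only` | $\exp(\mathbf{x}'\hat\beta + \hat\gamma_i)\,e^{\hat\sigma^2 w^{-1}/2}$ |
| `conditional` | $\exp(\mathbf{x}'\hat\beta + \hat\gamma_i)\,e^{v_i/2}\,e^{\hat\sigma^2 w^{-1}/2}$ |
| `smearing_global` | $\exp(\mathbf{x}'\hat\beta + \hat\gamma_i)\,e^{v_i/2}\,\tfrac1n\sum_{ij} e^{\hat\epsilon_{ij}}$ |
| `smearing_cluster` | $\exp(\mathbf{x}'\hat\beta + \hat\gamma_i)\,e^{v_i/2}\,\tfrac1{n_i}\sum_{j} e^{\hat\epsilon_{ij}}$ |

The `marginal` estimator uses the prior variance of $\gamma_i$ and no BLUP;
it is the right choice only when nothing is known about the cluster. The
`error_only` estimator corrects the error term but treats
$\exp(\hat\gamma_i)$ as if it were $E[\exp(\gamma_i)\mid \log \mathbf{Y}]$,
which again underestimates by Jensen. The `conditional` estimator is the
centrepiece: conditioning the random intercept on the observed sample gives

$$\gamma_i \mid \log \mathbf{Y} \sim
N\!\left(\hat\gamma_i,\; v_i\right), \qquad
v_i = \sigma_\gamma^2\left(1 -
\frac{\sigma_\gamma^2}{\sigma_\gamma^2 + \sigma^2/\sum_j w_{ij}}\right),$$

so $E[\exp(\gamma_i)\mid\log\mathbf{Y}] = \exp(\hat\gamma_i + v_i/2)$. The
posterior variance $v_i$ — equivalently the precision form
$(1/\sigma_\gamma^2 + \sum_j w_{ij}/\sigma^2)^{-1}$ — shrinks to zero as a
cluster accumulates weight, and grows to the prior $\sigma_\gamma^2$ for an
empty cluster; `conditional_variance()` exposes it directly. The smearing
variants replace the parametric error factor with the empirical mean of
exponentiated residuals (globally, or per cluster), which is robust to
non-normal errors; both retain the parametric $e^{v_i/2}$ factor for the
random intercept. With unit weights the heteroscedastic formulas reduce
exactly (bit-for-bit in this implementation) to their homoscedastic
special cases. For ordinary regression without random effects,
`ols_log_correction()` and `duan_smearing()` provide the same two routes.

Every prediction is returned together with its factor decomposition
(`eta`, `re_factor`, `err_factor`), so
`pred == exp(eta) * re_factor * err_factor` holds exactly and the
contribution of each correction is inspectable.

## Fitting

`fit_rim()` maximizes the Gaussian likelihood of
$\log \mathbf{y} \sim N(X\beta,\,V)$ with block-diagonal
$V_i = \sigma_\gamma^2 \mathbf{1}\mathbf{1}' + \sigma^2\,\mathrm{diag}(w_i^{-1})$.
Design choices, made once:

* **Parametrization and algorithm.** The objective is profiled over
  $\beta$ (GLS at each candidate) and optimized over
  $(\log\sigma^2, \log\sigma_\gamma^2)$ by L-BFGS-B, with a coarse-grid +
  Nelder-Mead restart if the first attempt fails. The log parametrization
  enforces positivity without constraints; a floor of $10^{-10}$ on both
  variances handles the boundary, and an estimate at the floor is flagged
  `"boundary"`.
* **REML by default, ML by flag.** REML variance estimates are less biased,
  and every correction formula takes the variances as inputs regardless of
  how they were estimated. The boundary likelihood-ratio test
  (`lrt_random_effect()`) forces ML on both sides so the two likelihoods
  are comparable, and halves the $\chi^2_1$ tail because the null pins
  $\sigma_\gamma^2$ to the boundary of its space.
* **$O(n)$ algebra.** All per-cluster computations use the rank-one
  Woodbury identity (the BLUP reduces to the scalar shrinkage
  $\hat\gamma_i = \sigma_\gamma^2 \sum_j w_{ij} r_{ij} /
  (\sigma_\gamma^2 \sum_j w_{ij} + \sigma^2)$); dense $n_i^3$ inversion
  exists only as a test oracle.
* **No degrees-of-freedom correction** is applied inside the correction
  factors; $\hat\sigma^2$ follows the fit method.
* **New clusters.** Predicting for a cluster unseen at fit time uses
  $\hat\gamma = 0$ with the full prior variance $\sigma_\gamma^2$ in the
  random-effect factor — the coherent out-of-sample extension of the
  marginal logic — and is reported via a message.

```{r}
cfg <- scenario_config(m = 50, n_i = 10, seed = 7)
d <- generate_lognormal(cfg, replicate = 1)
fit <- fit_rim(d)
fit
head(predict_rim(fit, method = "conditional"), 3)
```

## General linear mixed models and other transformations

With $q$ random effects per cluster ($\log \mathbf{Y} = X\beta + U\gamma +
\epsilon$, $\gamma_i \sim N_q(0, D)$), the conditional covariance is

$$\mathrm{Var}(\gamma_i \mid \log\mathbf{Y}) =
D - D U_i' (U_i D U_i' + \Sigma_i)^{-1} U_i D,$$

and the corrected predictor multiplies the naive value by
$\exp(\tfrac12 \mathbf{u}_{ij}' \mathrm{Var}(\gamma_i\mid\log\mathbf{Y})
\mathbf{u}_{ij})$ and the error factor (`conditional_cov_lmm()`,
`predict_lmm()`). Estimation of $(D, \sigma^2)$ for general designs is
deliberately delegated to established mixed-model software —
`as_lmm_components()` adapts `lme4::lmer` fits (single grouping factor) and
the package's own RIM fits — while the corrections are always computed
here. The multivariate BLUP
$D U_i'(U_i D U_i' + \Sigma_i)^{-1}(\log y_i - X_i\hat\beta)$ is used where
BLUPs are not supplied.

For an invertible transformation $g$ other than the logarithm (e.g. Box-Cox
with user-supplied $\lambda$; $\lambda$ *estimation* is out of scope),
closed forms are generally unavailable and `mc_backtransform()` averages
$g^{-1}(\mathbf{x}'\hat\beta + z_l + e_l)$ over draws
$z_l \sim N(\mathbf{u}'\hat\gamma_i,\,
\mathbf{u}'\mathrm{Var}(\gamma_i\mid g(\mathbf{Y}))\mathbf{u})$. The error
term is handled by flag: drawn from its fitted law (default), fixed at the
fitted residual, or zero. The default is the one mode that reproduces the
closed-form predictor when $g = \exp$, which makes it verifiable; the other
two are exposed because either convention is defensible and the choice is
genuinely open. Draws are seed-reproducible, a per-observation Monte-Carlo
standard error is attached, and observations whose draws leave the domain
of $g^{-1}$ (e.g. a Box-Cox inverse of a negative argument) are flagged
undefined rather than silently averaged.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the reference simulation design so that the MSE
study is a meaningful validation:

* `generate_lognormal()`: $p = 3$ with intercept, covariates i.i.d.
  $U(0,1)$ redrawn each replicate (a fixed-X variant is available by flag),
  $\beta = (0.8, 1.3, -0.7)'$, deterministic weights
  $w_{ij} = (i+1)/10 + j/1000$, $\sigma^2, \sigma_\gamma^2 \in \{0.2,
  0.4\}$; balanced designs $m \in \{50, 100\} \times n_i \in \{10, 20\}$
  and unbalanced designs with consecutive sizes $n_i = 10 + i$
  ($11..50$ with $m = 40$; $11..90$ with $m = 80$) — consecutive assignment
  is the only one consistent with both the size sets and the cluster
  counts.
* `generate_gamma()`: $Y_{ij} \sim \text{Gamma}(\text{shape} = \alpha
  w_{ij},\ \text{scale} = \exp(\mathbf{x}'\beta + \gamma_i)/(\alpha
  w_{ij}))$, $\alpha \in \{1, 1.5, 5\}$, so $E[Y_{ij}\mid\gamma_i] =
  \exp(\mathbf{x}'\beta + \gamma_i)$ exactly — a misspecification probe for
  the log-normal machinery (large $\alpha$ approaches log-normal-like
  behaviour; $\alpha = 1$ is exponential and genuinely far from it).
* `generate_mimic()`: an income-survey-like configuration — 2000
  observations in 20 clusters of sizes $58 + 4i$ (sum exactly 2000), an
  intercept near 9 so responses live on a currency-like scale, an integer
  count covariate (1..15) and a $U(0,1)$ covariate, with weights equal to
  the cluster size or to the count covariate (shifted to $\ge 0.1$ if
  needed). The error and random-intercept standard deviations default to
  0.594 and 0.079. This scenario is parameter-compatible with the survey
  application it gestures at, not a numerical replica of it.

Seeding: every replicate's seed is derived from the master seed by a fixed
rule (`set.seed(master)` then `sample.int`), so any single table cell can be
regenerated in isolation, in any order, bit-for-bit.

What passing tests on these generators do **not** show: real clustered
income data have categorical covariates, informative sampling, outliers and
weights that are at best estimated, none of which the generators emulate.
The study demonstrates correctness of the correction algebra and its
behaviour under the stated designs, not robustness to survey reality.

## The MSE study

`run_study()` runs the full loop — generate, fit the log-scale RIM
(regardless of the generating family), predict under every requested
method, score $\text{MSE} = \tfrac1n \sum_{ij} (Y_{ij} - \hat E[Y_{ij}])^2$
against the generated response — and reports the mean and standard
deviation of the per-replicate MSE for each scenario. Replicates whose fit
fails are dropped and counted, never imputed. Note that the
per-observation ordering naive $\le$ error-only $\le$ conditional is a
statement about predictions, not about MSE: the harness asserts nothing
about the ordering of the aggregated cells. A gamma-GLMM comparison
baseline is deliberately not part of the harness: fitting gamma GLMMs by
PQL/Laplace is standard-software territory and not part of this package's
contribution.

At the reference conditions the study uses 100 replicates per scenario; the
largest scenario (80 clusters, 4040 observations) completes in seconds
thanks to the $O(n)$ profile likelihood.

```{r}
run_study(scenario_config(m = 50, n_i = 10), reps = 20, seed = 1,
          methods = c("naive", "conditional"))
```

## Numerical notes and limitations

* Variance floor $10^{-10}$; boundary fits are flagged, not errors.
  Degenerate responses (exact linear function of $X$) drive
  $\hat\sigma^2$ to the floor and are flagged the same way.
* `conditional_variance()` is monotone decreasing in the weight mass and
  bounded by $[0, \sigma_\gamma^2]$; both closed forms (shrinkage and
  precision) agree to $10^{-10}$ and the package uses the shrinkage form.
* Ties/degeneracies: clusters with a single observation are fine
  (identifiability of $\sigma_\gamma^2$ is then joint, not per-cluster);
  rank-deficient designs are refused at fit time.
* Out of scope: crossed random effects, serial correlation within clusters,
  estimated variance functions (weights are known inputs), prediction
  intervals, closed-form Box-Cox moments for $\lambda \ne 0$, and two-part
  models.
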