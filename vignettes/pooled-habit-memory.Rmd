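---
title: "Pooled seasonal autoregression for daily habit panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled seasonal autoregression for daily habit panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memlag)
```

## The problem

Daily self-recorded counts of a habitual behavior — the motivating case is
cigarettes smoked per day by a few dozen smokers over roughly three months —
form a panel of short time series. Two questions drive the analysis:

1. **How long is the habit's memory?** That is, up to what lag does past
   behavior still predict today's count? In time-series terms, what is the
   order of the autoregressive (AR) process?
2. **Does the weekly routine shape the behavior?** Day-of-week effects are
   modeled with Sunday as the reference day.

Per-subject ("univariate") fits of series this short have little power, so
the series are *pooled*: one model, estimated on all subjects' days jointly.
Pooling requires confronting two sources of heterogeneity — subjects differ
strongly in both level and dispersion — which the package handles with a
per-subject rescaling and a lag structure that absorbs levels.

## The model

Let $Y_{t,j}$ be the count for subject $j$ on day $t$. Each subject is first
rescaled by their own sample standard deviation $s_j$ (computed over all
non-missing days):

$$Y^H_{t,j} = Y_{t,j} / s_j,$$

so every subject has within-subject sample variance exactly 1 (the
"homoscedastic" scale; `homoscedastic_transform()`). Values are *not*
mean-centered: level differences persist and are absorbed by the lag terms,
which is what allows a single pooled intercept.

The accepted model (called **M2** in the ladder below) is the pooled
regression

$$Y^H_{t,j} = b_0 + \sum_{k \in K} b_k\, Y^H_{t-k,j}
  + \sum_{d=\mathrm{Mon}}^{\mathrm{Sat}} \beta_d D_{d,t} + e_{t,j},$$

with lag set $K = \{1, 2\} \cup \{7, 14, \ldots, 56\}$ (two short-range lags
plus eight weekly multiples; `lag_spec()`) and six Sunday-reference weekday
dummies. Estimation is Gaussian maximum likelihood of the joint mean and
covariance structure of (response, lag block), with the dummies treated as
fixed regressors, under three families of constraints (`constraint_spec()`):

* **order** — within each chain the coefficients are non-negative and weakly
  decreasing: $b_1 \ge b_2 \ge 0$ and $b_7 \ge b_{14} \ge \cdots \ge b_{56}
  \ge 0$. More remote days never predict more strongly. Implemented by
  reparameterizing each chain as cumulative sums of non-negative increments
  and solving the resulting quadratic program exactly with an active-set
  iteration (no interior-point machinery, no tolerance tuning). Active
  increments (ties in the chain) are reported in the fit's
  `constraint_activity` table.
* **var_equal** — the lag columns are the same variable at different delays,
  so their variances are constrained equal.
* **cov_distance** — covariances between lag columns depend only on the
  distance in days between them (a Toeplitz-by-distance block). Together
  with `var_equal` this is the second-moment signature of stationarity.

With every constraint off, the estimates equal ordinary least squares (the
test suite asserts agreement to 1e-8) and the lag-block covariance is
saturated.

### The model ladder

* **M1** (`m1_spec()`): the full multilevel hypothesis — random intercept and
  random lag-1/lag-7 slopes across subjects, plus subject-constant gender and
  age terms. Fitted by ML through `lme4`. Non-convergence or a boundary
  (singular) random-effect variance is a *reported outcome* — the fit is
  flagged as degenerate, "collapsing to the fixed model" — not an exception.
* **M2** (`m2_spec()`): intercept + constrained lags + weekday dummies.
* **M3** (`m3_spec()`): intercept + constrained lags only. Comparing M3 to M2
  by the nested $\chi^2$ difference tests the overall weekday factor.
* **M0** (`m0_spec()`): the zero-covariance null (all variables mutually
  independent), the baseline for incremental fit indices.

### Fit indices and degrees of freedom

`fit_indices()` computes $\chi^2 = 2(\ell_{sat} - \ell_{model})$ against the
saturated model of the same family (`saturated_model()`), RMSEA with a 90% CI
by inverting the noncentral $\chi^2$ distribution, CFI and TLI against M0,
SRMR over the unique elements of the joint (response, lags) covariance, and
AIC. Degrees of freedom are counted as *free parameters of the saturated
family minus free parameters of the model*, where the family is the
conditional regression (mean coefficients + residual variance) plus the
lag-block moment structure (means, variances, covariances). Inequality
constraints do not reduce the count. This accounting is internally
consistent for nested comparisons, but it is deliberately **not** the
bookkeeping of SEM packages that parameterize every observed moment
(including the dummy block); df values from such software are therefore not
comparable and are not reproduced.

A related convention: the zero-covariance M0 is accepted as "restricted"
in `nested_chi2_test()` by convention, although a free-variance diagonal
block is not strictly a submodel of the equal-variance Toeplitz block.

### Inference conventions

Standard errors come from the observed information of the unconstrained
parameterization evaluated at the constrained solution, mapped back through
the (linear, invertible) chain map — which coincides with the usual
regression covariance at the solution. No polyhedral (constraint-adjusted)
inference is attempted. p-values are one-tailed for the sign-constrained lag
terms and two-tailed for the intercept, weekday and level-2 terms.
Standardized estimates are raw estimates times SD(predictor)/SD(response) on
the analysis sample.

## Correlograms and the memory span

`pooled_acf()` sums within-subject demeaned cross-products across subjects
and normalizes by the pooled lag-0 sum of squares; products never cross a
subject boundary, and missing days drop only the pairs they touch.
`pooled_pacf()` applies the Durbin–Levinson recursion to the pooled ACF.
The significance band is the white-noise approximation
$\pm z_{.975}/\sqrt{N_{\mathrm{eff}}(k)}$ with $N_{\mathrm{eff}}(k)$ the
number of valid pairs at lag $k$.

Two subtleties matter for reading a span off the correlogram:

* For a persistent AR process the ACF never cuts off, so the *order* is read
  from the PACF, which drops to zero beyond the true maximal lag.
* Within-subject demeaning subtracts the variance of each subject's sample
  mean from *every* autocovariance. The demeaned sequence is then not an
  exact AR ACF: its true PACF at lags just beyond the order is slightly
  **negative** (for the default near-integrated configuration, about
  $-0.01$ at lags 57–63), and at large pooled sample sizes a two-sided scan
  flags this artifact as "structure". Habit memory, by contrast, is positive
  dependence — the model constrains the lag coefficients to be non-negative
  and tests them one-tailed. The memory span is therefore scanned with
  `significant_lag_span(pacf, sign = "positive")`; the two-sided textbook
  scan remains the default of the function and both are reported by
  `run_full_analysis()`.

## Residual diagnostics

`diagnose_residuals()` requires the accepted model's residuals to be normal
and serially uncorrelated ("white noise"):

* **Normality.** One-sample KS statistic against a normal with the
  residuals' own mean and SD. Because those parameters are estimated, the
  primary p-value is Lilliefors-corrected; the naive fully-specified p-value
  is reported alongside.
* **Whiteness.** A pooled Ljung–Box statistic
  $Q = N(N+2)\sum_k r_k^2 / N_{\mathrm{eff}}(k)$ on the pooled residual
  autocorrelations, which reduces exactly to the textbook statistic for a
  single complete series. Residual autocorrelations are pooled with a single
  *global* demeaning: the regression already centers the residuals, and
  per-subject demeaning would re-introduce the negative small-sample
  artifact described above (the test suite calibrates the type-I error to
  5% under the null). The default lag count is three weekly seasons
  (3 × 7 = 21), and `df = n_lags` with no correction for fitted parameters;
  the corrected variant is available behind `fit_df_correction`.

## The synthetic generator

`simulate_panel()` inverts the fitted model into a generator so that every
stage is testable without access to the original records. Per subject it
draws a record length (mode 84 days, range 69–91), a start weekday, a latent
stationary level, and a log-normal raw scale $s_j$; runs the latent
recursion $y_t = a_j + \sum_k b_k y_{t-k} + \omega_{d(t)} + \varepsilon_t$
over a discarded 200-day burn-in (more than three times the longest lag);
multiplies by $s_j$; optionally rounds to non-negative integers; and deletes
days completely at random. The subject intercept $a_j$ is solved so the
latent stationary mean equals the drawn level.

Default parameters (`default_sim_config()`) are the published pooled
estimates: AR coefficients at lags 1–56, weekday effects with Sunday
reference, 62 subjects, 1.08% missingness. Two quantities the study does not
print are chosen as follows:

* **Innovation variance** (`innovation_sd = "auto"`): solved analytically so
  the latent within-subject stationary variance is 1, consistent with the
  unit-variance homoscedastic scale. The stationary variance decomposes into
  the deterministic weekly-cycle part (the periodic steady state of the
  recursion, obtained from a 7-day circulant system) and the AR-driven part
  (from the Yule–Walker equations); the innovation SD is the value that
  makes the sum 1.
* **Between-subject level spread**: the latent levels are drawn from a
  normal with mean 4.546 and variance 1.253, i.e. the arithmetic reading of
  "within variance 1 + between variance = total variance 2.253".

### What the generator does and does not emulate

The published AR coefficients sum to 0.984, with a characteristic root at
1.001 — an *almost integrated* process whose time constant (hundreds of
days) far exceeds an 84-day record. This has consequences a user should
know:

* A subject's 84-day sample mean wanders far from its stationary level, and
  the 84-day sample variance is well below the stationary variance. After
  the per-subject rescaling, the realized pooled variance and grand mean of
  simulated panels therefore overshoot the printed study values; the printed
  total variance and the printed $R^2$ cannot both be reproduced by one
  stationary configuration, and the package targets the model-side
  quantities (coefficients, $R^2$, memory span), which parameter-recovery
  tests confirm.
* The same mechanism means the homoscedastic transform itself *creates*
  level dispersion when subjects share a large mean (each mean is divided by
  a different sample SD). Pooled lag coefficients absorb that dispersion —
  which is precisely why the pooled model needs no random intercept — so
  recovery oracles that want the pure AR coefficient use mean-zero panels.
* The steady-state weekly profile implied by the printed weekday effects has
  its minimum midweek and maximum on Sunday once the AR filter mixes
  adjacent days; the printed raw-scale weekday table (Monday minimum,
  Saturday maximum) is not exactly reproducible from the same parameters.
  Tests assert the contrasts that hold in both (early week below weekend).
* Missingness is completely at random; the study reports no mechanism.
* With rounding off (the default for estimation studies) values are
  continuous and may be slightly negative for low-level subjects — the
  fitted model is linear-Gaussian and truncation would distort it. Rounding
  (`integerize = TRUE`) is a realism toggle for descriptive work.

## Validation protocol and problem sizes

The test suite exercises, among others: exact unit variance after the
transform; OLS equivalence at 1e-8; brute-force oracles for lag indexing,
weekday grouping, Levene sums of squares, ICC mean squares, the KS sup-gap
and single-series ACF/PACF/Ljung–Box; $\chi^2$-difference calibration under
a true restricted model; and parameter recovery at study scale. The
simulation sizes are the package's validation choices: 50 seeds of
62-subject panels for coefficient bias (each within 0.02 absolute) and
$R^2$ concentration; one 200 × 200 panel for the memory-span scan; 1,000
null replicates for the 5% ± 2-point type-I calibration of the pooled
Ljung–Box and Levene tests. `scripts/acceptance.R` re-runs the headline
quantities from scratch at the same sizes.

## Known limitations

* No count-data (Poisson / negative binomial) generative variant; no
  moving-average or GARCH terms; no Bayesian estimation; no robust
  (sandwich) standard errors.
* The multilevel path delegates to `lme4`'s single default optimizer start;
  a reported non-convergence there is evidence, not proof, that the
  multilevel parameterization is unsupported by the data.
* ICC is the one-way random-effects variant only (days nested in subjects);
  no two-way or absolute-agreement families.
* Missing values are never imputed anywhere in the pipeline; listwise
  deletion in the lag design is the only treatment.
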