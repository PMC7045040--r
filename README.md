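# memlag

Pooled (panel) time-series analysis of daily behavior counts — the
motivating application is daily smoking diaries — built around one idea:
habitual behavior has a measurable **memory**, the largest lag at which past
behavior still predicts today's, and that memory can be estimated with far
more power by pooling many subjects' short series into one model than by
fitting each series alone.

The package is for researchers analyzing intensive longitudinal count data
(daily diaries of smoking, drinking, exercise, medication use) who want a
reproducible pipeline from raw long- or wide-format records to a fitted,
diagnosed seasonal autoregressive model.

## The model

Counts are first made comparable across subjects by dividing each subject's
series by its own standard deviation, `Y^H_{t,j} = Y_{t,j} / s_j`, so every
subject has within-subject variance 1. The pooled model is then

    Y^H_t = b0 + b1 Y^H_{t-1} + b2 Y^H_{t-2}
          + b7 Y^H_{t-7} + b14 Y^H_{t-14} + ... + b56 Y^H_{t-56}
          + β_Mon D_Mon + ... + β_Sat D_Sat + e_t

— two short-range lags, eight weekly seasonal lags, and six day-of-week
dummies with Sunday as the reference — estimated by constrained Gaussian
maximum likelihood: the lag coefficients form non-negative, weakly
decreasing chains (`b1 ≥ b2 ≥ 0`, `b7 ≥ b14 ≥ ... ≥ b56 ≥ 0`), and the lag
block's covariance is constrained to equal variances with
distance-indexed (Toeplitz) covariances. Model comparison uses SEM-style fit
indices (χ², RMSEA, CFI, TLI, SRMR, AIC) and nested χ² difference tests; a
multilevel (random-coefficient) variant is attempted via `lme4` and its
non-convergence or degeneracy is reported as a result. Residuals must pass a
Lilliefors-corrected KS normality check and a pooled Ljung–Box white-noise
test over three weekly seasons (21 lags).

A synthetic panel generator (`simulate_panel()`) inverts the model into a
simulator with known ground truth, so the whole pipeline is testable by
parameter recovery. See the methods vignette
(`vignettes/pooled-habit-memory.Rmd`) for the estimation details, numerical
choices and known limitations.

## Worked example

```r
library(memlag)

panel <- simulate_panel(default_sim_config(), seed = 42)
summarize_panel(panel)
#> Panel: 62 subjects, 5152 subject-days (1.07% missing)
#> Record lengths 70-91, mode 84

hp     <- homoscedastic_transform(panel)
design <- build_lag_design(hp)          # lags 1,2,7,...,56 + weekday dummies
fit    <- fit_pooled(design, m2_spec()) # constrained ML
print(fit, digits = 3)
#> Pooled fit M2: n = 1506, loglik = -24073.62, params = 53, R2 = 0.847
#>       term estimate     se      t        p     std
#>  intercept   0.2175 0.1076  2.022 4.34e-02  0.0999
#>      d_mon  -0.5056 0.0933 -5.417 7.06e-08 -0.0817
#>      ...
#>      lag_1   0.2486 0.0235 10.578 1.44e-25  0.2456
#>      lag_7   0.1967 0.0247  7.954 1.77e-15  0.1928
#>      ...
```

The generating lag-1 and lag-7 coefficients (0.2468 and 0.1934) are
recovered within one standard error; `R2 = 0.847` says the lags plus weekday
profile explain most of the pooled variance (much of it between-subject
level differences absorbed by the lags — see the vignette). Fit indices and
diagnostics:

```r
m0 <- fit_pooled(design, m0_spec())     # zero-covariance baseline
fit_indices(fit, saturated_model(design), baseline = m0)
#> chi2(30) = 25.268, p = 0.712
#> RMSEA = 0.000 (0.000-0.015), SRMR = 0.010, CFI = 1.000, TLI = 1.000
#> AIC = 48253.248

diagnose_residuals(fit)
#> KS D = 0.0130, Lilliefors p = 0.778 -> normal
#> Ljung-Box Q(21) = 18.227, p = 0.635 -> white noise
```

The memory span is read from the pooled partial autocorrelations — positive
exceedances of the white-noise band, since memory means positive dependence.
On a large simulated panel (200 subjects × 200 days) the scan recovers the
generator's 56-day memory:

```r
big  <- { cfg <- default_sim_config()
          cfg$n_subjects <- 200L
          cfg$length_sampler <- list(values = 200L, mode = 200L, mode_mass = 1)
          cfg$missing_rate <- 0
          simulate_panel(cfg, seed = 42) }
significant_lag_span(pooled_pacf(homoscedastic_transform(big), 63),
                     sign = "positive")$span
#> [1] 56
```

`run_full_analysis(panel)` chains all stages (descriptives, correlograms,
the M0/M1/M2/M3 ladder, nested tests, diagnostics) into one report;
`write_report_json()` serializes it, and
`Rscript scripts/run_analysis.R --in panel.csv --out report.json` does the
same from the shell.

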