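unconstrained <- function(spec) {
  spec$constraints <- constraint_spec(FALSE, FALSE, FALSE)
  spec
}

test_that("with all constraints off the fit equals ordinary least squares to 1e-8", {
  p <- simulate_panel(default_sim_config(), seed = 31)
  d <- build_lag_design(homoscedastic_transform(p))
  fit <- fit_pooled(d, unconstrained(m2_spec()))
  cols <- c(paste0("d_", tolower(WEEKDAYS[1:6])), paste0("lag_", lag_spec()$lags))
  fml <- stats::as.formula(paste("y ~", paste(cols, collapse = " + ")))
  ref <- stats::lm(fml, data = as.data.frame(d))
  got <- stats::setNames(fit$terms$estimate, fit$terms$term)
  expect_lt(max(abs(got["intercept"] - stats::coef(ref)["(Intercept)"])), 1e-8)
  for (cn in cols) expect_lt(abs(got[cn] - stats::coef(ref)[cn]), 1e-8)
  # standard errors agree too
  se_ref <- summary(ref)$coefficients[, "Std. Error"]
  expect_equal(unname(stats::setNames(fit$terms$se, fit$terms$term)[cols]),
               unname(se_ref[cols]), tolerance = 1e-8)
  # standardized = raw * sd(x) / sd(y)
  i <- match("lag_1", fit$terms$term)
  expect_equal(fit$terms$std[i],
               fit$terms$estimate[i] * stats::sd(d$lag_1) / stats::sd(d$y),
               tolerance = 1e-12)
})

test_that("order constraints produce ordered non-negative chains and never raise the likelihood", {
  p <- simulate_panel(default_sim_config(), seed = 32)
  d <- build_lag_design(homoscedastic_transform(p))
  con <- fit_pooled(d, m2_spec())
  unc <- fit_pooled(d, unconstrained(m2_spec()))
  b <- stats::setNames(con$terms$estimate, con$terms$term)
  expect_gte(b["lag_1"], b["lag_2"])
  expect_gte(b["lag_2"], 0)
  seas <- b[paste0("lag_", 7 * (1:8))]
  expect_true(all(diff(seas) <= 1e-12))
  expect_gte(min(seas), 0)
  expect_lte(con$loglik_cond, unc$loglik_cond + 1e-8)
  # constraint activity is reported
  expect_s3_class(con$constraint_activity, "data.frame")
  expect_true(any(con$constraint_activity$active))
})

test_that("an inactive order constraint reproduces the unconstrained solution", {
  # well-separated coefficients: OLS already satisfies the chain
  set.seed(41)
  n <- 4000
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  y <- 0.9 * x1 + 0.2 * x2 + stats::rnorm(n, 0, 0.5)
  d <- as_lag_design(data.frame(y = y, lag_1 = x1, lag_2 = x2),
                     lag_spec(nonseasonal = 1:2, multiples = 0))
  spec <- model_spec("toy", lag_spec(nonseasonal = 1:2, multiples = 0),
                     weekday = FALSE,
                     constraints = constraint_spec(TRUE, FALSE, FALSE))
  con <- fit_pooled(d, spec)
  unc <- fit_pooled(d, unconstrained(spec))
  expect_equal(con$terms$estimate, unc$terms$estimate, tolerance = 1e-8)
})

test_that("coefficient recovery on a simulated AR(1) panel (least-squares oracle)", {
  p <- ar1_panel(n_subjects = 40L, n_days = 100L, phi = 0.5, seed = 43)
  d <- build_lag_design(homoscedastic_transform(p),
                        lag_spec(nonseasonal = 1L, multiples = 0))
  spec <- model_spec("ar1", lag_spec(nonseasonal = 1L, multiples = 0),
                     weekday = FALSE,
                     constraints = constraint_spec(FALSE, FALSE, FALSE))
  fit <- fit_pooled(d, spec)
  i <- match("lag_1", fit$terms$term)
  expect_lt(abs(fit$terms$estimate[i] - 0.5), 3 * fit$terms$se[i] + 0.02)
})

test_that("rank deficiency is reported with the collinear column names", {
  set.seed(44)
  x <- stats::rnorm(200)
  d <- as_lag_design(data.frame(y = stats::rnorm(200), lag_1 = x, lag_2 = x),
                     lag_spec(nonseasonal = 1:2, multiples = 0))
  spec <- model_spec("bad", lag_spec(nonseasonal = 1:2, multiples = 0),
                     weekday = FALSE)
  err <- expect_error(fit_pooled(d, spec), class = "memlag_rank_deficient")
  expect_match(conditionMessage(err), "lag_2")
})

test_that("fit indices hit their boundary identities", {
  p <- simulate_panel(default_sim_config(), seed = 33)
  d <- build_lag_design(homoscedastic_transform(p))
  sat <- saturated_model(d)
  m0 <- fit_pooled(d, m0_spec())
  satfit <- fit_pooled(d, unconstrained(m2_spec()))

  idx_sat <- fit_indices(satfit, sat, baseline = m0)
  expect_equal(idx_sat$chisq, 0, tolerance = 1e-6)
  expect_equal(idx_sat$df, 0)
  expect_false(idx_sat$defined)
  expect_equal(idx_sat$cfi, 1)

  idx_null <- fit_indices(m0, sat, baseline = m0)
  expect_equal(idx_null$cfi, 0)
  expect_gt(idx_null$srmr, 0.2)  # pooled lags are strongly correlated

  idx_m2 <- fit_indices(fit_pooled(d, m2_spec()), sat, baseline = m0)
  expect_true(idx_m2$defined)
  expect_gt(idx_m2$cfi, 0.9)
  expect_lt(idx_m2$rmsea, 0.08)
  expect_true(idx_m2$rmsea >= idx_m2$rmsea_ci[1] - 1e-12 &&
                idx_m2$rmsea <= idx_m2$rmsea_ci[2] + 1e-12)
})

test_that("structured-covariance indices match a direct discrepancy oracle (3-variable toy)", {
  set.seed(45)
  n <- 600
  x1 <- stats::rnorm(n)
  x2 <- 0.5 * x1 + stats::rnorm(n, 0, sqrt(0.75))
  y <- 0.4 * x1 + 0.3 * x2 + stats::rnorm(n, 0, 0.8)
  ls <- lag_spec(nonseasonal = 1:2, multiples = 0)
  d <- as_lag_design(data.frame(y = y, lag_1 = x1, lag_2 = x2), ls)
  spec <- model_spec("toy", ls, weekday = FALSE,
                     constraints = constraint_spec(FALSE, TRUE, FALSE))
  fit <- fit_pooled(d, spec)
  sat <- saturated_model(d, spec)
  got <- fit_indices(fit, sat)

  # oracle: minimize the ML discrepancy log|Sigma| + tr(S Sigma^-1) over the
  # two free moments (common variance v, covariance c) by direct search
  X <- cbind(x1, x2)
  S <- crossprod(sweep(X, 2, colMeans(X))) / n
  f <- function(par) {
    Sigma <- matrix(c(par[1], par[2], par[2], par[1]), 2)
    if (par[1] <= abs(par[2])) return(1e10)
    log(det(Sigma)) + sum(diag(S %*% solve(Sigma)))
  }
  opt <- stats::optim(c(mean(diag(S)), S[1, 2]), f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  chisq_oracle <- n * (opt$value - (log(det(S)) + 2))
  expect_equal(got$chisq, chisq_oracle, tolerance = 1e-3)
  expect_equal(got$df, 1L)  # one variance equality
})

test_that("nested chi-square tests behave and refuse mismatched rows", {
  p <- simulate_panel(default_sim_config(), seed = 34)
  d <- build_lag_design(homoscedastic_transform(p))
  m2 <- fit_pooled(d, m2_spec())
  m3 <- fit_pooled(d, m3_spec())
  m0 <- fit_pooled(d, m0_spec())

  same <- nested_chi2_test(m2, m2)
  expect_equal(same$delta_chisq, 0)
  expect_equal(same$delta_df, 0L)

  nt <- nested_chi2_test(m3, m2)
  expect_equal(nt$delta_df, 6L)  # the six weekday dummies
  expect_gt(nt$delta_chisq, 0)
  expect_lt(nt$p, 0.001)

  n0 <- nested_chi2_test(m0, m2)
  expect_gt(n0$delta_chisq, nt$delta_chisq)

  p2 <- simulate_panel(default_sim_config(), seed = 35)
  d2 <- build_lag_design(homoscedastic_transform(p2))
  m2b <- fit_pooled(d2, m2_spec())
  expect_error(nested_chi2_test(m3, m2b), class = "memlag_not_nested")
  expect_error(nested_chi2_test(m2, m3), class = "memlag_not_nested")
})

test_that("chi-square differences under a true restricted model are calibrated", {
  # restricted truth: no weekday effects; compare M3 (true) against M2
  deltas <- vapply(1:60, function(s) {
    cfg <- sim_config(n_subjects = 25L,
                      length_sampler = list(values = 40L, mode = 40L, mode_mass = 1),
                      ar = c(`1` = 0.4), innovation_sd = "auto", burn_in = 60L)
    p <- simulate_panel(cfg, seed = 300 + s)
    ls <- lag_spec(nonseasonal = 1L, multiples = 0)
    d <- build_lag_design(homoscedastic_transform(p), ls)
    cs <- constraint_spec(FALSE, FALSE, FALSE)
    m_full <- fit_pooled(d, model_spec("full", ls, weekday = TRUE, constraints = cs))
    m_rest <- fit_pooled(d, model_spec("rest", ls, weekday = FALSE, constraints = cs))
    nested_chi2_test(m_rest, m_full)$delta_chisq
  }, numeric(1))
  # Delta-chi2 should behave like chi2 with df 6: mean near 6, and the
  # empirical quantiles should not be grossly off
  expect_lt(abs(mean(deltas) - 6), 2)
  expect_lt(mean(deltas > stats::qchisq(0.95, 6)), 0.2)
  expect_gt(mean(deltas > stats::qchisq(0.5, 6)), 0.25)
})

test_that("multilevel path recovers a true random intercept and flags degeneracy", {
  set.seed(50)
  n_subj <- 40L; n_per <- 30L
  a <- stats::rnorm(n_subj, 0, 0.5)
  rows <- do.call(rbind, lapply(seq_len(n_subj), function(j) {
    x <- stats::rnorm(n_per)
    data.frame(subject_id = sprintf("S%02d", j), t = seq_len(n_per),
               y = 1 + a[j] + 0.3 * x + stats::rnorm(n_per, 0, 1), lag_1 = x)
  }))
  ls <- lag_spec(nonseasonal = 1L, multiples = 0)
  d <- as_lag_design(rows, ls)
  spec <- model_spec("ml", ls, weekday = FALSE, random = "intercept")
  fit <- fit_multilevel(d, spec)
  expect_true(fit$converged)
  sd_hat <- fit$varcorr$sdcor[fit$varcorr$grp == "subject_id" &
                                fit$varcorr$var1 == "(Intercept)" &
                                is.na(fit$varcorr$var2)]
  expect_lt(abs(sd_hat - 0.5), 0.2)
  i <- match("lag_1", fit$fixef$term)
  expect_lt(abs(fit$fixef$estimate[i] - 0.3), 0.1)

  # no true random slope: the slope variance collapses to the boundary
  spec2 <- model_spec("ml2", ls, weekday = FALSE, random = c("intercept", "lag_1"))
  fit2 <- fit_multilevel(d, spec2)
  sd_slope <- fit2$varcorr$sdcor[fit2$varcorr$var1 == "lag_1" &
                                   is.na(fit2$varcorr$var2)]
  expect_true(fit2$degenerate || sd_slope < 0.1)

  one <- as_lag_design(rows[rows$subject_id == "S01", ], ls)
  expect_error(fit_multilevel(one, spec), class = "memlag_bad_groups")
})
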