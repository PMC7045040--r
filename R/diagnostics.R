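#' Kolmogorov-Smirnov residual normality check
#'
#' One-sample KS statistic against a normal distribution with the residuals'
#' own mean and SD. Because the parameters are estimated, the primary
#' p-value is Lilliefors-corrected (`nortest::lillie.test`); the naive
#' fully-specified p-value is reported alongside for reference.
#'
#' @param residuals Numeric vector, at least 8 values.
#' @return List with `D`, `p` (Lilliefors), `p_naive`, `n`.
#' @export
ks_normality <- function(residuals) {
  residuals <- residuals[!is.na(residuals)]
  if (length(residuals) < 8L) {
    stop_memlag("need at least 8 residuals", "memlag_too_few_rows")
  }
  s <- stats::sd(residuals)
  if (s == 0) {
    stop_memlag("zero-variance residuals", "memlag_degenerate_series")
  }
  naive <- suppressWarnings(
    stats::ks.test(residuals, "pnorm", mean(residuals), s))
  lil <- nortest::lillie.test(residuals)
  list(D = unname(lil$statistic), p = unname(lil$p.value),
       p_naive = unname(naive$p.value), n = length(residuals))
}

#' Pooled Ljung-Box white-noise test
#'
#' Portmanteau statistic on the pooled residual autocorrelations,
#' Q = N (N + 2) * sum_k r_k^2 / N_eff(k), where N is the total number of
#' residuals and N_eff(k) the number of valid within-subject pairs at lag k
#' (for a single complete series this is the textbook Ljung-Box statistic).
#' Autocorrelations are pooled within subject — products never cross subject
#' boundaries — with a single global demeaning, so a concatenated-series
#' artifact cannot manufacture spurious lags.
#'
#' By default `df = n_lags` with no correction for fitted parameters
#' (matching the three-seasons convention of 21 lags, df 21);
#' `fit_df_correction` subtracts the number of autoregressive terms.
#'
#' @param x A `memlag_fit`, or a data frame with `subject_id`, `t` and a
#'   residual column named `resid`.
#' @param n_lags Number of lags; default `seasons * period`.
#' @param seasons,period The default lag count is three weekly seasons
#'   (3 x 7 = 21).
#' @param fit_df_correction Subtract the fitted AR term count from df.
#' @param n_ar Number of AR terms for the correction (taken from the fit
#'   when `x` is a `memlag_fit`).
#' @return List with `Q`, `df`, `p`, `n_lags`, `n`.
#' @export
ljung_box <- function(x, n_lags = NULL, seasons = 3L, period = 7L,
                      fit_df_correction = FALSE, n_ar = 0L) {
  if (inherits(x, "memlag_fit")) {
    n_ar <- length(x$spec$lags$lags)
    x <- x$residuals
  }
  if (is.null(n_lags)) n_lags <- seasons * period
  series <- panel_series(x, value_col = "resid")
  max_usable <- max(vapply(series, function(v) sum(!is.na(v)), numeric(1)))
  if (n_lags >= max_usable) {
    stop_memlag("n_lags is not smaller than the longest usable record",
                "memlag_lag_too_long")
  }
  core <- pooled_acf_core(series, n_lags, demean = "global")
  N <- core$n_total
  Q <- N * (N + 2) * sum(core$r^2 / core$n_eff)
  df <- n_lags - if (fit_df_correction) n_ar else 0L
  if (df <= 0) {
    stop_memlag("non-positive degrees of freedom after correction",
                "memlag_bad_spec")
  }
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       n_lags = n_lags, n = N)
}

#' Residual diagnostics report
#'
#' Normality (KS/Lilliefors) and white-noise (pooled Ljung-Box) checks plus
#' the pooled residual correlogram, with verdict flags at `alpha`.
#'
#' @param fit A `memlag_fit`.
#' @param n_lags Ljung-Box lag count (default 21 = three weekly seasons).
#' @param alpha Verdict threshold.
#' @return A `diagnostics_report` list with `ks`, `ljung_box`, `acf`,
#'   `normal`, `white_noise`.
#' @export
diagnose_residuals <- function(fit, n_lags = 21L, alpha = 0.05) {
  stopifnot(inherits(fit, "memlag_fit"))
  ks <- ks_normality(fit$residuals$resid)
  lb <- ljung_box(fit, n_lags = n_lags)
  acf_res <- pooled_acf(fit$residuals, max_lag = n_lags, demean = "global",
                        value_col = "resid")
  structure(list(ks = ks, ljung_box = lb, acf = acf_res,
                 normal = ks$p > alpha, white_noise = lb$p > alpha,
                 alpha = alpha),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("KS D = %.4f, Lilliefors p = %.3f -> %s\n",
              x$ks$D, x$ks$p, if (x$normal) "normal" else "non-normal"))
  cat(sprintf("Ljung-Box Q(%d) = %.3f, p = %.3f -> %s\n",
              x$ljung_box$df, x$ljung_box$Q, x$ljung_box$p,
              if (x$white_noise) "white noise" else "autocorrelated"))
  invisible(x)
}
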