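#' Run the full pooled analysis sequence on a panel
#'
#' Orchestrates the canonical sequence: panel summary -> descriptives ->
#' homoscedastic transform -> pooled correlograms and lag-span scan ->
#' model ladder (multilevel M1 attempt, fixed M2, lags-only M3,
#' zero-covariance M0) -> nested chi-square tests -> residual diagnostics
#' on the accepted model. Non-convergence of the multilevel attempt is a
#' reported outcome, not an error. Deterministic given the input panel.
#'
#' @param panel A `panel_dataset`.
#' @param lags A [lag_spec()].
#' @param max_lag Correlogram depth (default 63 = nine weekly seasons).
#' @param lb_lags Ljung-Box lag count (default 21).
#' @param alpha Significance level for verdicts.
#' @param attempt_multilevel Attempt the random-coefficient M1 first.
#' @return A `memlag_report` list; see [write_report_json()].
#' @export
run_full_analysis <- function(panel, lags = lag_spec(), max_lag = 63L,
                              lb_lags = 21L, alpha = 0.05,
                              attempt_multilevel = TRUE) {
  summary_ <- summarize_panel(panel)
  descriptives <- describe_panel(panel)
  hp <- homoscedastic_transform(panel)
  acf_ <- pooled_acf(hp, max_lag)
  pacf_ <- pooled_pacf(hp, max_lag)
  span <- list(acf = significant_lag_span(acf_),
               pacf = significant_lag_span(pacf_),
               memory = significant_lag_span(pacf_, sign = "positive"))
  design <- build_lag_design(hp, lags)

  sat <- saturated_model(design, m2_spec(lags))
  m0 <- fit_pooled(design, m0_spec(lags))
  m2 <- fit_pooled(design, m2_spec(lags))
  m3 <- fit_pooled(design, m3_spec(lags))
  meta <- attr(panel, "subjects")
  level2 <- intersect(c("gender", "age"), names(meta))
  m1 <- if (attempt_multilevel) {
    fit_multilevel(design, m1_spec(lags, level2 = level2))
  } else NULL

  idx_m2 <- fit_indices(m2, sat, baseline = m0)
  idx_m3 <- fit_indices(m3, sat, baseline = m0)
  idx_m0 <- fit_indices(m0, sat, baseline = m0)
  nested <- list(m3_in_m2 = nested_chi2_test(m3, m2),
                 m0_vs_m2 = nested_chi2_test(m0, m2))
  diag_m2 <- diagnose_residuals(m2, n_lags = lb_lags, alpha = alpha)

  criteria <- list(
    overall_fit = isTRUE(idx_m2$rmsea < 0.08 && idx_m2$srmr < 0.08),
    terms_significant = all(m2$terms$p < alpha),
    aic_prefers_m2 = isTRUE(m2$AIC < m3$AIC),
    residuals_ok = isTRUE(diag_m2$normal && diag_m2$white_noise)
  )
  chosen <- if (criteria$aic_prefers_m2) "M2" else "M3"

  structure(list(
    summary = summary_,
    descriptives = descriptives,
    correlogram = list(acf = acf_, pacf = pacf_, span = span),
    design_dropped = attr(design, "dropped"),
    fits = list(M1 = m1, M2 = m2, M3 = m3, M0 = m0),
    indices = list(M2 = idx_m2, M3 = idx_m3, M0 = idx_m0),
    nested = nested,
    diagnostics = diag_m2,
    criteria = criteria,
    chosen_model = chosen
  ), class = "memlag_report")
}

#' Serialize an analysis report to JSON
#'
#' Self-contained machine-readable report; every number traces to a module
#' output. Model objects are reduced to their tables and scalars.
#'
#' @param report A `memlag_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  slim_fit <- function(f) {
    if (is.null(f)) return(NULL)
    if (inherits(f, "memlag_mlfit")) {
      return(list(name = f$spec$name, converged = f$converged,
                  singular = f$singular, degenerate = f$degenerate,
                  messages = f$messages, loglik = f$loglik, AIC = f$AIC,
                  fixef = f$fixef, varcorr = f$varcorr))
    }
    list(name = f$spec$name, n = f$n, loglik = f$loglik, n_par = f$n_par,
         AIC = f$AIC, R2 = f$R2, sigma2 = f$sigma2, terms = f$terms,
         constraint_activity = f$constraint_activity)
  }
  slim_idx <- function(i) unclass(i)
  out <- list(
    summary = unclass(report$summary),
    descriptives = unclass(report$descriptives),
    correlogram = list(
      acf = as.data.frame(report$correlogram$acf),
      pacf = as.data.frame(report$correlogram$pacf),
      span = report$correlogram$span),
    design_dropped = as.list(report$design_dropped),
    fits = lapply(report$fits, slim_fit),
    indices = lapply(report$indices, slim_idx),
    nested = report$nested,
    diagnostics = list(ks = report$diagnostics$ks,
                       ljung_box = report$diagnostics$ljung_box,
                       normal = report$diagnostics$normal,
                       white_noise = report$diagnostics$white_noise),
    criteria = report$criteria,
    chosen_model = report$chosen_model
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
print.memlag_report <- function(x, ...) {
  print(x$summary)
  cat(sprintf("Lag span: ACF %d, PACF %d\n",
              x$correlogram$span$acf$span, x$correlogram$span$pacf$span))
  m1 <- x$fits$M1
  if (!is.null(m1)) {
    cat(sprintf("M1 (multilevel): %s\n",
                if (!m1$converged) "did not converge"
                else if (m1$degenerate) "degenerate (collapses to fixed model)"
                else "converged"))
  }
  cat(sprintf("M2 AIC %.1f vs M3 AIC %.1f -> chosen %s\n",
              x$fits$M2$AIC, x$fits$M3$AIC, x$chosen_model))
  print(x$diagnostics)
  invisible(x)
}
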