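# split a panel-like object into per-subject value vectors indexed by t
panel_series <- function(x, value_col = "count") {
  if (inherits(x, "panel_dataset")) value_col <- "count"
  if (!value_col %in% names(x)) {
    stop_memlag(sprintf("no value column '%s' in input", value_col),
                "memlag_bad_columns")
  }
  ids <- unique(x$subject_id)
  lapply(stats::setNames(ids, ids), function(id) {
    rows <- x[x$subject_id == id, , drop = FALSE]
    v <- rep(NA_real_, max(rows$t))
    v[rows$t] <- rows[[value_col]]
    v
  })
}

pooled_acf_core <- function(series, max_lag, demean = c("within", "global", "none")) {
  demean <- match.arg(demean)
  if (demean == "global") {
    gm <- mean(unlist(series), na.rm = TRUE)
    series <- lapply(series, function(v) v - gm)
  } else if (demean == "within") {
    series <- lapply(series, function(v) v - mean(v, na.rm = TRUE))
  }
  den <- sum(vapply(series, function(v) sum(v^2, na.rm = TRUE), numeric(1)))
  if (den <= 0) {
    stop_memlag("zero pooled variance", "memlag_degenerate_series")
  }
  num <- numeric(max_lag)
  n_eff <- integer(max_lag)
  for (v in series) {
    n <- length(v)
    for (k in seq_len(min(max_lag, n - 1L))) {
      prod <- v[1:(n - k)] * v[(k + 1):n]
      num[k] <- num[k] + sum(prod, na.rm = TRUE)
      n_eff[k] <- n_eff[k] + sum(!is.na(prod))
    }
  }
  if (n_eff[max_lag] == 0L) {
    stop_memlag("max_lag is at least as long as every subject's usable record",
                "memlag_lag_too_long")
  }
  r <- num / den
  list(r = r, n_eff = n_eff, den = den,
       n_total = sum(vapply(series, function(v) sum(!is.na(v)), numeric(1))))
}

make_correlogram <- function(lag, r, n_eff, type, demean, n_total) {
  band <- stats::qnorm(0.975) / sqrt(pmax(n_eff, 1))
  band[n_eff == 0L] <- NA_real_
  df <- data.frame(lag = c(0L, lag), r = c(1, r),
                   n_eff = c(NA_integer_, n_eff),
                   band = c(NA_real_, band),
                   significant = c(NA, abs(r) > band))
  structure(df, type = type, demean = demean, n_total = n_total,
            class = c("pooled_correlogram", "data.frame"))
}

#' Pooled autocorrelation function for panel data
#'
#' Within-subject (by default) demeaned cross-products are summed across
#' subjects and normalized by the pooled lag-0 sum of squares; products are
#' never formed across subject boundaries, and missing days simply drop the
#' pairs they touch. The significance band is the white-noise approximation
#' +/- z(.975)/sqrt(N_eff(k)), where N_eff(k) counts valid pairs at lag k.
#'
#' @param x A `panel_dataset` (column `count`) or a data frame with
#'   `subject_id`, `t` and `value_col`.
#' @param max_lag Largest lag.
#' @param demean `"within"` (subject means removed; default, prevents
#'   between-subject level differences inflating the correlations),
#'   `"global"` (one overall mean) or `"none"`.
#' @param value_col Value column for non-panel inputs.
#' @return A `pooled_correlogram` data frame (lag 0 included, r0 = 1).
#' @export
pooled_acf <- function(x, max_lag, demean = "within", value_col = "count") {
  series <- panel_series(x, value_col)
  core <- pooled_acf_core(series, max_lag, demean)
  make_correlogram(seq_len(max_lag), core$r, core$n_eff, "acf", demean,
                   core$n_total)
}

#' Pooled partial autocorrelation function
#'
#' Applies the Durbin-Levinson recursion to the pooled autocorrelation
#' sequence of [pooled_acf()].
#'
#' @inheritParams pooled_acf
#' @return A `pooled_correlogram` with type `"pacf"`.
#' @export
pooled_pacf <- function(x, max_lag, demean = "within", value_col = "count") {
  series <- panel_series(x, value_col)
  core <- pooled_acf_core(series, max_lag, demean)
  pac <- durbin_levinson(core$r)
  make_correlogram(seq_len(max_lag), pac, core$n_eff, "pacf", demean,
                   core$n_total)
}

# Durbin-Levinson: partial autocorrelations from the acf sequence r[1..m]
durbin_levinson <- function(r) {
  m <- length(r)
  pacf <- numeric(m)
  phi <- numeric(0)
  pacf[1] <- r[1]
  phi <- r[1]
  if (m >= 2) {
    for (k in 2:m) {
      num <- r[k] - sum(phi * r[(k - 1):1])
      den <- 1 - sum(phi * r[1:(k - 1)])
      a <- num / den
      phi <- c(phi - a * rev(phi), a)
      pacf[k] <- a
    }
  }
  pacf
}

#' Largest significant lag of a correlogram
#'
#' With `sign = "both"` (textbook default) a lag is significant when |r|
#' exceeds the white-noise band. For the habit-memory span the package uses
#' `sign = "positive"`: memory means positive dependence on past behavior
#' (the lag coefficients of the model are sign-constrained and tested
#' one-tailed), and within-subject demeaning leaves a small negative
#' artifact at all lags beyond the true order (about -Var(subject mean)
#' spread over the spectrum) that a two-sided scan mistakes for structure
#' at large pooled sample sizes.
#'
#' @param cg A `pooled_correlogram`.
#' @param sign Which exceedances count: `"both"`, `"positive"`, `"negative"`.
#' @return List with `span` (largest significant lag; 0 when none) and
#'   `significant_lags`.
#' @export
significant_lag_span <- function(cg, sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  keep <- switch(sign,
                 both = !is.na(cg$significant) & cg$significant,
                 positive = !is.na(cg$band) & cg$r > cg$band,
                 negative = !is.na(cg$band) & cg$r < -cg$band)
  sig <- cg$lag[keep]
  list(span = if (length(sig)) max(sig) else 0L, significant_lags = sig)
}

#' @export
print.pooled_correlogram <- function(x, ...) {
  cat(sprintf("Pooled %s (demeaning: %s), %d lags\n",
              toupper(attr(x, "type")), attr(x, "demean"), max(x$lag)))
  print(utils::head(as.data.frame(x), 15), digits = 3)
  invisible(x)
}
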