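#' Per-subject scale factors
#'
#' The scale s_j is the sample standard deviation (n - 1 denominator) of a
#' subject's non-missing raw counts, computed over all recorded days.
#'
#' @param x A `panel_dataset`.
#' @return Data frame with `subject_id` and `s`.
#' @export
subject_scales <- function(x) {
  ids <- unique(x$subject_id)
  s <- vapply(ids, function(id) {
    v <- x$count[x$subject_id == id]
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    stats::sd(v)
  }, numeric(1))
  bad <- ids[is.na(s) | s == 0]
  if (length(bad)) {
    stop_memlag(sprintf("constant or degenerate series (zero scale) for subject(s): %s",
                        paste(bad, collapse = ", ")),
                "memlag_constant_series")
  }
  data.frame(subject_id = ids, s = as.numeric(s), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Homoscedastic per-subject rescaling
#'
#' Divides every count by its subject's own sample standard deviation, so
#' each subject's non-missing values have sample variance exactly 1. Values
#' are scaled only, not centered: between-subject level differences persist
#' on the transformed scale (and are absorbed by the lag structure
#' downstream). Missing days are preserved.
#'
#' @param x A `panel_dataset`.
#' @return A `homoscedastic_panel`: the transformed panel carrying the
#'   per-subject scale table as attribute `scales`.
#' @export
homoscedastic_transform <- function(x) {
  scales <- subject_scales(x)
  s <- scales$s[match(x$subject_id, scales$subject_id)]
  out <- x
  out$count <- x$count / s
  attr(out, "scales") <- scales
  class(out) <- c("homoscedastic_panel", class(x))
  out
}

#' Lag specification for the seasonal design
#'
#' @param nonseasonal Short-range lags (default 1 and 2 days).
#' @param period Seasonal period in days (default 7, the weekly cycle).
#' @param multiples Number of seasonal multiples (default 8, giving lags
#'   7, 14, ..., 56).
#' @return A `lag_spec` with the combined ordered lag set.
#' @export
lag_spec <- function(nonseasonal = c(1L, 2L), period = 7L, multiples = 8L) {
  nonseasonal <- sort(unique(as.integer(nonseasonal)))
  seasonal <- if (multiples >= 1L) period * seq_len(multiples) else integer()
  lags <- sort(unique(c(nonseasonal, seasonal)))
  if (length(lags) == 0L || any(lags < 1L)) {
    stop_memlag("lag set must be non-empty with positive lags", "memlag_bad_lags")
  }
  if (length(intersect(nonseasonal, seasonal))) {
    stop_memlag("nonseasonal and seasonal lags must be distinct", "memlag_bad_lags")
  }
  structure(list(nonseasonal = nonseasonal, period = as.integer(period),
                 multiples = as.integer(multiples), seasonal = seasonal,
                 lags = lags, max_lag = max(lags)),
            class = "lag_spec")
}

#' Build the regression-ready lag design
#'
#' For each subject, usable rows are days `max_lag + 1 .. n_j`; a row is kept
#' only when the response and every required lag are present for the same
#' subject (exact index arithmetic, no cross-subject leakage). Listwise
#' deletion around missing days is bookkept per cause. Weekday dummies use
#' Sunday as the reference.
#'
#' @param x A `homoscedastic_panel` (or any `panel_dataset`).
#' @param spec A [lag_spec()].
#' @return A `lag_design` data frame with columns `subject_id`, `t`,
#'   `weekday`, `y`, `lag_<k>`, `d_mon`..`d_sat` (plus `gender`/`age` when
#'   the panel carries them), and attributes `lag_spec` and `dropped`
#'   (the deletion ledger).
#' @export
build_lag_design <- function(x, spec = lag_spec()) {
  lags <- spec$lags
  maxlag <- spec$max_lag
  meta <- attr(x, "subjects")
  dropped <- c(subjects_too_short = 0L, burn_in_rows = 0L,
               missing_response = 0L, missing_lag = 0L)
  pieces <- list()
  for (id in meta$subject_id) {
    rows <- x[x$subject_id == id, , drop = FALSE]
    n_j <- nrow(rows)
    v <- rows$count  # indexed by t = 1..n_j (validated gapless)
    if (n_j <= maxlag) {
      dropped["subjects_too_short"] <- dropped["subjects_too_short"] + 1L
      next
    }
    tt <- (maxlag + 1L):n_j
    dropped["burn_in_rows"] <- dropped["burn_in_rows"] + maxlag
    lagm <- vapply(lags, function(k) v[tt - k], numeric(length(tt)))
    if (length(tt) == 1L) lagm <- matrix(lagm, nrow = 1L)
    colnames(lagm) <- paste0("lag_", lags)
    resp <- v[tt]
    miss_resp <- is.na(resp)
    miss_lag <- !miss_resp & (rowSums(is.na(lagm)) > 0L)
    keep <- !miss_resp & !miss_lag
    dropped["missing_response"] <- dropped["missing_response"] + sum(miss_resp)
    dropped["missing_lag"] <- dropped["missing_lag"] + sum(miss_lag)
    if (!any(keep)) next
    piece <- data.frame(subject_id = id, t = tt[keep],
                        weekday = rows$weekday[tt][keep],
                        y = resp[keep], stringsAsFactors = FALSE)
    piece <- cbind(piece, as.data.frame(lagm[keep, , drop = FALSE]),
                   as.data.frame(encode_weekday(piece$weekday)))
    if (!is.null(meta$gender)) piece$gender <- meta$gender[meta$subject_id == id]
    if (!is.null(meta$age)) piece$age <- meta$age[meta$subject_id == id]
    pieces[[id]] <- piece
  }
  if (!length(pieces)) {
    stop_memlag("no subject is long enough for the requested lags",
                "memlag_empty_design")
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, lag_spec = spec, dropped = dropped,
            class = c("lag_design", "data.frame"))
}

#' Mark a plain data frame as a lag design
#'
#' Lightweight constructor for hand-built designs (toys, tests). The data
#' frame must contain `y` and one `lag_<k>` column per lag; `subject_id`,
#' `t` and the weekday dummies are filled in with defaults when absent.
#'
#' @param df Data frame.
#' @param spec A [lag_spec()] describing which lag columns are present.
#' @return A `lag_design`.
#' @export
as_lag_design <- function(df, spec) {
  df <- as.data.frame(df)
  need <- paste0("lag_", spec$lags)
  miss <- setdiff(c("y", need), names(df))
  if (length(miss)) {
    stop_memlag(paste("missing design columns:", paste(miss, collapse = ", ")),
                "memlag_bad_columns")
  }
  if (!"subject_id" %in% names(df)) df$subject_id <- "S01"
  if (!"t" %in% names(df)) df$t <- seq_len(nrow(df))
  if (!"d_mon" %in% names(df)) {
    wd <- if ("weekday" %in% names(df)) df$weekday else
      weekday_sequence("Mon", nrow(df))
    df$weekday <- wd
    df <- cbind(df, as.data.frame(encode_weekday(wd)))
  }
  structure(df, lag_spec = spec,
            dropped = c(subjects_too_short = 0L, burn_in_rows = 0L,
                        missing_response = 0L, missing_lag = 0L),
            class = c("lag_design", "data.frame"))
}
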