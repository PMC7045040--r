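#' Day-of-week means and standard deviations
#'
#' Missing days are excluded; SDs use the n - 1 sample convention. A weekday
#' with no data gets `NA` entries (flagged absent, not zero).
#'
#' @param x A `panel_dataset`.
#' @return List with a 7-row `weekday` table (Mon..Sun), `grand_mean` and
#'   `grand_sd` over all non-missing days.
#' @export
weekday_stats <- function(x) {
  v <- x$count
  ok <- !is.na(v)
  tab <- data.frame(weekday = WEEKDAYS,
                    n = NA_integer_, mean = NA_real_, sd = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(WEEKDAYS)) {
    sel <- ok & x$weekday == WEEKDAYS[i]
    tab$n[i] <- sum(sel)
    if (tab$n[i] > 0L) tab$mean[i] <- mean(v[sel])
    if (tab$n[i] > 1L) tab$sd[i] <- stats::sd(v[sel])
  }
  list(weekday = tab,
       grand_mean = mean(v[ok]),
       grand_sd = stats::sd(v[ok]))
}

#' Levene / Brown-Forsythe homogeneity-of-variance test
#'
#' Classic Levene: a one-way ANOVA on absolute deviations from the group
#' center (mean by default; `center = "median"` gives the Brown-Forsythe
#' variant). Degrees of freedom are (groups - 1, N - groups).
#'
#' @param values Numeric vector (`NA` dropped).
#' @param groups Grouping vector of the same length.
#' @param center `"mean"` or `"median"`.
#' @return List with `statistic`, `df1`, `df2`, `p_value`, `center`.
#' @export
levene_homogeneity <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop_memlag("Levene test needs at least 2 groups with at least 2 values each",
                "memlag_bad_groups")
  }
  centre_fun <- if (center == "mean") mean else stats::median
  centres <- tapply(values, groups, centre_fun)
  d <- abs(values - centres[groups])
  ft <- stats::oneway.test(d ~ groups, var.equal = TRUE)
  list(statistic = unname(ft$statistic),
       df1 = unname(ft$parameter["num df"]),
       df2 = unname(ft$parameter["denom df"]),
       p_value = unname(ft$p.value),
       center = center)
}

#' One-way random-effects intraclass correlation
#'
#' Variance decomposition of days nested in subjects, from the one-way ANOVA
#' mean squares with the unbalanced-group correction
#' k0 = (N - sum(n_j^2)/N) / (J - 1):
#' ICC = sigma2_between / (sigma2_between + sigma2_within), clipped to [0, 1].
#'
#' @param x A `panel_dataset`, or a numeric vector of values.
#' @param groups Grouping vector when `x` is a plain vector.
#' @param use For a panel: compute on `"raw"` counts (default) or on the
#'   `"homoscedastic"` transform.
#' @return ICC value in [0, 1].
#' @export
icc_oneway <- function(x, groups = NULL, use = c("raw", "homoscedastic")) {
  use <- match.arg(use)
  if (inherits(x, "panel_dataset")) {
    if (use == "homoscedastic" && !inherits(x, "homoscedastic_panel")) {
      x <- homoscedastic_transform(x)
    }
    groups <- x$subject_id
    x <- x$count
  }
  ok <- !is.na(x) & !is.na(groups)
  v <- x[ok]
  g <- factor(groups[ok])
  n_j <- as.numeric(table(g))
  J <- length(n_j)
  if (J < 2L || any(n_j < 2)) {
    stop_memlag("ICC needs at least 2 subjects with at least 2 observations each",
                "memlag_bad_groups")
  }
  N <- sum(n_j)
  gm <- mean(v)
  means <- tapply(v, g, mean)
  msb <- sum(n_j * (means - gm)^2) / (J - 1)
  msw <- sum((v - means[g])^2) / (N - J)
  k0 <- (N - sum(n_j^2) / N) / (J - 1)
  sigma_b <- (msb - msw) / k0
  icc <- sigma_b / (sigma_b + msw)
  min(max(icc, 0), 1)
}

#' Descriptive report for a daily panel
#'
#' Mirrors the descriptive layer of a pooled smoking-diary analysis:
#' weekday means/SDs, grand mean/SD, a per-subject raw and homoscedastic
#' mean/SD table, Levene tests for weekday and subject groupings, and the
#' one-way intraclass correlation.
#'
#' @param x A `panel_dataset`.
#' @param center Levene centering, see [levene_homogeneity()].
#' @return A `descriptives_report` list.
#' @export
describe_panel <- function(x, center = "mean") {
  ws <- weekday_stats(x)
  hp <- homoscedastic_transform(x)
  ids <- unique(x$subject_id)
  per_subject <- do.call(rbind, lapply(ids, function(id) {
    raw <- x$count[x$subject_id == id]
    hom <- hp$count[hp$subject_id == id]
    data.frame(subject_id = id,
               mean_raw = mean(raw, na.rm = TRUE),
               sd_raw = stats::sd(raw[!is.na(raw)]),
               mean_hom = mean(hom, na.rm = TRUE),
               sd_hom = stats::sd(hom[!is.na(hom)]),
               stringsAsFactors = FALSE)
  }))
  per_subject <- per_subject[order(per_subject$mean_raw), ]
  rownames(per_subject) <- NULL
  structure(list(
    weekday = ws$weekday,
    grand_mean = ws$grand_mean,
    grand_sd = ws$grand_sd,
    homoscedastic_grand_mean = mean(hp$count, na.rm = TRUE),
    homoscedastic_total_variance = stats::var(hp$count[!is.na(hp$count)]),
    subjects = per_subject,
    levene_weekday = levene_homogeneity(x$count, x$weekday, center = center),
    levene_subject = levene_homogeneity(x$count, x$subject_id, center = center),
    icc = icc_oneway(x)
  ), class = "descriptives_report")
}

#' @export
print.descriptives_report <- function(x, ...) {
  cat("Day-of-week descriptives (non-missing days):\n")
  print(x$weekday, digits = 4)
  cat(sprintf("Grand mean %.3f (SD %.3f); homoscedastic mean %.3f, total variance %.3f\n",
              x$grand_mean, x$grand_sd, x$homoscedastic_grand_mean,
              x$homoscedastic_total_variance))
  cat(sprintf("Levene (subjects): F(%d, %d) = %.2f, p = %.3g\n",
              x$levene_subject$df1, x$levene_subject$df2,
              x$levene_subject$statistic, x$levene_subject$p_value))
  cat(sprintf("ICC (one-way): %.3f\n", x$icc))
  invisible(x)
}
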