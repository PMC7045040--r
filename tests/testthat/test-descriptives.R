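test_that("weekday stats match a brute-force group-and-average oracle", {
  p <- toy_panel(list(A = c(3, 5, 4, 6, 2, 8, 7, 1, 9, 5, 4, 3, 6, 2)),
                 start_weekday = "Thu")
  ws <- weekday_stats(p)
  # oracle: direct split by weekday label
  for (d in WEEKDAYS) {
    vals <- p$count[p$weekday == d & !is.na(p$count)]
    i <- match(d, ws$weekday$weekday)
    expect_equal(ws$weekday$mean[i], mean(vals))
    expect_equal(ws$weekday$sd[i], stats::sd(vals))
  }
  expect_equal(ws$grand_mean, mean(p$count))
})

test_that("constant series gives flat weekday means and zero SD; absent days flagged", {
  p <- toy_panel(list(A = rep(5, 14)))
  ws <- weekday_stats(p)$weekday
  expect_true(all(ws$mean == 5))
  expect_true(all(ws$sd == 0))

  short <- toy_panel(list(A = c(1, 2, 3)))  # Mon..Wed only
  ws2 <- weekday_stats(short)$weekday
  expect_true(all(is.na(ws2$mean[ws2$weekday %in% c("Thu", "Fri", "Sat", "Sun")])))
})

test_that("Levene test equals the explicit sums-of-squares oracle", {
  vals <- c(1.2, 3.4, 2.2, 5.1, 0.3, 7.7, 2.9, 3.3, 4.8, 1.1, 6.0, 2.5)
  grp <- rep(c("a", "b", "c"), each = 4)
  lev <- levene_homogeneity(vals, grp)
  # oracle: one-way ANOVA on absolute deviations, computed from raw sums
  d <- abs(vals - ave(vals, grp))
  k <- 3; N <- 12
  ssb <- sum(tapply(d, grp, length) * (tapply(d, grp, mean) - mean(d))^2)
  ssw <- sum((d - ave(d, grp))^2)
  f_oracle <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(lev$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(lev$df1, 2)
  expect_equal(lev$df2, 9)
  expect_equal(lev$p_value, stats::pf(f_oracle, 2, 9, lower.tail = FALSE),
               tolerance = 1e-12)
  # cross-check against the established implementation
  if (requireNamespace("car", quietly = TRUE)) {
    ct <- car::leveneTest(vals ~ factor(grp), center = mean)
    expect_equal(lev$statistic, ct$`F value`[1], tolerance = 1e-10)
  }
})

test_that("identical dispersion patterns give F = 0; small groups are rejected", {
  g1 <- c(1, 3, 2, 4)
  lev <- levene_homogeneity(c(g1, g1 + 10), rep(1:2, each = 4))
  expect_equal(lev$statistic, 0)
  expect_equal(lev$p_value, 1)
  expect_error(levene_homogeneity(c(1, 2, 3), c("a", "a", "b")),
               class = "memlag_bad_groups")
})

test_that("subject-grouped Levene has df (J - 1, N - J)", {
  set.seed(2)
  sizes <- c(rep(83, 61), 96)  # 62 subjects, 5159 values
  vals <- stats::rnorm(sum(sizes))
  grp <- rep(seq_along(sizes), sizes)
  lev <- levene_homogeneity(vals, grp)
  expect_equal(lev$df1, 61)
  expect_equal(lev$df2, 5097)
})

test_that("ICC hits its boundary cases and matches the mean-squares oracle", {
  # identical constant series at different levels: all variance is between
  p1 <- toy_panel(list(A = rep(3, 10), B = rep(8, 10), C = rep(5, 10)))
  expect_equal(icc_oneway(p1), 1)

  # one subject duplicated under two ids: no between variance
  v <- c(4, 7, 2, 9, 5, 6)
  p2 <- toy_panel(list(A = v, B = v))
  expect_equal(icc_oneway(p2), 0)

  # balanced toy vs direct mean-squares formula
  set.seed(11)
  vals <- stats::rnorm(40, rep(c(0, 2, 4, 6), each = 10), 1)
  grp <- rep(1:4, each = 10)
  J <- 4; n <- 10; N <- 40
  means <- tapply(vals, grp, mean)
  msb <- n * sum((means - mean(vals))^2) / (J - 1)
  msw <- sum((vals - means[grp])^2) / (N - J)
  icc_oracle <- ((msb - msw) / n) / (((msb - msw) / n) + msw)
  expect_equal(icc_oneway(vals, grp), icc_oracle, tolerance = 1e-12)

  expect_error(icc_oneway(toy_panel(list(A = 1:5))), class = "memlag_bad_groups")
})

test_that("ICC is invariant to relabeling, shifting and positive scaling", {
  set.seed(4)
  counts <- lapply(1:6, function(i) stats::rnorm(20, mean = i * 2, sd = 1) + 10)
  names(counts) <- paste0("S", 1:6)
  p <- toy_panel(counts, allow_negative = TRUE)
  base <- icc_oneway(p)

  relabeled <- counts
  names(relabeled) <- paste0("Z", 6:1)
  expect_equal(icc_oneway(toy_panel(relabeled, allow_negative = TRUE)), base)

  shifted <- lapply(counts, function(v) v + 100)
  expect_equal(icc_oneway(toy_panel(shifted, allow_negative = TRUE)), base,
               tolerance = 1e-10)

  scaled <- lapply(counts, function(v) v * 3.7)
  expect_equal(icc_oneway(toy_panel(scaled, allow_negative = TRUE)), base,
               tolerance = 1e-10)
})

test_that("the full descriptive report is assembled coherently", {
  p <- simulate_panel(default_sim_config(), seed = 2)
  rep_ <- describe_panel(p)
  expect_equal(nrow(rep_$weekday), 7L)
  expect_equal(rep_$levene_subject$df1, 61)
  expect_equal(rep_$levene_subject$df2,
               sum(!is.na(p$count)) - 62)
  # heteroscedastic by construction: subject grouping strongly rejected
  expect_lt(rep_$levene_subject$p_value, 1e-6)
  expect_gt(rep_$icc, 0)
  expect_true(all(diff(rep_$subjects$mean_raw) >= 0))
})
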