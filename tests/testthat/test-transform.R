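test_that("two-point subject: scale is sqrt(2) and values divide through", {
  p <- toy_panel(list(A = c(4, 6)))
  s <- subject_scales(p)
  expect_equal(s$s, sqrt(2))
  hp <- homoscedastic_transform(p)
  expect_equal(hp$count, c(4, 6) / sqrt(2), tolerance = 1e-12)
})

test_that("every subject has unit variance after the transform; missing preserved", {
  p <- simulate_panel(default_sim_config(), seed = 6)
  hp <- homoscedastic_transform(p)
  v <- tapply(hp$count, hp$subject_id, function(x) stats::var(x[!is.na(x)]))
  expect_true(all(abs(v - 1) < 1e-10))
  expect_identical(which(is.na(hp$count)), which(is.na(p$count)))
})

test_that("the transform is equivariant to positive rescaling of a subject", {
  counts <- list(A = c(3, 8, 5, 9, 2, 7), B = c(10, 12, 15, 9, 14, 11))
  p1 <- toy_panel(counts)
  counts$A <- counts$A * 4.2
  p2 <- toy_panel(counts)
  expect_equal(homoscedastic_transform(p1)$count,
               homoscedastic_transform(p2)$count, tolerance = 1e-12)
})

test_that("constant series are rejected by name", {
  p <- toy_panel(list(A = c(1, 2, 3, 4), B = rep(7, 4)))
  err <- expect_error(homoscedastic_transform(p), class = "memlag_constant_series")
  expect_match(conditionMessage(err), "B")
})

test_that("weekday dummy coding: Sunday reference, unit rows elsewhere", {
  expect_equal(unname(encode_weekday("Sun")), matrix(0, 1, 6))
  expect_equal(unname(encode_weekday("Mon")), matrix(c(1, 0, 0, 0, 0, 0), 1))
  m <- encode_weekday(WEEKDAYS)
  expect_equal(ncol(m), 6L)
  expect_identical(rowSums(m), c(rep(1, 6), 0))
})

test_that("lag design row counts follow the per-subject (n_j - max_lag) oracle", {
  # 1 subject, 10 days, lags {1,2}: 8 rows
  p <- toy_panel(list(A = c(5, 3, 6, 2, 7, 4, 8, 1, 9, 5)))
  d <- build_lag_design(homoscedastic_transform(p),
                        lag_spec(nonseasonal = 1:2, multiples = 0))
  expect_equal(nrow(d), 8L)

  # study scale, fixed 84-day records, no missing: 62 * 28 rows
  cfg <- default_sim_config()
  cfg$length_sampler <- list(values = 84L, mode = 84L, mode_mass = 1)
  cfg$missing_rate <- 0
  d2 <- build_lag_design(homoscedastic_transform(simulate_panel(cfg, seed = 4)))
  expect_equal(nrow(d2), 62L * 28L)

  # ragged lengths: sum over subjects of max(0, n_j - 56)
  p3 <- simulate_panel({
    c3 <- default_sim_config(); c3$missing_rate <- 0; c3
  }, seed = 8)
  lens <- attr(p3, "subjects")$n_days
  d3 <- build_lag_design(homoscedastic_transform(p3))
  expect_equal(nrow(d3), sum(pmax(0L, lens - 56L)))
})

test_that("a missing day knocks out exactly the rows whose lags touch it", {
  v <- as.numeric(1:40) + c(0, 0.5)  # non-constant
  v[30] <- NA
  p <- toy_panel(list(A = v))
  d <- build_lag_design(homoscedastic_transform(p),
                        lag_spec(nonseasonal = 1:2, multiples = 0))
  expect_false(any(d$t %in% c(30, 31, 32)))
  expect_true(all(setdiff(3:40, 30:32) %in% d$t))
  drop <- attr(d, "dropped")
  expect_equal(unname(drop["missing_response"]), 1L)
  expect_equal(unname(drop["missing_lag"]), 2L)
})

test_that("short subjects contribute nothing; an empty design is an error", {
  p <- toy_panel(list(A = c(1, 5, 3, 8, 2, 6, 9, 4),
                      B = as.numeric(1:70) + rep(c(0, .3), 35)))
  d <- build_lag_design(homoscedastic_transform(p))  # max lag 56
  expect_equal(unname(attr(d, "dropped")["subjects_too_short"]), 1L)
  expect_equal(nrow(d), 70L - 56L)

  tiny <- toy_panel(list(A = c(1, 5, 3, 8)))
  expect_error(build_lag_design(homoscedastic_transform(tiny)),
               class = "memlag_empty_design")
})

test_that("lag columns match a brute-force re-indexing oracle on every row", {
  p <- simulate_panel(default_sim_config(), seed = 17)
  hp <- homoscedastic_transform(p)
  spec <- lag_spec()
  d <- build_lag_design(hp, spec)
  # oracle: look each value up in the raw transformed series by (subject, t - k)
  series <- split(hp, hp$subject_id)
  lookup <- function(id, t) {
    rows <- series[[id]]
    rows$count[match(t, rows$t)]
  }
  idx <- sample.int(nrow(d), 200)
  for (i in idx) {
    expect_identical(d$y[i], lookup(d$subject_id[i], d$t[i]))
    for (k in spec$lags) {
      expect_identical(d[[paste0("lag_", k)]][i],
                       lookup(d$subject_id[i], d$t[i] - k))
    }
  }
  # dummies agree with the weekday column
  expect_equal(unname(as.matrix(d[paste0("d_", tolower(WEEKDAYS[1:6]))])),
               unname(encode_weekday(d$weekday)))
})

test_that("design construction is order-stable in subject order", {
  counts <- list(A = as.numeric(1:70) + rep(c(0, .4), 35),
                 B = as.numeric(70:1) + rep(c(0, .7), 35))
  d1 <- build_lag_design(homoscedastic_transform(toy_panel(counts)))
  d2 <- build_lag_design(homoscedastic_transform(toy_panel(rev(counts))))
  strip <- function(x, id) {
    x <- as.data.frame(x)[x$subject_id == id, ]
    rownames(x) <- NULL
    x
  }
  for (id in c("A", "B")) {
    expect_identical(strip(d1, id), strip(d2, id))
  }
})
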