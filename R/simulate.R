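#' Configure the synthetic panel generator
#'
#' The generator emulates a pooled daily-count study: each subject runs the
#' same seasonal autoregression on a latent unit-variance ("homoscedastic")
#' scale around a subject-specific level, a weekly mean profile enters with
#' Sunday as the reference day, and the latent series is mapped to raw counts
#' by a subject-specific scale factor. Missing days are injected completely
#' at random.
#'
#' @param n_subjects Number of subjects.
#' @param length_sampler List with `values` (admissible record lengths),
#'   `mode` and `mode_mass`: the mode is drawn with probability `mode_mass`,
#'   otherwise a uniform draw over the remaining values.
#' @param subject_mean List with `mean` and `sd` of the per-subject latent
#'   stationary level, or `NULL` to use `intercept` directly as the common
#'   regression intercept.
#' @param subject_scale List with `meanlog`, `sdlog` of the log-normal raw
#'   scale factor s_j (> 0) that maps the latent scale to counts.
#' @param ar Named numeric vector of autoregressive coefficients, names are
#'   integer lags (days). Must define a stationary recursion.
#' @param weekday_effects Named numeric vector `Mon`..`Sat` of weekday mean
#'   shifts on the latent scale; Sunday is the zero reference.
#' @param intercept Common regression intercept, used when `subject_mean`
#'   is `NULL` (otherwise each subject's intercept is solved from its drawn
#'   level).
#' @param innovation_sd Innovation standard deviation, or `"auto"` to solve
#'   for within-subject stationary variance 1 on the latent scale
#'   (deterministic-weekly-cycle variance plus autoregressive variance).
#' @param missing_rate Fraction of days whose count is missing (MCAR).
#' @param integerize Round raw values to non-negative integers. Off by
#'   default: the fitted model is linear-Gaussian and rounding is a realism
#'   toggle only.
#' @param burn_in Days simulated and discarded before the recorded window
#'   (default 200, more than three times the longest default lag).
#' @param seed Default seed used by [simulate_panel()] when none is given.
#' @return A `sim_config` object.
#' @seealso [default_sim_config()] for the study-calibrated defaults.
#' @export
sim_config <- function(n_subjects = 62L,
                       length_sampler = list(values = 69:91, mode = 84L,
                                             mode_mass = 46 / 62),
                       subject_mean = list(mean = 4.546, sd = sqrt(1.253)),
                       subject_scale = list(meanlog = log(3.4), sdlog = 0.35),
                       ar = numeric(),
                       weekday_effects = c(Mon = 0, Tue = 0, Wed = 0,
                                           Thu = 0, Fri = 0, Sat = 0),
                       intercept = 0,
                       innovation_sd = "auto",
                       missing_rate = 0,
                       integerize = FALSE,
                       burn_in = 200L,
                       seed = 1L) {
  stopifnot(n_subjects >= 1L, burn_in >= 0L,
            missing_rate >= 0, missing_rate < 1)
  if (length(ar)) {
    lags <- as.integer(names(ar))
    if (anyNA(lags) || any(lags < 1L) || anyDuplicated(lags)) {
      stop_memlag("`ar` must be named by distinct positive integer lags",
                  "memlag_bad_ar")
    }
    ar <- ar[order(lags)]
    check_stationary(ar)
  }
  wd <- weekday_effects[WEEKDAYS[1:6]]
  if (anyNA(wd)) {
    stop_memlag("weekday_effects must be named Mon..Sat (Sunday is the reference)",
                "memlag_bad_weekday_effects")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 length_sampler = length_sampler,
                 subject_mean = subject_mean,
                 subject_scale = subject_scale,
                 ar = ar, weekday_effects = wd, intercept = intercept,
                 innovation_sd = innovation_sd,
                 missing_rate = missing_rate, integerize = integerize,
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "sim_config")
}

#' Default generator configuration calibrated to the published study
#'
#' Autoregressive coefficients at lags 1, 2 and the eight weekly multiples
#' 7..56, weekday effects (Sunday reference) and intercept are set to the
#' published pooled estimates for daily cigarette counts; 62 subjects with
#' record lengths 69-91 days (mode 84), 1.08% missingness, and innovation
#' variance solved so the latent within-subject stationary variance is 1.
#'
#' @return A `sim_config`.
#' @export
default_sim_config <- function() {
  sim_config(
    n_subjects = 62L,
    ar = c(`1` = .2468, `2` = .0983, `7` = .1934, `14` = .0867, `21` = .0716,
           `28` = .0653, `35` = .0652, `42` = .0523, `49` = .0522, `56` = .0521),
    weekday_effects = c(Mon = -.3845, Tue = -.2052, Wed = -.1910,
                        Thu = -.1479, Fri = -.0449, Sat = -.0732),
    intercept = .2618,
    missing_rate = .0108,
    innovation_sd = "auto"
  )
}

# stationarity: all roots of 1 - sum b_k z^k outside the unit circle
check_stationary <- function(ar) {
  p <- max(as.integer(names(ar)))
  coefs <- numeric(p)
  coefs[as.integer(names(ar))] <- ar
  roots <- polyroot(c(1, -coefs))
  if (min(Mod(roots)) <= 1) {
    stop_memlag("autoregressive configuration is non-stationary", "memlag_nonstationary")
  }
  invisible(min(Mod(roots)))
}

#' Stationary autocorrelations of a sparse-lag autoregression
#'
#' Solves the Yule-Walker system for the theoretical autocorrelation
#' function of `y_t = sum_k b_k y_(t-k) + e_t`, extended by recursion
#' beyond the largest lag.
#'
#' @param ar Named coefficient vector (names are lags).
#' @param max_lag Largest lag to return.
#' @return Numeric vector `rho[1..max_lag]`.
#' @export
ar_stationary_acf <- function(ar, max_lag) {
  if (!length(ar)) return(numeric(max_lag))
  lags <- as.integer(names(ar))
  p <- max(lags)
  coefs <- numeric(p)
  coefs[lags] <- ar
  A <- matrix(0, p, p)
  rhs <- numeric(p)
  for (k in seq_len(p)) {
    for (m in lags) {
      d <- abs(k - m)
      if (d == 0L) rhs[k] <- rhs[k] + coefs[m] else A[k, d] <- A[k, d] + coefs[m]
    }
  }
  rho <- solve(diag(p) - A, rhs)
  if (max_lag > p) {
    rho <- c(rho, numeric(max_lag - p))
    for (k in (p + 1L):max_lag) rho[k] <- sum(coefs[lags] * rho[k - lags])
  }
  rho[seq_len(max_lag)]
}

# periodic steady-state weekday means (relative to their average) and the
# variance they contribute; the intercept shifts all seven equally so it
# drops out of the variance
weekly_cycle <- function(ar, weekday_effects) {
  om <- c(weekday_effects, Sun = 0)[WEEKDAYS]
  if (!length(ar)) {
    m <- om - mean(om)
    return(list(means = m, variance = mean(m^2)))
  }
  lags <- as.integer(names(ar))
  B <- matrix(0, 7, 7)
  for (d in 1:7) {
    for (i in seq_along(lags)) {
      j <- ((d - 1L - lags[i]) %% 7L) + 1L
      B[d, j] <- B[d, j] + ar[i]
    }
  }
  m <- solve(diag(7) - B, om)
  m <- m - mean(m)
  list(means = stats::setNames(as.numeric(m), WEEKDAYS), variance = mean(m^2))
}

#' Innovation SD solving for unit latent stationary variance
#'
#' Decomposes the latent within-subject variance into the deterministic
#' weekly-cycle part and the autoregressive part, and returns the innovation
#' standard deviation for which the total equals `target`.
#'
#' @param ar Named coefficient vector.
#' @param weekday_effects Named Mon..Sat effects.
#' @param target Target stationary variance (default 1).
#' @return Innovation standard deviation.
#' @export
innovation_sd_auto <- function(ar, weekday_effects, target = 1) {
  vc <- weekly_cycle(ar, weekday_effects)$variance
  if (vc >= target) {
    stop_memlag("weekly cycle variance alone exceeds the target stationary variance",
                "memlag_bad_config")
  }
  if (!length(ar)) return(sqrt(target - vc))
  rho <- ar_stationary_acf(ar, max(as.integer(names(ar))))
  sbr <- sum(ar * rho[as.integer(names(ar))])
  sqrt((target - vc) * (1 - sbr))
}

#' Simulate a heteroscedastic seasonal-autoregressive panel
#'
#' For each subject: draw a record length, start weekday, latent level and
#' raw scale; run the latent recursion
#' `y_t = a_j + sum_k b_k y_(t-k) + omega_(weekday(t)) + e_t` over a
#' discarded burn-in; multiply by the subject scale; optionally round to
#' non-negative integers; and inject missing days at random. The subject
#' intercept `a_j` is solved so the latent stationary mean equals the drawn
#' level. Identical seeds give identical datasets.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `panel_dataset` with a `ground_truth` attribute recording the
#'   configuration, the innovation SD actually used, each subject's latents,
#'   and the latent (pre-scaling, pre-rounding) series.
#' @export
simulate_panel <- function(config = default_sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$ar)) check_stationary(config$ar)
  set.seed(seed)
  ar <- config$ar
  lags <- if (length(ar)) as.integer(names(ar)) else integer()
  maxlag <- if (length(lags)) max(lags) else 0L
  sum_b <- sum(ar)
  om6 <- config$weekday_effects
  om <- c(om6, Sun = 0)[WEEKDAYS]
  om_bar <- mean(om)
  sigma_e <- if (identical(config$innovation_sd, "auto")) {
    innovation_sd_auto(ar, om6)
  } else as.numeric(config$innovation_sd)
  # stationary SD of the AR-driven part, used to start the recursion near
  # its stationary law
  init_sd <- if (length(ar)) {
    rho <- ar_stationary_acf(ar, maxlag)
    sigma_e / sqrt(1 - sum(ar * rho[lags]))
  } else sigma_e

  ls <- config$length_sampler
  other <- setdiff(ls$values, ls$mode)
  subj_rows <- vector("list", config$n_subjects)
  latents <- vector("list", config$n_subjects)
  truth <- data.frame(subject_id = character(config$n_subjects),
                      n_days = integer(config$n_subjects),
                      start_weekday = character(config$n_subjects),
                      mu = numeric(config$n_subjects),
                      scale = numeric(config$n_subjects),
                      intercept = numeric(config$n_subjects),
                      gender = character(config$n_subjects),
                      age = integer(config$n_subjects),
                      stringsAsFactors = FALSE)

  for (j in seq_len(config$n_subjects)) {
    id <- sprintf("S%02d", j)
    n_j <- if (stats::runif(1) < ls$mode_mass || !length(other)) ls$mode else
      other[sample.int(length(other), 1L)]
    start_wd <- WEEKDAYS[sample.int(7L, 1L)]
    if (is.null(config$subject_mean)) {
      a_j <- config$intercept
      mu_j <- (a_j + om_bar) / (1 - sum_b)
    } else {
      mu_j <- stats::rnorm(1, config$subject_mean$mean, config$subject_mean$sd)
      a_j <- mu_j * (1 - sum_b) - om_bar
    }
    s_j <- stats::rlnorm(1, config$subject_scale$meanlog, config$subject_scale$sdlog)
    gender <- if (stats::runif(1) < 36 / 62) "male" else "female"
    age <- 18L + min(stats::rgeom(1, 0.35), 8L)

    total <- config$burn_in + n_j
    # weekday index over burn-in + record so that recorded day 1 = start_wd
    wd_idx <- ((weekday_index(start_wd) - 1L +
                  (seq_len(total) - config$burn_in - 1L)) %% 7L) + 1L
    y <- numeric(total)
    pre <- seq_len(maxlag)
    if (maxlag > 0L) y[pre] <- mu_j + stats::rnorm(maxlag, 0, init_sd)
    eps <- stats::rnorm(total - maxlag, 0, sigma_e)
    for (t in (maxlag + 1L):total) {
      ar_part <- if (maxlag > 0L) sum(ar * y[t - lags]) else 0
      y[t] <- a_j + ar_part + om[wd_idx[t]] + eps[t - maxlag]
    }
    latent <- y[(config$burn_in + 1L):total]
    raw <- latent * s_j
    if (config$integerize) raw <- pmax(0, round(raw))
    if (config$missing_rate > 0) {
      raw[stats::runif(n_j) < config$missing_rate] <- NA_real_
    }
    subj_rows[[j]] <- data.frame(subject_id = id, t = seq_len(n_j),
                                 weekday = WEEKDAYS[wd_idx[(config$burn_in + 1L):total]],
                                 count = raw, stringsAsFactors = FALSE)
    latents[[j]] <- latent
    truth[j, ] <- list(id, n_j, start_wd, mu_j, s_j, a_j, gender, age)
  }

  covars <- truth[c("subject_id", "gender", "age")]
  panel <- panel_dataset(do.call(rbind, subj_rows), subjects = covars,
                         allow_negative = !config$integerize)
  attr(panel, "ground_truth") <- list(config = config, sigma_eps = sigma_e,
                                      subjects = truth,
                                      latent = stats::setNames(latents, truth$subject_id))
  panel
}

#' Named fixture panels for tests and examples
#'
#' Deterministic per seed. `tiny`: 2 subjects x 10 days, lag-1 dependence
#' only. `white_noise`: no autoregression, no weekday effects.
#' `no_missing`: the study-scale configuration without missing days or
#' rounding. `study`: the full default configuration.
#'
#' @param seed Integer seed.
#' @return Named list of `panel_dataset` objects.
#' @export
make_fixture_suite <- function(seed = 1L) {
  tiny_cfg <- sim_config(n_subjects = 2L,
                         length_sampler = list(values = 10L, mode = 10L, mode_mass = 1),
                         ar = c(`1` = 0.3), burn_in = 100L)
  wn_cfg <- sim_config(ar = numeric(), missing_rate = 0)
  nomiss_cfg <- default_sim_config()
  nomiss_cfg$missing_rate <- 0
  list(tiny = simulate_panel(tiny_cfg, seed = seed),
       white_noise = simulate_panel(wn_cfg, seed = seed + 1L),
       no_missing = simulate_panel(nomiss_cfg, seed = seed + 2L),
       study = simulate_panel(default_sim_config(), seed = seed + 3L))
}
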