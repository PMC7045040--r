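# build a panel from a named list of count vectors (one per subject)
toy_panel <- function(counts, start_weekday = "Mon", subjects = NULL,
                      allow_negative = FALSE) {
  sw <- if (length(start_weekday) == 1L)
    stats::setNames(rep(start_weekday, length(counts)), names(counts)) else
      start_weekday
  if (!length(counts)) {
    return(panel_dataset(data.frame(subject_id = character(), t = integer(),
                                    weekday = character(), count = numeric())))
  }
  rows <- do.call(rbind, lapply(names(counts), function(id) {
    v <- counts[[id]]
    data.frame(subject_id = id, t = seq_along(v),
               weekday = weekday_sequence(sw[[id]], length(v)),
               count = as.numeric(v), stringsAsFactors = FALSE)
  }))
  panel_dataset(rows, subjects = subjects, allow_negative = allow_negative)
}

# a small stationary AR(1) panel on the latent scale, handy for estimation;
# mean-zero homogeneous levels so the pooled coefficient estimates the true
# phi (any level dispersion — including what the per-subject SD rescaling
# induces when means are large — is absorbed by the lags otherwise)
ar1_panel <- function(n_subjects = 8L, n_days = 60L, phi = 0.5, seed = 1L,
                      mean_level = 0, scale = 2) {
  cfg <- sim_config(
    n_subjects = n_subjects,
    length_sampler = list(values = n_days, mode = n_days, mode_mass = 1),
    subject_mean = list(mean = mean_level, sd = 0),
    subject_scale = list(meanlog = log(scale), sdlog = 0.1),
    ar = stats::setNames(phi, "1"),
    innovation_sd = "auto", burn_in = 100L)
  simulate_panel(cfg, seed = seed)
}

# shared memoized study-scale Monte Carlo used by several acceptance checks
study_fit_cache <- local({
  cache <- NULL
  function(n_seeds = 50L) {
    if (!is.null(cache) && length(cache) >= n_seeds) return(cache[seq_len(n_seeds)])
    cfg <- default_sim_config()
    cache <<- lapply(seq_len(n_seeds), function(s) {
      panel <- simulate_panel(cfg, seed = 1000L + s)
      design <- build_lag_design(homoscedastic_transform(panel))
      fit <- fit_pooled(design, m2_spec())
      list(terms = fit$terms, R2 = fit$R2)
    })
    cache
  }
})
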