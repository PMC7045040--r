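#' Constraint specification for the pooled fit
#'
#' Three families of constraints, each independently toggleable:
#' \describe{
#'   \item{order}{non-negative, weakly decreasing coefficient chains:
#'     the non-seasonal chain (e.g. b1 >= b2 >= 0) and the seasonal chain
#'     (b7 >= b14 >= ... >= 0), enforced by a non-negative-increment
#'     reparameterization. More remote days never predict more strongly.}
#'   \item{var_equal}{equal variances across all lag columns (the same
#'     variable at different delays).}
#'   \item{cov_distance}{covariances between lag columns depend only on the
#'     distance in days between the lags (a Toeplitz-by-distance block).}
#' }
#'
#' @param order,var_equal,cov_distance Logical toggles.
#' @return A `constraint_spec`.
#' @export
constraint_spec <- function(order = TRUE, var_equal = TRUE, cov_distance = TRUE) {
  structure(list(order = order, var_equal = var_equal,
                 cov_distance = cov_distance), class = "constraint_spec")
}

#' Model specification for the pooled / multilevel ladder
#'
#' @param name Label for reports.
#' @param lags A [lag_spec()].
#' @param weekday Include the six Sunday-reference weekday dummies.
#' @param level2 Subject-constant covariates to include (subset of
#'   `c("gender", "age")`).
#' @param constraints A [constraint_spec()].
#' @param random Random-coefficient set for the multilevel path (subset of
#'   `c("intercept", "lag_1", "lag_7")` or other lag column names). Nonempty
#'   implies [fit_multilevel()].
#' @param baseline Zero-covariance null: every variable independent, no
#'   structural coefficients (the reference model for incremental fit
#'   indices).
#' @return A `model_spec`.
#' @export
model_spec <- function(name = "custom", lags = lag_spec(), weekday = TRUE,
                       level2 = character(), constraints = constraint_spec(),
                       random = character(), baseline = FALSE) {
  stopifnot(inherits(lags, "lag_spec"), inherits(constraints, "constraint_spec"))
  structure(list(name = name, lags = lags, weekday = weekday,
                 level2 = level2, constraints = constraints,
                 random = random, baseline = baseline),
            class = "model_spec")
}

#' @rdname model_spec
#' @details `m2_spec()`: intercept, constrained lags and weekday dummies
#'   (the accepted fixed-effects model). `m3_spec()`: intercept and lags
#'   only. `m0_spec()`: the zero-covariance null. `m1_spec()`: the full
#'   multilevel hypothesis with random intercept and random lag-1/lag-7
#'   slopes plus subject-level covariates.
#' @export
m2_spec <- function(lags = lag_spec()) model_spec("M2", lags)

#' @rdname model_spec
#' @export
m3_spec <- function(lags = lag_spec()) model_spec("M3", lags, weekday = FALSE)

#' @rdname model_spec
#' @export
m0_spec <- function(lags = lag_spec()) {
  model_spec("M0", lags, baseline = TRUE)
}

#' @rdname model_spec
#' @export
m1_spec <- function(lags = lag_spec(), level2 = c("gender", "age")) {
  model_spec("M1", lags, level2 = level2,
             random = c("intercept", "lag_1", "lag_7"))
}

# ---- design matrices ------------------------------------------------------

design_matrices <- function(design, spec) {
  lag_cols <- paste0("lag_", spec$lags$lags)
  miss <- setdiff(lag_cols, names(design))
  if (length(miss)) {
    stop_memlag(paste("design lacks lag columns:", paste(miss, collapse = ", ")),
                "memlag_bad_columns")
  }
  X <- as.matrix(design[lag_cols])
  Z <- matrix(1, nrow(design), 1L, dimnames = list(NULL, "intercept"))
  if (spec$weekday) {
    Z <- cbind(Z, as.matrix(design[paste0("d_", tolower(WEEKDAYS[1:6]))]))
  }
  if (length(spec$level2)) {
    for (v in spec$level2) {
      if (!v %in% names(design)) {
        stop_memlag(sprintf("level-2 covariate '%s' not in design", v),
                    "memlag_bad_columns")
      }
      col <- design[[v]]
      if (v == "gender") {
        Z <- cbind(Z, gender_male = as.numeric(col == "male"))
      } else {
        Z <- cbind(Z, stats::setNames(as.numeric(col), NULL))
        colnames(Z)[ncol(Z)] <- v
      }
    }
  }
  list(y = design$y, X = X, Z = Z, lag_cols = lag_cols)
}

# increments-to-coefficients map for the two ordered chains; invertible
chain_map <- function(spec) {
  lags <- spec$lags$lags
  nlag <- length(lags)
  A <- matrix(0, nlag, nlag)
  chains <- list(nonseasonal = match(spec$lags$nonseasonal, lags),
                 seasonal = match(spec$lags$seasonal, lags))
  chains <- Filter(function(p) length(p) > 0, chains)
  for (pos in chains) {
    for (i in seq_along(pos)) A[pos[i], pos[i:length(pos)]] <- 1
  }
  list(A = A, chains = chains)
}

# active-set solver: minimize ||y - M theta||^2 subject to
# theta[i] >= 0 for i > n_free (strictly convex QP, exact at convergence)
qp_nonneg <- function(M, y, n_free) {
  p <- ncol(M)
  MtM <- crossprod(M)
  Mty <- drop(crossprod(M, y))
  bound <- seq_len(p) > n_free
  active <- rep(FALSE, p)
  for (iter in seq_len(40L * p + 40L)) {
    free <- !active
    theta <- numeric(p)
    theta[free] <- tryCatch(
      solve(MtM[free, free, drop = FALSE], Mty[free]),
      error = function(e) qr.solve(MtM[free, free, drop = FALSE], Mty[free]))
    neg <- which(free & bound & theta < -1e-10)
    if (length(neg)) {
      active[neg[which.min(theta[neg])]] <- TRUE
      next
    }
    theta[bound & theta < 0] <- 0
    g <- drop(MtM %*% theta) - Mty
    viol <- which(active & g < -1e-8)
    if (!length(viol)) {
      return(list(theta = theta, iterations = iter))
    }
    active[viol[which.min(g[viol])]] <- FALSE
  }
  stop_memlag("constrained least-squares active set did not converge",
              "memlag_qp_failed")
}

# ---- structured covariance of the lag block -------------------------------

# class index matrix for the lag-block covariance under the constraints
moment_classes <- function(lags, var_equal, cov_distance) {
  nlag <- length(lags)
  cls <- matrix(NA_integer_, nlag, nlag)
  labels <- character(0)
  get_id <- function(lab) {
    i <- match(lab, labels)
    if (is.na(i)) {
      labels <<- c(labels, lab)
      i <- length(labels)
    }
    i
  }
  for (i in seq_len(nlag)) {
    lab <- if (var_equal) "var" else paste0("var_", lags[i])
    cls[i, i] <- get_id(lab)
  }
  if (nlag >= 2L) {
    for (i in 1:(nlag - 1L)) {
      for (j in (i + 1L):nlag) {
        lab <- if (cov_distance) paste0("cov_d", abs(lags[j] - lags[i])) else
          paste0("cov_", lags[i], "_", lags[j])
        cls[i, j] <- cls[j, i] <- get_id(lab)
      }
    }
  }
  list(classes = cls, labels = labels)
}

# Gaussian ML fit of a class-structured covariance to the ML sample
# covariance S; returns the fitted matrix, parameters and the minimized
# discrepancy log det(Sigma) + tr(S Sigma^-1)
fit_structured_cov <- function(S, classes) {
  cls <- classes$classes
  n_par <- length(classes$labels)
  p <- nrow(S)
  init <- vapply(seq_len(n_par), function(k) mean(S[cls == k]), numeric(1))
  build <- function(par) {
    Sigma <- matrix(par[cls], p, p)
    Sigma
  }
  obj <- function(par) {
    Sigma <- build(par)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    2 * sum(log(diag(ch))) + sum(S * chol2inv(ch))
  }
  opt <- stats::optim(init, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(Sigma = build(opt$par),
       par = stats::setNames(opt$par, classes$labels),
       value = opt$value, converged = opt$convergence == 0)
}

ml_cov <- function(M) {
  Mc <- sweep(M, 2L, colMeans(M))
  crossprod(Mc) / nrow(M)
}

log_det <- function(S) {
  2 * sum(log(diag(chol(S))))
}

# ---- pooled fit ------------------------------------------------------------

#' Fit the pooled constrained model
#'
#' Gaussian maximum likelihood of the joint mean-plus-covariance structure of
#' (response, lag block), with the weekday dummies and any subject-level
#' covariates treated as fixed regressors. The mean structure is the pooled
#' regression; order constraints on the coefficient chains are enforced by a
#' non-negative-increment reparameterization solved exactly by an active-set
#' quadratic program; the lag-block covariance is parameterized per
#' [constraint_spec()] (equal variances, distance-indexed covariances) and
#' fitted by ML. With every constraint disabled the estimates coincide with
#' ordinary least squares and the covariance block is saturated.
#'
#' Standard errors come from the observed information of the unconstrained
#' parameterization evaluated at the constrained solution, mapped back by the
#' delta method (the chain map is linear and invertible, so this equals the
#' usual regression covariance at the solution). p-values are one-tailed for
#' sign-constrained lag terms and two-tailed elsewhere.
#'
#' @param design A [build_lag_design()] result.
#' @param spec A [model_spec()] without random coefficients.
#' @return A `memlag_fit` with coefficient table (raw and standardized),
#'   log-likelihood (conditional + lag-block parts), parameter counts,
#'   AIC, R-squared, residuals, the observed and model-implied joint
#'   covariance, and the constraint-activity table.
#' @export
fit_pooled <- function(design, spec = m2_spec()) {
  stopifnot(inherits(design, "lag_design"), inherits(spec, "model_spec"))
  if (length(spec$random)) {
    stop_memlag("spec has random coefficients; use fit_multilevel()",
                "memlag_bad_spec")
  }
  n <- nrow(design)
  dm <- design_matrices(design, spec)
  y <- dm$y
  X <- dm$X
  row_key <- paste(design$subject_id, design$t)

  if (spec$baseline) {
    return(fit_baseline(y, X, spec, design, row_key))
  }

  Z <- dm$Z
  W <- cbind(Z, X)
  if (n <= ncol(W)) {
    stop_memlag("design has fewer rows than free mean parameters",
                "memlag_too_few_rows")
  }
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    bad <- colnames(W)[qrW$pivot[(qrW$rank + 1L):ncol(W)]]
    stop_memlag(paste("rank-deficient design; collinear columns:",
                      paste(bad, collapse = ", ")),
                "memlag_rank_deficient")
  }

  pZ <- ncol(Z)
  nlag <- ncol(X)
  activity <- NULL
  qp_iter <- NA_integer_
  if (spec$constraints$order) {
    cm <- chain_map(spec)
    M <- cbind(Z, X %*% cm$A)
    sol <- qp_nonneg(M, y, n_free = pZ)
    gamma <- sol$theta[seq_len(pZ)]
    delta <- sol$theta[(pZ + 1L):(pZ + nlag)]
    b <- drop(cm$A %*% delta)
    qp_iter <- sol$iterations
    activity <- data.frame(lag = spec$lags$lags, increment = delta,
                           active = delta <= 1e-10)
  } else {
    beta_ols <- qr.coef(qrW, y)
    gamma <- beta_ols[seq_len(pZ)]
    b <- beta_ols[(pZ + 1L):(pZ + nlag)]
  }
  coefs <- c(gamma, b)
  names(coefs) <- colnames(W)
  fitted <- drop(W %*% coefs)
  resid <- y - fitted
  rss <- sum(resid^2)
  sigma2_ml <- rss / n
  p_mean <- ncol(W)
  sigma2_unb <- rss / (n - p_mean)

  V <- sigma2_unb * chol2inv(qr.R(qrW))[order(qrW$pivot), order(qrW$pivot)]
  se <- sqrt(diag(V))
  tval <- coefs / se
  df_t <- n - p_mean
  is_lag <- c(rep(FALSE, pZ), rep(TRUE, nlag))
  pval <- ifelse(is_lag & spec$constraints$order,
                 stats::pt(tval, df_t, lower.tail = FALSE),
                 2 * stats::pt(abs(tval), df_t, lower.tail = FALSE))
  sd_y <- stats::sd(y)
  sd_w <- apply(W, 2L, stats::sd)
  std <- coefs * sd_w / sd_y
  std[1L] <- coefs[1L] / sd_y  # intercept: level in response-SD units
  terms <- data.frame(term = names(coefs), estimate = unname(coefs),
                      se = unname(se), t = unname(tval), p = unname(pval),
                      std = unname(std), stringsAsFactors = FALSE)

  ll_cond <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)

  # marginal (lag-block) structure
  S_xx <- ml_cov(X)
  structured <- spec$constraints$var_equal || spec$constraints$cov_distance
  if (structured) {
    classes <- moment_classes(spec$lags$lags, spec$constraints$var_equal,
                              spec$constraints$cov_distance)
    sf <- fit_structured_cov(S_xx, classes)
    Sigma_xx <- sf$Sigma
    marg_value <- sf$value
    n_par_marg <- length(sf$par) + nlag  # covariance classes + free means
    marg <- list(Sigma = Sigma_xx, par = sf$par, converged = sf$converged)
  } else {
    Sigma_xx <- S_xx
    marg_value <- log_det(S_xx) + nlag
    n_par_marg <- nlag + nlag * (nlag + 1L) / 2L
    marg <- list(Sigma = Sigma_xx, par = NULL, converged = TRUE)
  }
  ll_marg <- -n / 2 * (nlag * log(2 * pi) + marg_value)

  # implied joint covariance of (y, lags); dummy / level-2 regressors enter
  # through their sample moments (fixed-regressor convention)
  beta_z <- coefs[seq_len(pZ)][-1L]  # without intercept
  Zc <- Z[, -1L, drop = FALSE]
  if (ncol(Zc)) {
    S_xz <- crossprod(sweep(X, 2L, colMeans(X)),
                      sweep(Zc, 2L, colMeans(Zc))) / n
    S_zz <- ml_cov(Zc)
    implied_xy <- drop(Sigma_xx %*% b + S_xz %*% beta_z)
    implied_yy <- drop(t(b) %*% Sigma_xx %*% b +
                         t(beta_z) %*% S_zz %*% beta_z +
                         2 * t(b) %*% S_xz %*% beta_z) + sigma2_ml
  } else {
    implied_xy <- drop(Sigma_xx %*% b)
    implied_yy <- drop(t(b) %*% Sigma_xx %*% b) + sigma2_ml
  }
  implied <- rbind(c(implied_yy, implied_xy),
                   cbind(implied_xy, Sigma_xx))
  dimnames(implied) <- list(c("y", dm$lag_cols), c("y", dm$lag_cols))
  S_joint <- ml_cov(cbind(y = y, X))

  n_par <- p_mean + 1L + n_par_marg
  loglik <- ll_cond + ll_marg
  structure(list(
    spec = spec, n = n,
    terms = terms, term_names = names(coefs),
    sigma2 = sigma2_ml, sigma2_unbiased = sigma2_unb,
    loglik = loglik, loglik_cond = ll_cond, loglik_marg = ll_marg,
    n_par = n_par, n_par_cond = p_mean + 1L,
    AIC = -2 * loglik + 2 * n_par,
    AIC_cond = -2 * ll_cond + 2 * (p_mean + 1L),
    R2 = 1 - rss / sum((y - mean(y))^2),
    residuals = data.frame(subject_id = design$subject_id, t = design$t,
                           weekday = design$weekday, resid = resid,
                           stringsAsFactors = FALSE),
    fitted = fitted, row_key = row_key,
    S_joint = S_joint, implied = implied, marginal = marg,
    constraint_activity = activity,
    convergence = list(converged = marg$converged, qp_iterations = qp_iter)
  ), class = "memlag_fit")
}

fit_baseline <- function(y, X, spec, design, row_key) {
  n <- length(y)
  V <- cbind(y = y, X)
  v_ml <- apply(V, 2L, function(col) mean((col - mean(col))^2))
  ll <- sum(-n / 2 * (log(2 * pi * v_ml) + 1))
  implied <- diag(v_ml)
  dimnames(implied) <- list(colnames(V), colnames(V))
  structure(list(
    spec = spec, n = n,
    terms = data.frame(term = character(), estimate = numeric(),
                       se = numeric(), t = numeric(), p = numeric(),
                       std = numeric()),
    term_names = character(),
    sigma2 = unname(v_ml["y"]), sigma2_unbiased = unname(v_ml["y"]) * n / (n - 1),
    loglik = ll, loglik_cond = -n / 2 * (log(2 * pi * v_ml["y"]) + 1),
    loglik_marg = ll - (-n / 2 * (log(2 * pi * v_ml["y"]) + 1)),
    n_par = 2L * ncol(V), n_par_cond = 2L,
    AIC = -2 * ll + 4L * ncol(V),
    AIC_cond = -2 * (-n / 2 * (log(2 * pi * v_ml["y"]) + 1)) + 4,
    R2 = 0,
    residuals = data.frame(subject_id = design$subject_id, t = design$t,
                           weekday = design$weekday, resid = y - mean(y),
                           stringsAsFactors = FALSE),
    fitted = rep(mean(y), n), row_key = row_key,
    S_joint = ml_cov(V), implied = implied,
    marginal = list(Sigma = implied[-1L, -1L, drop = FALSE], par = NULL,
                    converged = TRUE),
    constraint_activity = NULL,
    convergence = list(converged = TRUE, qp_iterations = NA_integer_)
  ), class = "memlag_fit")
}

#' Saturated reference model for a design
#'
#' Unconstrained regression on the full term set (intercept, all lags,
#' weekday dummies and any level-2 covariates present in `spec`) plus a
#' saturated lag-block covariance. Every ladder model is nested in it.
#'
#' @param design A `lag_design`.
#' @param spec A `model_spec` naming the full term set (default [m2_spec()]).
#' @return List with `loglik`, `n_par`, `n`.
#' @export
saturated_model <- function(design, spec = m2_spec()) {
  full <- spec
  full$constraints <- constraint_spec(FALSE, FALSE, FALSE)
  full$baseline <- FALSE
  fit <- fit_pooled(design, full)
  list(loglik = fit$loglik, n_par = fit$n_par, n = fit$n)
}

#' @export
print.memlag_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Pooled fit %s: n = %d, loglik = %.2f, params = %d, R2 = %.3f\n",
              x$spec$name, x$n, x$loglik, x$n_par, x$R2))
  if (nrow(x$terms)) print(x$terms, digits = digits, row.names = FALSE)
  invisible(x)
}

# ---- fit indices -----------------------------------------------------------

rmsea_point <- function(chisq, df, n) {
  if (df <= 0) return(NA_real_)
  sqrt(max(0, chisq - df) / (df * n))
}

rmsea_ci <- function(chisq, df, n, level = 0.90) {
  if (df <= 0) return(c(NA_real_, NA_real_))
  lo_p <- 1 - (1 - level) / 2
  hi_p <- (1 - level) / 2
  find_ncp <- function(target) {
    if (stats::pchisq(chisq, df, ncp = 0) < target) return(0)
    ub <- max(chisq * 2, 10)
    while (stats::pchisq(chisq, df, ncp = ub) > target) ub <- ub * 2
    stats::uniroot(function(l) stats::pchisq(chisq, df, ncp = l) - target,
                   c(0, ub), tol = 1e-8)$root
  }
  c(sqrt(find_ncp(lo_p) / (df * n)), sqrt(find_ncp(hi_p) / (df * n)))
}

srmr_value <- function(S, implied) {
  d <- sqrt(diag(S))
  std_resid <- (S - implied) / tcrossprod(d)
  sqrt(mean(std_resid[upper.tri(std_resid, diag = TRUE)]^2))
}

#' SEM-style fit indices against a saturated and a baseline model
#'
#' chi2 = 2 (loglik_saturated - loglik_model); df = difference in free
#' parameters; RMSEA with a 90% CI from the noncentral chi-square inversion;
#' CFI and TLI against the zero-covariance baseline; SRMR as the root mean
#' squared standardized residual over the unique elements of the joint
#' (response, lags) covariance matrix.
#'
#' @param fit A `memlag_fit`.
#' @param saturated Result of [saturated_model()] on the same design.
#' @param baseline A baseline `memlag_fit` (from [m0_spec()]), or `NULL` to
#'   skip incremental indices.
#' @return A `fit_indices` list: `chisq`, `df`, `p`, `rmsea`, `rmsea_ci`,
#'   `cfi`, `tli`, `srmr`, `aic`, `defined` flag.
#' @export
fit_indices <- function(fit, saturated, baseline = NULL) {
  chisq <- max(0, 2 * (saturated$loglik - fit$loglik))
  df <- saturated$n_par - fit$n_par
  n <- fit$n
  out <- list(chisq = chisq, df = df,
              p = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE)
              else NA_real_,
              rmsea = rmsea_point(chisq, df, n),
              rmsea_ci = rmsea_ci(chisq, df, n),
              srmr = srmr_value(fit$S_joint, fit$implied),
              aic = fit$AIC, defined = df > 0)
  if (!is.null(baseline)) {
    chisq_b <- max(0, 2 * (saturated$loglik - baseline$loglik))
    df_b <- saturated$n_par - baseline$n_par
    num <- max(chisq - df, 0)
    den <- max(chisq - df, chisq_b - df_b, 0)
    out$cfi <- if (den == 0) 1 else 1 - num / den
    out$tli <- if (df_b > 0 && df > 0 && (chisq_b / df_b) != 1) {
      ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1)
    } else NA_real_
    out$baseline_chisq <- chisq_b
    out$baseline_df <- df_b
  }
  structure(out, class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f, p = %.3g\nRMSEA = %.3f (%.3f-%.3f), SRMR = %.3f",
              x$df, x$chisq, x$p, x$rmsea, x$rmsea_ci[1], x$rmsea_ci[2], x$srmr))
  if (!is.null(x$cfi)) cat(sprintf(", CFI = %.3f, TLI = %.3f", x$cfi, x$tli))
  cat(sprintf("\nAIC = %.3f\n", x$aic))
  invisible(x)
}

#' Nested chi-square difference test
#'
#' Delta-chi2 = 2 (loglik_full - loglik_restricted) with Delta-df the
#' difference in free parameters, referred to the chi-square distribution.
#' Requires the two fits to use identical analysis rows and the restricted
#' term set to be contained in the full one (the zero-covariance baseline is
#' accepted as restricted by convention).
#'
#' @param restricted,full `memlag_fit` objects on the same rows.
#' @return List with `delta_chisq`, `delta_df`, `p`.
#' @export
nested_chi2_test <- function(restricted, full) {
  if (!identical(restricted$row_key, full$row_key)) {
    stop_memlag("fits use different analysis rows; nesting requires identical data",
                "memlag_not_nested")
  }
  if (!restricted$spec$baseline &&
      !all(restricted$term_names %in% full$term_names)) {
    stop_memlag("restricted term set is not contained in the full term set",
                "memlag_not_nested")
  }
  delta <- 2 * (full$loglik - restricted$loglik)
  ddf <- full$n_par - restricted$n_par
  if (ddf < 0) {
    stop_memlag("restricted model has more free parameters than the full model",
                "memlag_not_nested")
  }
  p <- if (ddf == 0) {
    if (abs(delta) < 1e-8) 1 else NA_real_
  } else stats::pchisq(max(delta, 0), ddf, lower.tail = FALSE)
  list(delta_chisq = delta, delta_df = ddf, p = p)
}

# ---- multilevel path -------------------------------------------------------

#' Fit the multilevel (random-coefficient) model
#'
#' Random-intercept / random-slope Gaussian mixed model estimated by maximum
#' likelihood via `lme4::lmer`. Non-convergence and boundary (singular)
#' random-effect variances are reportable outcomes, not exceptions: a
#' degenerate fit is flagged as collapsing to the fixed-effects model.
#'
#' @param design A `lag_design`.
#' @param spec A [model_spec()] with a nonempty `random` set.
#' @return A `memlag_mlfit`: fixed-effect table, random-effect variances,
#'   log-likelihood, AIC, and `converged` / `singular` / `degenerate` flags.
#' @export
fit_multilevel <- function(design, spec = m1_spec()) {
  stopifnot(inherits(design, "lag_design"))
  if (!length(spec$random)) {
    stop_memlag("spec has no random coefficients; use fit_pooled()",
                "memlag_bad_spec")
  }
  if (length(unique(design$subject_id)) < 2L) {
    stop_memlag("multilevel fit needs at least 2 subjects", "memlag_bad_groups")
  }
  lag_cols <- paste0("lag_", spec$lags$lags)
  fixed <- c("1", lag_cols,
             if (spec$weekday) paste0("d_", tolower(WEEKDAYS[1:6])),
             spec$level2)
  rand <- spec$random
  re_terms <- c(if ("intercept" %in% rand) "1" else "0",
                setdiff(rand, "intercept"))
  fml <- stats::as.formula(paste(
    "y ~", paste(fixed, collapse = " + "),
    "+ (", paste(re_terms, collapse = " + "), "| subject_id)"))
  dat <- as.data.frame(design)
  ans <- tryCatch({
    fit <- lme4::lmer(fml, data = dat, REML = FALSE,
                      control = lme4::lmerControl(calc.derivs = TRUE))
    msgs <- unlist(fit@optinfo$conv$lme4$messages)
    singular <- lme4::isSingular(fit, tol = 1e-5)
    vc <- as.data.frame(lme4::VarCorr(fit))
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    list(converged = length(msgs) == 0L, singular = singular,
         messages = msgs,
         fixef = data.frame(term = names(fe), estimate = unname(fe),
                            se = unname(se), t = unname(fe / se),
                            stringsAsFactors = FALSE),
         varcorr = vc,
         loglik = as.numeric(stats::logLik(fit)),
         n_par = attr(stats::logLik(fit), "df"),
         AIC = stats::AIC(fit), fit = fit, error = NULL)
  }, error = function(e) {
    list(converged = FALSE, singular = NA, messages = conditionMessage(e),
         fixef = NULL, varcorr = NULL, loglik = NA_real_, n_par = NA_integer_,
         AIC = NA_real_, fit = NULL, error = conditionMessage(e))
  })
  ans$degenerate <- isTRUE(ans$singular)
  ans$spec <- spec
  ans$n <- nrow(design)
  structure(ans, class = "memlag_mlfit")
}

#' @export
print.memlag_mlfit <- function(x, ...) {
  status <- if (!x$converged) "did not converge"
  else if (x$degenerate) "degenerate - collapses to fixed model"
  else "converged"
  cat(sprintf("Multilevel fit %s: %s\n", x$spec$name, status))
  if (!is.null(x$fixef)) {
    cat(sprintf("loglik = %.2f, AIC = %.2f\n", x$loglik, x$AIC))
  }
  invisible(x)
}
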