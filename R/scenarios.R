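#' Built-in simulation scenarios
#'
#' Pre-packaged generative conditions used throughout the package's
#' calibration and recovery studies.  All return [simulation_spec()]s (or, for
#' the cohort generators, lists of simulated objects) and are fully
#' deterministic given `seed`.
#'
#' * `scenario_null()`: white noise — all intercepts and coefficients zero,
#'   independent innovations with SD 0.5.  The exchangeable null for
#'   detection (type-I) calibration.
#' * `scenario_constant()`: a stationary, constant-coefficient VAR(1) —
#'   autoregressive effects 0.3, two modest cross-lags, independent
#'   innovations with SD 0.5.  The null condition for detection calibration.
#' * `scenario_sine()`: the same process with a sinusoidal cross-lagged
#'   coefficient (Male PA -> Female NA), default amplitude 0.4 and period 40
#'   days.  The alternative condition for detection power.
#' * `scenario_drift()`: the same process with the Female PA autoregressive
#'   coefficient drifting linearly (default 0.1 to 0.6).  The trajectory
#'   recovery condition.
#'
#' @param T number of days.
#' @param seed integer seed.
#' @param amplitude,period,phase sine parameters (Male PA -> Female NA).
#' @param from,to endpoints of the linear autoregressive drift.
#' @return a [simulation_spec()].
#' @name scenarios
NULL

calibration_base_phi <- function() {
  Phi <- diag(0.3, 4)
  Phi[2, 1] <- -0.1  # Female PA -> Female NA
  Phi[3, 1] <- 0.15  # Female PA -> Male PA
  Phi
}

#' @rdname scenarios
#' @export
scenario_null <- function(T = 300, seed = 1L) {
  simulation_spec(T, intercepts = rep(0, 4),
                  coefficients = matrix(0, 4, 4),
                  innovation_covariance = diag(0.25, 4), seed = seed)
}

#' @rdname scenarios
#' @export
scenario_constant <- function(T = 300, seed = 1L) {
  simulation_spec(T, intercepts = rep(0, 4),
                  coefficients = calibration_base_phi(),
                  innovation_covariance = diag(0.25, 4), seed = seed)
}

#' @rdname scenarios
#' @export
scenario_sine <- function(T = 300, amplitude = 0.4, period = 40, phase = 0,
                          seed = 1L) {
  spec <- scenario_constant(T, seed)
  # response Female NA (row 2), lagged predictor Male PA (column 3)
  spec$coefficients[[2, 3]] <- trajectory_spec("sine", level = 0,
                                               amplitude = amplitude,
                                               period = period, phase = phase)
  spec
}

#' @rdname scenarios
#' @export
scenario_drift <- function(T = 300, from = 0.1, to = 0.6, seed = 1L) {
  spec <- scenario_constant(T, seed)
  # Female PA autoregressive coefficient (row 1, column 1)
  spec$coefficients[[1, 1]] <- trajectory_spec("linear", level = from,
                                               delta = to - from)
  spec
}

#' Innovation covariance emulating daily relationship-affect composites
#'
#' SDs of roughly 0.45 (positive affect) and 0.30 (negative affect) with a
#' negative within-person PA-NA correlation and positive cross-partner
#' same-valence correlations, in line with the correlation structure of
#' observed affect composites.
#'
#' @return a 4 x 4 covariance matrix in canonical variable order.
#' @export
affect_innovation_covariance <- function() {
  sds <- c(0.45, 0.30, 0.45, 0.30)
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- -0.30  # within female PA-NA
  R[3, 4] <- R[4, 3] <- -0.30  # within male PA-NA
  R[1, 3] <- R[3, 1] <- 0.30   # cross-partner PA-PA
  R[2, 4] <- R[4, 2] <- 0.25   # cross-partner NA-NA
  R[1, 4] <- R[4, 1] <- -0.15
  R[2, 3] <- R[3, 2] <- -0.15
  diag(sds) %*% R %*% diag(sds)
}

# Random per-dyad generating dynamics on the affect scale: modest
# heterogeneous constant levels, with each of the 16 parameters independently
# given a sinusoidal time-varying component with probability p_tv (so that on
# average about two of the 16 parameters vary over time).  Must be called
# inside an active RNG context.
random_dyad_dynamics <- function(p_tv = 0.125) {
  lev <- matrix(rnorm(16, 0, 0.05), 4, 4)
  diag(lev) <- runif(4, 0.05, 0.35)
  cf <- matrix(vector("list", 16), 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (runif(1) < p_tv) {
      cf[[i, j]] <- trajectory_spec("sine", level = lev[i, j],
                                    amplitude = runif(1, 0.1, 0.4),
                                    period = runif(1, 30, 60),
                                    phase = runif(1, 0, 2 * pi))
    } else {
      cf[[i, j]] <- trajectory_spec("constant", level = lev[i, j])
    }
  }
  list(phi_level = lev, coefficients = cf)
}

# Unmask randomly chosen missing cells (restoring the true simulated values)
# until the series yields at least `needed` complete lagged rows; used to
# construct dyads that are sufficient by design.  Must be called inside an
# active RNG context.
ensure_min_rows <- function(series, full_values, needed) {
  repeat {
    if (nrow(build_lagged_rows(series)) >= needed) return(series)
    hidden <- which(!series$observed)
    if (length(hidden) == 0) return(series)
    reveal <- sample(hidden, min(4, length(hidden)))
    series$observed[reveal] <- TRUE
    series$values[reveal] <- full_values[reveal]
  }
}

# Corrupt a series so that no complete lagged day-pair survives while nearly
# all diary days still carry observations: one variable is masked on every
# other day, so every consecutive pair contains a missing cell.
corrupt_insufficient <- function(series) {
  odd <- seq(1, length(series$days), by = 2)
  v <- (seq_along(odd) - 1) %% 4 + 1
  for (k in seq_along(odd)) {
    series$observed[odd[k], v[k]] <- FALSE
    series$values[odd[k], v[k]] <- NA_real_
  }
  series
}

#' Simulate a cohort of dyads under study-like conditions
#'
#' Generates `n_dyads` couples with heterogeneous dynamics on the affect
#' scale (stationary means near the observed PA/NA levels, about two of 16
#' parameters time-varying per dyad on average), diary lengths drawn from
#' `t_range`, per-cell missingness at `missing_rate`, values clipped to the
#' 1-5 scale, and outcomes generated from the true dynamics summaries.
#'
#' `n_insufficient` members are corrupted so that listwise deletion leaves
#' them below the complete-row floor needed by a k-basis fit (they still
#' record enough diary days to pass the inclusion filter); the remaining
#' members are constructed to clear that floor, so the cohort's
#' converged/failed bookkeeping is known by design.
#'
#' @param n_dyads cohort size.
#' @param n_insufficient number of members forced below the complete-row
#'   floor.
#' @param t_range range of diary lengths in days.
#' @param missing_rate per variable-day missing probability.
#' @param k basis dimension the cohort is meant to support (sets the
#'   complete-row floor `max(5 * k, min_rows)`).
#' @param min_rows minimum complete lagged rows for convergence.
#' @param outcome_spec an [outcome_gen_spec()] for the outcome table; its
#'   seed is re-derived from `seed`.
#' @param seed root seed; all per-dyad randomness derives from it.
#' @return list with `series` (list of [dyad_series()]), `outcomes` (data
#'   frame), `truth` (per-dyad true summary means/SDs and sufficiency flag).
#' @export
simulate_cohort <- function(n_dyads = 148, n_insufficient = 0,
                            t_range = c(50, 90), missing_rate = 0.04,
                            k = 10, min_rows = 30,
                            outcome_spec = outcome_gen_spec(),
                            seed = 1L) {
  stopifnot(n_insufficient <= n_dyads)
  needed <- max(5L * k, min_rows)
  withr::with_seed(seed, {
    dyad_seeds <- sample.int(.Machine$integer.max - 1L, n_dyads)
    insufficient <- rep(FALSE, n_dyads)
    if (n_insufficient > 0)
      insufficient[sample.int(n_dyads, n_insufficient)] <- TRUE
  })
  mu <- c(3.50, 1.34, 3.54, 1.35)  # observed-scale PA/NA means
  Sigma <- affect_innovation_covariance()
  series <- vector("list", n_dyads)
  truth_means <- truth_sds <- matrix(NA_real_, n_dyads, 16,
                                     dimnames = list(NULL, param_labels()$key))
  ids <- sprintf("dyad%03d", seq_len(n_dyads))
  for (d in seq_len(n_dyads)) {
    series[[d]] <- withr::with_seed(dyad_seeds[d], {
      lo <- if (insufficient[d]) t_range[1] else max(t_range[1], needed + 1L)
      T <- sample(seq(lo, t_range[2]), 1)
      dyn <- random_dyad_dynamics()
      intercepts <- as.numeric((diag(4) - dyn$phi_level) %*% mu)
      spec <- simulation_spec(T, intercepts = intercepts,
                              coefficients = dyn$coefficients,
                              innovation_covariance = Sigma,
                              clip_to_likert = TRUE,
                              seed = sample.int(.Machine$integer.max - 1L, 1))
      ts <- true_dynamics_summary(spec)
      full <- simulate_dyad(spec, dyad_id = ids[d])
      obs <- matrix(runif(T * 4) >= missing_rate, T, 4)
      vals <- full$values
      vals[!obs] <- NA_real_
      s <- dyad_series(ids[d], seq_len(T), vals, obs)
      s <- if (insufficient[d]) corrupt_insufficient(s)
           else ensure_min_rows(s, full$values, needed)
      attr(s, "truth") <- ts
      s
    })
    truth_means[d, ] <- attr(series[[d]], "truth")$means
    truth_sds[d, ] <- attr(series[[d]], "truth")$sds
  }
  truth_df <- data.frame(dyad_id = ids, truth_means, truth_sds)
  names(truth_df) <- c("dyad_id", paste0("mean_", colnames(truth_means)),
                       paste0("sd_", colnames(truth_sds)))
  outcome_spec$seed <- withr::with_seed(seed + 1L,
                                        sample.int(.Machine$integer.max - 1L, 1))
  outcomes <- simulate_outcomes(truth_df, outcome_spec)
  list(series = series, outcomes = outcomes,
       truth = list(summaries = truth_df, insufficient = insufficient))
}

#' Cohort in which dissolution depends on one variability predictor
#'
#' Generates couples whose Male PA -> Female NA cross-lagged coefficient
#' oscillates with a dyad-specific amplitude; relationship dissolution is
#' Bernoulli with log-odds linear in the *true* SD over time of that
#' coefficient (slope `slope`), so end-to-end selection recovery can be
#' scored against ground truth.  All other dynamics are heterogeneous
#' constants.
#'
#' @param n_dyads cohort size.
#' @param T diary length (complete data).
#' @param slope log-odds slope on the true `sd_mpa_fna` predictor.
#' @param seed root seed.
#' @return list with `series`, `outcomes`, and `truth` (`sd_true`, the target
#'   predictor name `target`).
#' @export
scenario_selection_cohort <- function(n_dyads = 200, T = 90, slope = 3,
                                      seed = 1L) {
  withr::with_seed(seed, {
    dyad_seeds <- sample.int(.Machine$integer.max - 1L, n_dyads)
    outcome_seed <- sample.int(.Machine$integer.max - 1L, 1)
  })
  ids <- sprintf("dyad%03d", seq_len(n_dyads))
  series <- vector("list", n_dyads)
  sd_true <- numeric(n_dyads)
  for (d in seq_len(n_dyads)) {
    series[[d]] <- withr::with_seed(dyad_seeds[d], {
      lev <- matrix(rnorm(16, 0, 0.05), 4, 4)
      diag(lev) <- runif(4, 0.1, 0.4)
      cf <- matrix(vector("list", 16), 4, 4)
      for (i in 1:4) for (j in 1:4)
        cf[[i, j]] <- trajectory_spec("constant", level = lev[i, j])
      cf[[2, 3]] <- trajectory_spec("sine", level = lev[2, 3],
                                    amplitude = runif(1, 0, 0.8),
                                    period = 45, phase = runif(1, 0, 2 * pi))
      spec <- simulation_spec(T, intercepts = rep(0, 4), coefficients = cf,
                              innovation_covariance = diag(0.25, 4),
                              seed = sample.int(.Machine$integer.max - 1L, 1))
      s <- simulate_dyad(spec, dyad_id = ids[d])
      attr(s, "sd_true") <- sd(evaluate_trajectory(cf[[2, 3]], T))
      s
    })
    sd_true[d] <- attr(series[[d]], "sd_true")
  }
  b0 <- qlogis(0.35) - slope * 0.28
  outcomes <- withr::with_seed(outcome_seed, {
    data.frame(dyad_id = ids,
               quality_final = rnorm(n_dyads, 5.96, 0.77),
               dissolved = rbinom(n_dyads, 1, plogis(b0 + slope * sd_true)),
               years_together = rlnorm(n_dyads, 0.4, 1.1),
               quality_initial = pmin(pmax(rnorm(n_dyads, 6.26, 0.61), 1), 7),
               stringsAsFactors = FALSE)
  })
  list(series = series, outcomes = outcomes,
       truth = list(sd_true = sd_true, target = "sd_mpa_fna", slope = slope))
}
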