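#' Generative specification for one dyad's TV-VAR(1) process
#'
#' Defines the forward model `y_t = c_t + Phi_t y_{t-1} + eps_t` for a single
#' couple: four intercept trajectories, a 4 x 4 grid of coefficient
#' trajectories (row = response, column = lagged predictor, canonical variable
#' order), a positive semidefinite innovation covariance, and the missingness
#' and clipping rules applied after simulation.
#'
#' @param T number of diary days (>= 2).
#' @param intercepts list of 4 [trajectory_spec()]s, or a numeric 4-vector of
#'   constant intercepts.
#' @param coefficients 4 x 4 list-matrix of [trajectory_spec()]s, or a numeric
#'   4 x 4 matrix of constant coefficients.
#' @param innovation_covariance 4 x 4 symmetric positive semidefinite matrix
#'   (affect-scale units squared).
#' @param initial_state optional numeric 4-vector `y_0`; if `NULL`, the
#'   simulator starts at the (approximate) stationary mean of the day-1
#'   parameters and discards 20 burn-in steps.
#' @param missing_rate per variable-day missing probability in \[0, 1).
#' @param clip_to_likert truncate simulated values to \[1, 5\]. Off by
#'   default: clipping biases coefficient recovery and the estimation model
#'   ignores bounds.
#' @param seed integer seed; identical specs give bit-identical series.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(T, intercepts, coefficients, innovation_covariance,
                            initial_state = NULL, missing_rate = 0,
                            clip_to_likert = FALSE, seed = 1L) {
  stopifnot(T >= 2, missing_rate >= 0, missing_rate < 1)
  if (is.numeric(intercepts)) {
    stopifnot(length(intercepts) == 4)
    intercepts <- lapply(intercepts, as_trajectory)
  }
  stopifnot(length(intercepts) == 4)
  intercepts <- lapply(intercepts, as_trajectory)
  if (is.numeric(coefficients) && is.matrix(coefficients)) {
    stopifnot(all(dim(coefficients) == c(4, 4)))
    cf <- matrix(vector("list", 16), 4, 4)
    for (i in 1:4) for (j in 1:4) cf[[i, j]] <- as_trajectory(coefficients[i, j])
    coefficients <- cf
  }
  stopifnot(is.matrix(coefficients), all(dim(coefficients) == c(4, 4)))
  for (i in 1:4) for (j in 1:4) coefficients[[i, j]] <- as_trajectory(coefficients[[i, j]])
  V <- as.matrix(innovation_covariance)
  stopifnot(all(dim(V) == c(4, 4)))
  if (max(abs(V - t(V))) > 1e-8) stop("innovation_covariance must be symmetric")
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("innovation_covariance must be positive semidefinite")
  if (!is.null(initial_state)) stopifnot(length(initial_state) == 4)
  structure(list(T = as.integer(T), intercepts = intercepts,
                 coefficients = coefficients, innovation_covariance = V,
                 initial_state = initial_state, missing_rate = missing_rate,
                 clip_to_likert = clip_to_likert, seed = as.integer(seed)),
            class = "simulation_spec")
}

# Evaluate the generating parameters on days 1..T.
# Returns list(C = T x 4 intercepts, Phi = T x 4 x 4 array).
eval_generating_params <- function(spec) {
  T <- spec$T
  C <- sapply(spec$intercepts, evaluate_trajectory, T = T)
  Phi <- array(0, c(T, 4, 4))
  for (i in 1:4) for (j in 1:4)
    Phi[, i, j] <- evaluate_trajectory(spec$coefficients[[i, j]], T)
  list(C = matrix(C, nrow = T), Phi = Phi)
}

# True per-parameter trajectory summaries (ground truth for recovery studies):
# mean and sample SD of each of the 16 generating coefficient trajectories.
true_dynamics_summary <- function(spec) {
  p <- eval_generating_params(spec)
  lab <- param_labels()
  vars <- affect_vars()
  means <- sds <- numeric(16)
  for (r in seq_len(16)) {
    i <- match(lab$target[r], vars); j <- match(lab$source[r], vars)
    tr <- p$Phi[, i, j]
    means[r] <- mean(tr); sds[r] <- sd(tr)
  }
  names(means) <- names(sds) <- lab$key
  list(means = means, sds = sds)
}

#' Simulate one dyad's diary series from a TV-VAR(1) process
#'
#' Iterates `y_t = c_t + Phi_t y_{t-1} + eps_t` with Gaussian innovations,
#' optionally clips to the 1-5 affect scale, then masks each variable-day
#' independently with probability `missing_rate`.  The returned series always
#' has a complete day index `1..T`; missingness lives only in the mask.
#'
#' @param spec a [simulation_spec()].
#' @param dyad_id identifier for the returned series.
#' @return a [dyad_series()].
#' @export
simulate_dyad <- function(spec, dyad_id = "dyad") {
  stopifnot(inherits(spec, "simulation_spec"))
  p <- eval_generating_params(spec)
  T <- spec$T
  eg <- eigen((spec$innovation_covariance + t(spec$innovation_covariance)) / 2,
              symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 4)
  const_phi <- all(vapply(spec$coefficients, function(s) s$shape == "constant", TRUE))
  Phi1 <- p$Phi[1, , ]
  if (const_phi && !spec$clip_to_likert) {
    if (max(Mod(eigen(Phi1, only.values = TRUE)$values)) >= 1)
      warning("constant coefficient matrix has spectral radius >= 1; ",
              "the simulated process is non-stationary", call. = FALSE)
  }
  withr::with_seed(spec$seed, {
    if (is.null(spec$initial_state)) {
      y <- tryCatch(solve(diag(4) - Phi1, p$C[1, ]), error = function(e) p$C[1, ])
      if (!all(is.finite(y))) y <- p$C[1, ]
      for (b in seq_len(20)) {
        y <- p$C[1, ] + Phi1 %*% y + L %*% rnorm(4)
        if (spec$clip_to_likert) y <- pmin(pmax(y, 1), 5)
      }
    } else {
      y <- spec$initial_state
    }
    values <- matrix(NA_real_, T, 4)
    for (t in seq_len(T)) {
      y <- p$C[t, ] + p$Phi[t, , ] %*% y + L %*% rnorm(4)
      if (spec$clip_to_likert) y <- pmin(pmax(y, 1), 5)
      values[t, ] <- y
    }
    observed <- matrix(runif(T * 4) >= spec$missing_rate, T, 4)
    values[!observed] <- NA_real_
    dyad_series(dyad_id, seq_len(T), values, observed)
  })
}
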