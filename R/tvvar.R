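#' Build complete lagged design rows from a dyad series
#'
#' A row is emitted for calendar day `t` if and only if day `t - 1` is
#' present in the index, the two days are consecutive calendar days, and all
#' four affect variables are observed on both days (listwise deletion over
#' the full lagged pair; a diary gap breaks the pair because a lag-1 model
#' across a multi-day gap would change the meaning of the coefficients).
#'
#' @param series a [dyad_series()].
#' @return data frame with columns `day` (the response day, the model's time
#'   covariate), `y_f_pa` .. `y_m_na` (responses at day `t`) and
#'   `x_f_pa` .. `x_m_na` (predictors at day `t - 1`).  May have zero rows.
#' @export
build_lagged_rows <- function(series) {
  stopifnot(inherits(series, "dyad_series"))
  d <- series$days
  complete <- rowSums(series$observed) == 4L
  prev <- match(d - 1L, d)
  ok <- !is.na(prev) & complete
  ok[ok] <- complete[prev[ok]]
  use <- which(ok)
  vars <- affect_vars()
  out <- data.frame(day = d[use])
  for (v in seq_len(4)) out[[paste0("y_", vars[v])]] <- series$values[use, v]
  for (v in seq_len(4)) out[[paste0("x_", vars[v])]] <- series$values[prev[use], v]
  out
}

#' Assemble the varying-coefficient design matrix
#'
#' Columns are the intercept-smooth basis followed, for each lagged
#' predictor, by the basis columns multiplied elementwise by that predictor
#' (one block of `k` columns per smooth; with `k = 10` the design has 50
#' columns in 5 blocks).
#'
#' @param rows output of [build_lagged_rows()].
#' @param B n x k basis matrix evaluated at `rows$day`.
#' @return list with `X` (n x 5k design), `blocks` (named list of column
#'   index vectors, `intercept` then `phi_<var>`), and `k`.
#' @export
assemble_varying_coefficient_design <- function(rows, B) {
  stopifnot(nrow(rows) > 0, nrow(B) == nrow(rows))
  k <- ncol(B)
  vars <- affect_vars()
  Xs <- vector("list", 5)
  Xs[[1]] <- B
  for (v in seq_len(4)) Xs[[v + 1]] <- B * rows[[paste0("x_", vars[v])]]
  X <- do.call(cbind, Xs)
  blocks <- lapply(0:4, function(b) seq_len(k) + b * k)
  names(blocks) <- c("intercept", paste0("phi_", vars))
  colnames(X) <- unlist(lapply(names(blocks), function(nm) paste0(nm, ".", seq_len(k))))
  list(X = X, blocks = blocks, k = k)
}

#' Fitting controls for the time-varying VAR
#'
#' @param min_rows minimum number of complete lagged rows for a fit to be
#'   attempted (in addition to the design column count).
#' @param loglambda_grid coarse common-log-lambda grid from which the GCV
#'   polish starts.
#' @param gcv_maxit,gcv_reltol Nelder-Mead budget for the joint 5-dimensional
#'   log-lambda search.
#' @param gcv_gamma degrees-of-freedom cost inflation in the GCV denominator
#'   `(n - gamma * tr A)^2`.  The default 1.4 is the standard correction
#'   against occasional GCV undersmoothing; `gamma = 1` gives plain GCV.
#' @return list of class `tvvar_control`.
#' @export
tvvar_control <- function(min_rows = 30,
                          loglambda_grid = seq(-7, 9, by = 2),
                          gcv_maxit = 250, gcv_reltol = 1e-7,
                          gcv_gamma = 1.4) {
  structure(list(min_rows = as.integer(min_rows),
                 loglambda_grid = loglambda_grid,
                 gcv_maxit = gcv_maxit, gcv_reltol = gcv_reltol,
                 gcv_gamma = gcv_gamma),
            class = "tvvar_control")
}

tvvar_error <- function(msg) {
  stop(structure(class = c("tvvar_nonconvergence", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Solve one penalized varying-coefficient equation at fixed lambdas
#'
#' Minimizes `||y - X alpha||^2 + sum_m lambda_m alpha' S~_m alpha`, where
#' `S~_m` embeds the difference penalty into smooth block `m`, and populates
#' the per-smooth effective degrees of freedom (trace of the corresponding
#' diagonal block of `(X'X + sum lambda S~)^{-1} X'X`), residual variance
#' `rss / (n - total_edf)`, the GCV score, the Bayesian coefficient
#' covariance `sigma2 * (X'X + sum lambda S~)^{-1}`, and approximate
#' per-smooth p-values.
#'
#' @param design output of [assemble_varying_coefficient_design()].
#' @param response numeric response vector.
#' @param lambdas nonnegative smoothing parameters, one per smooth block.
#' @param S k x k penalty matrix (from [build_basis_and_penalty()]).
#' @return object of class `penalized_fit` with fields `coefficients`,
#'   `lambdas`, `edf_per_smooth`, `total_edf`, `rss`, `sigma2`, `gcv`,
#'   `coef_covariance`, `smooth_pvalues`, `n_used`, `blocks`.
#' @export
fit_penalized_equation <- function(design, response, lambdas, S) {
  X <- design$X
  n <- nrow(X)
  stopifnot(length(response) == n, length(lambdas) == length(design$blocks),
            all(lambdas >= 0))
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, response))
  yty <- sum(response^2)
  sol <- pen_fit_cpp(XtX, Xty, yty, n, S, as.numeric(lambdas), TRUE)
  if (!isTRUE(sol$ok))
    tvvar_error("singular penalized normal equations (insufficient data or zero penalty)")
  total_edf <- sol$total_edf
  sigma2 <- if (n - total_edf > 0) sol$rss / (n - total_edf) else NA_real_
  Vb <- if (is.finite(sigma2)) sigma2 * sol$Minv else sol$Minv * NA_real_
  fit <- structure(list(coefficients = setNames(drop(sol$alpha), colnames(X)),
                        lambdas = as.numeric(lambdas),
                        edf_per_smooth = setNames(drop(sol$edf), names(design$blocks)),
                        total_edf = total_edf,
                        rss = sol$rss, sigma2 = sigma2, gcv = sol$gcv,
                        coef_covariance = Vb,
                        smooth_pvalues = NULL,
                        n_used = n, blocks = design$blocks, k = design$k,
                        design_X = X),
                   class = "penalized_fit")
  fit$smooth_pvalues <- setNames(
    vapply(seq_along(design$blocks), function(b) smooth_significance(fit, b), 0.0),
    names(design$blocks))
  fit
}

#' Select smoothing parameters by generalized cross-validation
#'
#' Minimizes `GCV(lambda) = n * RSS(lambda) / (n - gamma * tr A(lambda))^2`
#' jointly over the per-smooth log-smoothing parameters: a coarse
#' common-lambda grid locates a starting point, which Nelder-Mead then
#' polishes.  `gamma` (default 1.4, see [tvvar_control()]) inflates the
#' degrees-of-freedom cost to guard against occasional GCV undersmoothing;
#' `gamma = 1` is the plain GCV score.  Points where `n - gamma * tr A <= 0`
#' or the penalized system is singular score `Inf` and are never selected.
#' Deterministic given its inputs.
#'
#' @inheritParams fit_penalized_equation
#' @param control a [tvvar_control()].
#' @return numeric vector of selected lambdas, one per smooth block.
#' @export
select_lambdas_gcv <- function(design, response, S, control = tvvar_control()) {
  X <- design$X
  n <- nrow(X)
  nb <- length(design$blocks)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, response))
  yty <- sum(response^2)
  score <- function(loglam) pen_gcv_cpp(XtX, Xty, yty, n, S, exp(loglam),
                                        control$gcv_gamma)
  grid <- control$loglambda_grid
  grid_scores <- vapply(grid, function(g) score(rep(g, nb)), 0.0)
  if (all(!is.finite(grid_scores)))
    tvvar_error("GCV objective is infinite everywhere on the starting grid")
  cur <- rep(grid[which.min(grid_scores)], nb)
  cur_score <- min(grid_scores)
  # cyclic per-block coordinate refinement on the grid: catches minima where
  # one smooth wants a very different penalty than the others
  for (sweep in 1:2) {
    for (b in seq_len(nb)) {
      trial <- cur
      for (g in grid) {
        trial[b] <- g
        sc <- score(trial)
        if (sc < cur_score - 1e-12) {
          cur <- trial
          cur_score <- sc
        }
      }
    }
  }
  opt <- optim(cur, score, method = "Nelder-Mead",
               control = list(maxit = control$gcv_maxit,
                              reltol = control$gcv_reltol))
  best <- if (opt$value <= cur_score) opt$par else cur
  exp(best)
}

#' Approximate significance test for one smooth term
#'
#' Wald-type test of the whole smooth being zero, in fitted-value space: the
#' block's contribution to the linear predictor, `f_m = X_m alpha_m`, is
#' referred to its Bayesian covariance `X_m V_m X_m'` through a rank-`r`
#' pseudoinverse with `r = max(1, round(edf_m))`, and `T_m / r` is compared
#' to an F distribution with `(r, n - total_edf)` degrees of freedom.
#' Working in fitted-value space weights coefficient directions by their
#' data support (testing the raw coefficient block against its covariance
#' ranks directions by prior variance instead, which can drop exactly the
#' directions that carry the signal).  A smooth with essentially zero
#' effective degrees of freedom (fully suppressed) returns p = 1.
#'
#' @param fit a `penalized_fit`.
#' @param block smooth index (1 = intercept smooth, 2..5 = lagged predictors).
#' @return p-value in \[0, 1\].
#' @export
smooth_significance <- function(fit, block) {
  edf <- fit$edf_per_smooth[[block]]
  if (!is.finite(edf) || edf < 1e-6) return(1)
  idx <- fit$blocks[[block]]
  a <- fit$coefficients[idx]
  V <- fit$coef_covariance[idx, idx, drop = FALSE]
  if (any(!is.finite(V))) return(NA_real_)
  X <- fit$design_X[, idx, drop = FALSE]
  f <- drop(X %*% a)
  if (max(abs(f)) == 0) {
    return(1)
  }
  # eigenstructure of X V X' via the thin factor X V^{1/2}
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-12
  if (!any(pos)) return(1)
  half <- X %*% (eg$vectors[, pos, drop = FALSE] *
                   rep(sqrt(eg$values[pos]), each = nrow(eg$vectors)))
  sv <- svd(half, nv = 0)
  ev <- sv$d^2
  keep <- ev > max(ev) * 1e-10
  r <- min(max(1L, as.integer(round(edf))), sum(keep))
  if (r < 1) return(1)
  u <- drop(crossprod(sv$u[, seq_len(r), drop = FALSE], f))
  stat <- sum(u^2 / ev[seq_len(r)])
  df2 <- fit$n_used - fit$total_edf
  if (df2 <= 0) return(NA_real_)
  min(1, max(0, pf(stat / r, r, df2, lower.tail = FALSE)))
}

#' Fit a time-varying VAR(1) to one dyad
#'
#' Builds the complete lagged rows, then for each of the four response
#' variables assembles the varying-coefficient design (intercept smooth plus
#' one smooth per lagged predictor), selects smoothing parameters by GCV,
#' solves the penalized equation, and evaluates the intercept and the 16
#' coefficient trajectories on the full daily grid from the first to the
#' last observed day.
#'
#' @param series a [dyad_series()].
#' @param basis a [basis_spec()] (default: cubic P-spline, `k = 10`,
#'   second-order penalty).
#' @param control a [tvvar_control()].
#' @return object of class `tvvar_fit` with fields `dyad_id`,
#'   `equation_fits` (4 `penalized_fit`s), `eval_days`, `intercepts`
#'   (length(eval_days) x 4), `coefficients`
#'   (length(eval_days) x 4 x 4 array, response x lagged predictor),
#'   `n_used`, `converged`, `failure_reason`.  On data insufficiency or a
#'   singular solve the fit is returned with `converged = FALSE` and the
#'   trajectories absent.
#' @export
fit_tvvar <- function(series, basis = basis_spec(), control = tvvar_control()) {
  stopifnot(inherits(series, "dyad_series"), inherits(basis, "basis_spec"))
  rows <- build_lagged_rows(series)
  obs_days <- series$days[rowSums(series$observed) > 0]
  failed <- function(reason) {
    structure(list(dyad_id = series$dyad_id, equation_fits = NULL,
                   eval_days = NULL, intercepts = NULL, coefficients = NULL,
                   n_used = nrow(rows), basis = basis,
                   converged = FALSE, failure_reason = reason),
              class = "tvvar_fit")
  }
  p <- 5L * basis$k
  if (nrow(rows) < max(p, control$min_rows))
    return(failed("insufficient number of timepoints with complete data"))
  eval_days <- seq(min(obs_days), max(obs_days))
  bas <- build_basis_and_penalty(rows$day, basis, day_range = range(eval_days))
  design <- assemble_varying_coefficient_design(rows, bas$B)
  Bev <- bas$eval(eval_days)
  vars <- affect_vars()
  fits <- vector("list", 4)
  intercepts <- matrix(NA_real_, length(eval_days), 4,
                       dimnames = list(NULL, vars))
  coefs <- array(NA_real_, c(length(eval_days), 4, 4),
                 dimnames = list(NULL, vars, vars))
  for (v in seq_len(4)) {
    y <- rows[[paste0("y_", vars[v])]]
    fit_v <- tryCatch({
      lam <- select_lambdas_gcv(design, y, bas$S, control)
      fit_penalized_equation(design, y, lam, bas$S)
    }, tvvar_nonconvergence = function(e) e)
    if (inherits(fit_v, "condition")) return(failed(conditionMessage(fit_v)))
    fits[[v]] <- fit_v
    intercepts[, v] <- Bev %*% fit_v$coefficients[design$blocks$intercept]
    for (u in seq_len(4)) {
      coefs[, v, u] <- Bev %*% fit_v$coefficients[design$blocks[[u + 1]]]
    }
  }
  names(fits) <- vars
  structure(list(dyad_id = series$dyad_id, equation_fits = fits,
                 eval_days = eval_days, intercepts = intercepts,
                 coefficients = coefs, n_used = nrow(rows), basis = basis,
                 converged = TRUE, failure_reason = NULL),
            class = "tvvar_fit")
}

#' @export
print.tvvar_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<tvvar_fit %s: %d complete rows, days %d..%d, converged>\n",
                x$dyad_id, x$n_used, min(x$eval_days), max(x$eval_days)))
  } else {
    cat(sprintf("<tvvar_fit %s: not converged (%s)>\n",
                x$dyad_id, x$failure_reason))
  }
  invisible(x)
}
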