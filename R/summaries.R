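#' Reduce a fitted TV-VAR to per-parameter summaries
#'
#' Computes the mean and sample standard deviation (denominator `n - 1`) of
#' each of the 16 estimated coefficient trajectories over the full daily
#' evaluation grid, and flags a dynamic parameter as time-varying when its
#' smooth is statistically significant at level `alpha` *and* its effective
#' degrees of freedom exceed 2 (both conditions are required: significance
#' marks the smooth as important to the model, edf > 2 marks it as
#' non-linear in time).
#'
#' @param fit a converged [fit_tvvar()] object.
#' @param alpha significance level for the smooth tests (default 0.05).
#' @return object of class `dynamics_summary` with fields `dyad_id`,
#'   `labels` (16 display labels in fixed reporting order), `keys`, `means`,
#'   `sds`, `timevarying_flags`, `n_timevarying`.
#' @export
summarize_dynamics <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "tvvar_fit"), alpha > 0, alpha < 1)
  if (!fit$converged)
    stop("cannot summarize a non-converged fit (", fit$failure_reason, ")")
  lab <- param_labels()
  vars <- affect_vars()
  means <- sds <- numeric(16)
  flags <- logical(16)
  for (r in seq_len(16)) {
    resp <- match(lab$target[r], vars)
    pred <- match(lab$source[r], vars)
    traj <- fit$coefficients[, resp, pred]
    means[r] <- mean(traj)
    sds[r] <- sd(traj)
    eq <- fit$equation_fits[[resp]]
    block <- pred + 1L  # block 1 is the intercept smooth
    flags[r] <- isTRUE(eq$smooth_pvalues[[block]] < alpha) &&
      eq$edf_per_smooth[[block]] > 2
  }
  structure(list(dyad_id = fit$dyad_id, labels = lab$label, keys = lab$key,
                 means = setNames(means, lab$key),
                 sds = setNames(sds, lab$key),
                 timevarying_flags = setNames(flags, lab$key),
                 n_timevarying = sum(flags), alpha = alpha),
            class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf("<dynamics_summary %s: %d of 16 parameters time-varying>\n",
              x$dyad_id, x$n_timevarying))
  invisible(x)
}

#' Flatten dynamics summaries to a data frame
#'
#' @param summaries list of `dynamics_summary` objects.
#' @return data frame with `dyad_id`, 16 `mean_*`, 16 `sd_*`, 16 `tv_*`
#'   columns and `n_timevarying`.
#' @export
summaries_to_df <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  rows <- lapply(summaries, function(s) {
    stopifnot(inherits(s, "dynamics_summary"))
    out <- c(list(dyad_id = s$dyad_id),
             as.list(setNames(s$means, paste0("mean_", s$keys))),
             as.list(setNames(s$sds, paste0("sd_", s$keys))),
             as.list(setNames(as.integer(s$timevarying_flags),
                              paste0("tv_", s$keys))),
             list(n_timevarying = s$n_timevarying))
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort-level descriptive table of dynamics summaries
#'
#' Produces the 32-row descriptive table (16 parameter means and 16
#' parameter variabilities, each summarized across dyads by mean, SD, min
#' and max) together with the distribution of the number of time-varying
#' parameters per dyad.  Invariant under permutation of the input order.
#'
#' @param summaries list of `dynamics_summary` objects (>= 1).
#' @return object of class `cohort_table`: list with `table` (32-row data
#'   frame), `n_timevarying` (named count table) and `n_dyads`.
#' @export
tabulate_cohort <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  lab <- param_labels()
  M <- t(vapply(summaries, function(s) s$means, numeric(16)))
  S <- t(vapply(summaries, function(s) s$sds, numeric(16)))
  ntv <- vapply(summaries, function(s) s$n_timevarying, integer(1))
  one <- function(x, statistic) {
    data.frame(statistic = statistic, parameter = lab$label,
               mean = apply(x, 2, mean),
               sd = if (nrow(x) > 1) apply(x, 2, sd) else rep(0, 16),
               min = apply(x, 2, min), max = apply(x, 2, max),
               stringsAsFactors = FALSE)
  }
  tab <- rbind(one(M, "mean"), one(S, "variability"))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 n_timevarying = table(factor(ntv, levels = 0:16)),
                 n_dyads = length(summaries)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table: %d dyads; median time-varying parameters %.0f>\n",
              x$n_dyads,
              median(rep(as.integer(names(x$n_timevarying)), x$n_timevarying))))
  print(x$table, digits = 3)
  invisible(x)
}
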