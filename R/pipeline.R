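#' Configuration for a full cohort analysis run
#'
#' @param input_series path to the stacked dyad diary CSV (see
#'   [read_dyad_csv()]), or a list of [dyad_series()] objects.
#' @param input_outcomes path to the outcomes CSV (see
#'   [read_outcomes_csv()]), or an outcome data frame.
#' @param output_dir optional directory for the run artifacts (summaries,
#'   trajectories, fit metadata, model reports, log); nothing is written when
#'   `NULL`.
#' @param k,penalty_order,knot_placement basis settings ([basis_spec()]).
#' @param alpha significance level for the time-varying flag.
#' @param min_rows convergence floor on complete lagged rows.
#' @param min_days_inclusion minimum diary days (with any recorded value)
#'   for a dyad to enter the analysis at all; couples below the floor are
#'   excluded before fitting.
#' @param stepwise_criterion `"aic"` or `"pvalue"`.
#' @param seed root seed echoed into the log (the analysis itself is
#'   deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(input_series, input_outcomes, output_dir = NULL,
                       k = 10, penalty_order = 2, knot_placement = "even",
                       alpha = 0.05, min_rows = 30, min_days_inclusion = 50,
                       stepwise_criterion = c("aic", "pvalue"), seed = 1L) {
  stopifnot(min_days_inclusion >= 2, alpha > 0, alpha < 1)
  structure(list(input_series = input_series, input_outcomes = input_outcomes,
                 output_dir = output_dir,
                 basis = basis_spec(k = k, penalty_order = penalty_order,
                                    knot_placement = knot_placement),
                 alpha = alpha, min_rows = min_rows,
                 min_days_inclusion = min_days_inclusion,
                 stepwise_criterion = match.arg(stepwise_criterion),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full dyadic dynamics analysis pipeline
#'
#' Reads the cohort, applies the diary-length inclusion floor, fits a TV-VAR
#' per dyad, summarizes the dynamic-parameter trajectories, and relates the
#' summaries to relationship quality (stepwise linear regression) and
#' dissolution (stepwise logistic regression), with covariate-adjusted
#' refits.  Dyads whose fit fails to converge are excluded listwise from the
#' outcome models.  Reruns with identical config and inputs produce
#' byte-identical artifacts.
#'
#' @param config a [run_config()].
#' @return object of class `tvvar_report`: counts (`n_input`, `n_excluded`,
#'   `n_converged`, `n_failed`), per-dyad `status` data frame, `summaries`
#'   data frame, `cohort_table`, fitted `models` (quality / dissolution plus
#'   `*_adjusted`), and the `log` lines.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  series <- if (is.character(config$input_series))
    read_dyad_csv(config$input_series) else config$input_series
  outcomes <- if (is.character(config$input_outcomes))
    read_outcomes_csv(config$input_outcomes) else config$input_outcomes
  if (inherits(series, "dyad_series")) series <- list(series)
  n_input <- length(series)
  log_lines <- c(sprintf("run_pipeline: %d dyads, k=%d, alpha=%g, min_rows=%d, floor=%d days, criterion=%s, seed=%d",
                         n_input, config$basis$k, config$alpha, config$min_rows,
                         config$min_days_inclusion, config$stepwise_criterion,
                         config$seed))
  control <- tvvar_control(min_rows = config$min_rows)
  status <- data.frame(dyad_id = character(0), status = character(0),
                       reason = character(0), n_used = integer(0),
                       seconds = numeric(0), stringsAsFactors = FALSE)
  fits <- list()
  for (s in series) {
    t0 <- proc.time()[["elapsed"]]
    nd <- n_observed_days(s)
    if (nd < config$min_days_inclusion) {
      status <- rbind(status, data.frame(
        dyad_id = s$dyad_id, status = "excluded",
        reason = "below inclusion floor", n_used = NA_integer_,
        seconds = proc.time()[["elapsed"]] - t0, stringsAsFactors = FALSE))
      next
    }
    fit <- fit_tvvar(s, config$basis, control)
    status <- rbind(status, data.frame(
      dyad_id = s$dyad_id,
      status = if (fit$converged) "converged" else "failed",
      reason = if (fit$converged) "" else fit$failure_reason,
      n_used = fit$n_used,
      seconds = proc.time()[["elapsed"]] - t0, stringsAsFactors = FALSE))
    if (fit$converged) fits[[s$dyad_id]] <- fit
  }
  n_excluded <- sum(status$status == "excluded")
  n_failed <- sum(status$status == "failed")
  n_converged <- length(fits)
  log_lines <- c(log_lines,
                 sprintf("excluded %d, converged %d, failed %d",
                         n_excluded, n_converged, n_failed),
                 sprintf("dyad %s: %s %s (%.2fs)", status$dyad_id,
                         status$status, status$reason, status$seconds))
  if (n_converged == 0) stop("no dyad's TV-VAR fit converged; aborting run")
  summaries <- lapply(fits, summarize_dynamics, alpha = config$alpha)
  sdf <- summaries_to_df(summaries)
  cohort <- tabulate_cohort(summaries)
  dat <- outcome_dataset(sdf, outcomes)
  safe_model <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      log_lines <<- c(log_lines, sprintf("model %s failed: %s", label,
                                         conditionMessage(e)))
      structure(list(label = label, message = conditionMessage(e)),
                class = "outcome_model_error")
    })
  }
  models <- list()
  models$quality <- safe_model("quality",
    stepwise_select(dat, "quality", config$stepwise_criterion))
  models$quality_adjusted <- safe_model("quality_adjusted",
    if (inherits(models$quality, "outcome_model"))
      adjusted_refit(dat, models$quality) else stop("prior model unavailable"))
  models$dissolution <- safe_model("dissolution",
    stepwise_select(dat, "dissolution", config$stepwise_criterion))
  models$dissolution_adjusted <- safe_model("dissolution_adjusted",
    if (inherits(models$dissolution, "outcome_model"))
      adjusted_refit(dat, models$dissolution) else stop("prior model unavailable"))
  report <- structure(list(n_input = n_input, n_excluded = n_excluded,
                           n_converged = n_converged, n_failed = n_failed,
                           status = status, summaries = sdf,
                           cohort_table = cohort, models = models,
                           fits = fits, config = config, log = log_lines),
                      class = "tvvar_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

model_report_df <- function(m) {
  tab <- data.frame(term = names(m$coefficients), b = m$coefficients,
                    se = m$standard_errors, statistic = m$test_statistics,
                    p = m$p_values, stringsAsFactors = FALSE)
  if (!is.null(m$odds_ratios)) tab$odds_ratio <- m$odds_ratios
  rownames(tab) <- NULL
  tab
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$summaries, file.path(dir, "summaries.csv"), row.names = FALSE)
  write.csv(report$status, file.path(dir, "fit_status.csv"), row.names = FALSE)
  write.csv(report$cohort_table$table, file.path(dir, "cohort_table.csv"),
            row.names = FALSE)
  traj <- do.call(rbind, lapply(report$fits, trajectories_to_df))
  write.csv(traj, file.path(dir, "trajectories.csv"), row.names = FALSE)
  meta <- do.call(rbind, lapply(report$fits, fit_metadata_df))
  write.csv(meta, file.path(dir, "fit_metadata.csv"), row.names = FALSE)
  for (nm in names(report$models)) {
    if (!inherits(report$models[[nm]], "outcome_model")) next
    write.csv(model_report_df(report$models[[nm]]),
              file.path(dir, paste0("model_", nm, ".csv")), row.names = FALSE)
  }
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Flatten fitted trajectories to a data frame
#'
#' One row per evaluation day: `dyad_id`, `eval_day`, the 4 intercepts
#' (`c_<var>`) and the 16 coefficients (`phi_<target>_<source>`, response by
#' lagged predictor).
#'
#' @param fit a converged `tvvar_fit`.
#' @return data frame.
#' @export
trajectories_to_df <- function(fit) {
  stopifnot(fit$converged)
  vars <- affect_vars()
  out <- data.frame(dyad_id = fit$dyad_id, eval_day = fit$eval_days)
  for (v in seq_len(4)) out[[paste0("c_", vars[v])]] <- fit$intercepts[, v]
  for (v in seq_len(4)) for (u in seq_len(4))
    out[[paste0("phi_", vars[v], "_", vars[u])]] <- fit$coefficients[, v, u]
  rownames(out) <- NULL
  out
}

fit_metadata_df <- function(fit) {
  rows <- lapply(seq_len(4), function(v) {
    eq <- fit$equation_fits[[v]]
    data.frame(dyad_id = fit$dyad_id, response = affect_vars()[v],
               smooth = names(eq$blocks), lambda = eq$lambdas,
               edf = unname(eq$edf_per_smooth),
               p_value = unname(eq$smooth_pvalues),
               n_used = eq$n_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.tvvar_report <- function(x, ...) {
  cat(sprintf("<tvvar_report: %d dyads in; %d excluded, %d converged, %d failed>\n",
              x$n_input, x$n_excluded, x$n_converged, x$n_failed))
  invisible(x)
}
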