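#' Join dynamics summaries and outcomes into one modelling dataset
#'
#' @param summaries list of `dynamics_summary` objects or a data frame from
#'   [summaries_to_df()].
#' @param outcomes data frame with `dyad_id`, `quality_final`, `dissolved`,
#'   `years_together`, `quality_initial`.
#' @return data frame keyed by `dyad_id` with the 32 summary predictors and
#'   the outcome columns; only dyads present in both inputs are kept.
#' @export
outcome_dataset <- function(summaries, outcomes) {
  sdf <- if (is.data.frame(summaries)) summaries else summaries_to_df(summaries)
  out <- merge(sdf, outcomes, by = "dyad_id", sort = TRUE)
  rownames(out) <- NULL
  out
}

outcome_column <- function(outcome) {
  switch(outcome, quality = "quality_final", dissolution = "dissolved",
         stop("unknown outcome: ", outcome))
}

model_formula <- function(ycol, terms) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  as.formula(paste(ycol, "~", rhs))
}

new_outcome_result <- function(outcome, terms, fit, data, extras) {
  sm <- summary(fit)
  ct <- sm$coefficients
  res <- c(list(outcome = outcome, selected_terms = terms,
                coefficients = ct[, 1], standard_errors = ct[, 2],
                test_statistics = ct[, 3], p_values = ct[, 4],
                n = nrow(data), model = fit),
           extras)
  structure(res, class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("<outcome_model (%s): %d terms, n = %d>\n",
              x$outcome, length(x$selected_terms), x$n))
  tab <- data.frame(b = x$coefficients, SE = x$standard_errors,
                    statistic = x$test_statistics, p = x$p_values)
  if (!is.null(x$odds_ratios)) tab$odds_ratio <- x$odds_ratios
  print(round(tab, 4))
  if (x$outcome == "quality") {
    cat(sprintf("R-squared: %.4f\n", x$r_squared))
  } else {
    cat(sprintf("Cox & Snell R2: %.4f  Nagelkerke R2: %.4f  accuracy: %.1f%%\n",
                x$cox_snell_r2, x$nagelkerke_r2, 100 * x$classification_accuracy))
  }
  invisible(x)
}

#' Linear model for relationship quality
#'
#' Least-squares fit of final relationship quality on the given terms, with
#' coefficient table, R-squared, and both an F and a likelihood-ratio
#' comparison against the intercept-only model.
#'
#' @param data an [outcome_dataset()].
#' @param terms character vector of predictor column names (may be empty for
#'   the null model).
#' @param outcome_col response column (default `"quality_final"`).
#' @return an `outcome_model`.
#' @export
fit_linear <- function(data, terms = character(0), outcome_col = "quality_final") {
  fml <- model_formula(outcome_col, terms)
  fit <- lm(fml, data = data)
  if (anyNA(coef(fit)))
    stop("rank-deficient linear model; collinear terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  sm <- summary(fit)
  null_fit <- lm(model_formula(outcome_col, character(0)), data = data)
  ll1 <- as.numeric(logLik(fit)); ll0 <- as.numeric(logLik(null_fit))
  df <- length(terms)
  fstat <- if (df > 0) sm$fstatistic else NULL
  extras <- list(
    r_squared = sm$r.squared,
    null_comparison = list(
      f_statistic = if (df > 0) unname(fstat[1]) else 0,
      f_df = if (df > 0) unname(fstat[2:3]) else c(0, fit$df.residual),
      f_pvalue = if (df > 0) unname(pf(fstat[1], fstat[2], fstat[3],
                                       lower.tail = FALSE)) else 1,
      lr_statistic = 2 * (ll1 - ll0), lr_df = df,
      lr_pvalue = if (df > 0) pchisq(2 * (ll1 - ll0), df, lower.tail = FALSE) else 1))
  new_outcome_result("quality", terms, fit, data, extras)
}

#' Logistic model for relationship dissolution
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of the
#' dissolution indicator on the given terms: coefficient table with Wald z
#' statistics, odds ratios, classification accuracy at threshold 0.5,
#' Cox & Snell and Nagelkerke pseudo R-squared, and a likelihood-ratio
#' comparison against the intercept-only model.
#'
#' @inheritParams fit_linear
#' @param outcome_col response column (default `"dissolved"`, coded 0/1).
#' @return an `outcome_model`.
#' @export
fit_logistic <- function(data, terms = character(0), outcome_col = "dissolved") {
  fml <- model_formula(outcome_col, terms)
  fit <- suppressWarnings(glm(fml, data = data, family = binomial()))
  probs <- fitted(fit)
  if (length(terms) && (any(probs < 1e-8) || any(probs > 1 - 1e-8))) {
    suspects <- names(which(abs(coef(fit)[-1]) > 10))
    if (!length(suspects)) suspects <- terms
    stop("perfect separation in logistic model; separating term(s): ",
         paste(suspects, collapse = ", "))
  }
  if (!fit$converged)
    stop("logistic fit did not converge after maximum iterations; final deviance ",
         format(fit$deviance))
  y <- data[[outcome_col]]
  n <- nrow(data)
  null_fit <- glm(model_formula(outcome_col, character(0)), data = data,
                  family = binomial())
  ll1 <- as.numeric(logLik(fit)); ll0 <- as.numeric(logLik(null_fit))
  cs <- 1 - exp(-2 * (ll1 - ll0) / n)
  cs_max <- 1 - exp(2 * ll0 / n)
  extras <- list(
    odds_ratios = exp(coef(fit)),
    classification_accuracy = mean((probs > 0.5) == (y == 1)),
    cox_snell_r2 = cs,
    nagelkerke_r2 = if (cs_max > 0) cs / cs_max else 0,
    null_comparison = list(lr_statistic = 2 * (ll1 - ll0),
                           lr_df = length(terms),
                           lr_pvalue = if (length(terms))
                             pchisq(2 * (ll1 - ll0), length(terms),
                                    lower.tail = FALSE) else 1))
  new_outcome_result("dissolution", terms, fit, data, extras)
}

fit_outcome <- function(data, terms, outcome) {
  if (outcome == "quality") fit_linear(data, terms) else fit_logistic(data, terms)
}

outcome_criterion <- function(data, terms, outcome, criterion) {
  ycol <- outcome_column(outcome)
  fml <- model_formula(ycol, terms)
  fit <- if (outcome == "quality") lm(fml, data = data)
         else suppressWarnings(glm(fml, data = data, family = binomial()))
  if (anyNA(coef(fit))) return(Inf)
  if (outcome == "dissolution" && length(terms)) {
    pr <- fitted(fit)
    if (any(pr < 1e-8) || any(pr > 1 - 1e-8)) return(Inf)  # separation
  }
  AIC(fit)
}

#' Bidirectional stepwise selection of dynamics-summary predictors
#'
#' Starting from the intercept-only model, each step evaluates every
#' single-term addition and removal, applies the best criterion-improving
#' move, and stops when no move improves the criterion.  With
#' `criterion = "aic"` (the default) the criterion is AIC and the procedure
#' is fully deterministic, ties broken by lexicographic term name (removals
#' preferred over additions on exact ties).  With `criterion = "pvalue"`
#' forward steps add the smallest-p term below `p_enter` and backward steps
#' drop the largest-p term above `p_remove`.
#'
#' @param data an [outcome_dataset()].
#' @param outcome `"quality"` (linear) or `"dissolution"` (logistic).
#' @param criterion `"aic"` or `"pvalue"`.
#' @param candidates candidate predictor columns (default: the 32 summary
#'   predictors present in `data`, sorted).
#' @param p_enter,p_remove entry/stay thresholds for the p-value mode.
#' @param max_terms cap on the selected-model size; defaults to `n %/% 3` so
#'   that small cohorts cannot be fit to saturation (additions stop at the
#'   cap, removals are always allowed).
#' @return an `outcome_model` for the final refit, with the selection
#'   `path` (data frame of accepted moves and criterion values) attached.
#' @export
stepwise_select <- function(data, outcome = c("quality", "dissolution"),
                            criterion = c("aic", "pvalue"),
                            candidates = NULL, p_enter = 0.05, p_remove = 0.10,
                            max_terms = NULL) {
  outcome <- match.arg(outcome)
  criterion <- match.arg(criterion)
  if (is.null(candidates))
    candidates <- sort(intersect(predictor_names(), names(data)))
  stopifnot(length(candidates) >= 1)
  if (is.null(max_terms)) max_terms <- max(1L, nrow(data) %/% 3L)
  selected <- character(0)
  if (criterion == "aic") {
    current <- outcome_criterion(data, selected, outcome, criterion)
    path <- data.frame(move = "<start>", term = "", criterion = current,
                       stringsAsFactors = FALSE)
    repeat {
      drops <- sort(selected)
      adds <- if (length(selected) < max_terms)
        sort(setdiff(candidates, selected)) else character(0)
      moves <- rbind(
        if (length(drops)) data.frame(move = "drop", term = drops,
                                      stringsAsFactors = FALSE),
        if (length(adds)) data.frame(move = "add", term = adds,
                                     stringsAsFactors = FALSE))
      if (is.null(moves) || !nrow(moves)) break
      moves$criterion <- vapply(seq_len(nrow(moves)), function(i) {
        terms <- if (moves$move[i] == "drop") setdiff(selected, moves$term[i])
                 else c(selected, moves$term[i])
        tryCatch(outcome_criterion(data, terms, outcome, criterion),
                 error = function(e) Inf)
      }, 0.0)
      best <- which.min(moves$criterion)  # first minimum: drops, then adds, lexicographic
      if (!is.finite(moves$criterion[best]) ||
          moves$criterion[best] >= current - 1e-8) break
      current <- moves$criterion[best]
      selected <- if (moves$move[best] == "drop") setdiff(selected, moves$term[best])
                  else c(selected, moves$term[best])
      path <- rbind(path, moves[best, c("move", "term", "criterion")])
    }
  } else {
    path <- data.frame(move = character(0), term = character(0),
                       criterion = numeric(0), stringsAsFactors = FALSE)
    repeat {
      changed <- FALSE
      adds <- if (length(selected) < max_terms)
        sort(setdiff(candidates, selected)) else character(0)
      if (length(adds)) {
        pvals <- vapply(adds, function(tm) {
          tryCatch(fit_outcome(data, c(selected, tm), outcome)$p_values[[tm]],
                   error = function(e) 1)
        }, 0.0)
        if (min(pvals) < p_enter) {
          tm <- adds[which.min(pvals)]
          selected <- c(selected, tm)
          path <- rbind(path, data.frame(move = "add", term = tm,
                                         criterion = min(pvals)))
          changed <- TRUE
        }
      }
      if (length(selected)) {
        fit <- fit_outcome(data, selected, outcome)
        pv <- fit$p_values[selected]
        if (max(pv) > p_remove) {
          tm <- selected[which.max(pv)]
          selected <- setdiff(selected, tm)
          path <- rbind(path, data.frame(move = "drop", term = tm,
                                         criterion = max(pv)))
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  result <- fit_outcome(data, sort(selected), outcome)
  result$path <- path
  result$criterion <- criterion
  result
}

#' Covariate-adjusted refit of a selected outcome model
#'
#' Refits the previously selected terms (no re-selection) with the control
#' covariates added.
#'
#' @param data an [outcome_dataset()].
#' @param prior_result an `outcome_model` from [stepwise_select()] or a fit
#'   function.
#' @param covariates covariate columns to adjoin (default time in
#'   relationship and initial quality).
#' @return an `outcome_model`.
#' @export
adjusted_refit <- function(data, prior_result,
                           covariates = c("years_together", "quality_initial")) {
  stopifnot(inherits(prior_result, "outcome_model"))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stop("covariates absent from data: ", paste(missing_cov, collapse = ", "))
  terms <- unique(c(prior_result$selected_terms, covariates))
  fit_outcome(data, terms, prior_result$outcome)
}
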