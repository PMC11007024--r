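#' Generative specification for relationship outcomes
#'
#' The forward direction of the outcome step of the pipeline: final
#' relationship quality is a linear function of dynamics-summary predictors
#' plus Gaussian noise, and dissolution is Bernoulli with log-odds linear in
#' the predictors.  Slope names must be drawn from the 32 predictor names
#' ([predictor_names()]).
#'
#' @param quality_intercept intercept of the quality model (1-7 scale).
#' @param quality_slopes named numeric vector of slopes on summary predictors.
#' @param quality_noise_sd residual SD of quality (>= 0).
#' @param dissolution_intercept intercept on the log-odds scale.  The default
#'   `qlogis(0.23)` reproduces the observed base rate of roughly 23% of
#'   couples dissolving by follow-up.
#' @param dissolution_slopes named numeric vector of log-odds slopes.
#' @param covariate_generators named list of functions of `n` generating the
#'   covariates `years_together` and `quality_initial`.
#' @param seed integer seed.
#' @return an object of class `outcome_gen_spec`.
#' @export
outcome_gen_spec <- function(quality_intercept = 5.96,
                             quality_slopes = numeric(0),
                             quality_noise_sd = 0.77,
                             dissolution_intercept = qlogis(0.23),
                             dissolution_slopes = numeric(0),
                             covariate_generators = list(
                               years_together = function(n) rlnorm(n, meanlog = 0.4, sdlog = 1.1),
                               quality_initial = function(n) pmin(pmax(rnorm(n, 6.26, 0.61), 1), 7)),
                             seed = 1L) {
  stopifnot(quality_noise_sd >= 0)
  check_slopes <- function(sl, what) {
    if (length(sl) == 0) return(invisible())
    bad <- setdiff(names(sl), predictor_names())
    if (is.null(names(sl)) || any(!nzchar(names(sl))) || length(bad))
      stop(sprintf("unknown %s predictor label(s): %s", what,
                   paste(bad, collapse = ", ")))
  }
  check_slopes(quality_slopes, "quality")
  check_slopes(dissolution_slopes, "dissolution")
  structure(list(quality_intercept = quality_intercept,
                 quality_slopes = quality_slopes,
                 quality_noise_sd = quality_noise_sd,
                 dissolution_intercept = dissolution_intercept,
                 dissolution_slopes = dissolution_slopes,
                 covariate_generators = covariate_generators,
                 seed = as.integer(seed)),
            class = "outcome_gen_spec")
}

#' Simulate relationship outcomes from dynamics summaries
#'
#' @param summaries a list of `dynamics_summary` objects, or a data frame
#'   containing `dyad_id` plus the 32 summary predictor columns.
#' @param spec an [outcome_gen_spec()].
#' @return data frame with columns `dyad_id`, `quality_final`, `dissolved`,
#'   `years_together`, `quality_initial`.
#' @export
simulate_outcomes <- function(summaries, spec = outcome_gen_spec()) {
  stopifnot(inherits(spec, "outcome_gen_spec"))
  df <- if (is.data.frame(summaries)) summaries else summaries_to_df(summaries)
  n <- nrow(df)
  lincomb <- function(slopes) {
    out <- rep(0, n)
    for (nm in names(slopes)) {
      if (!nm %in% names(df)) stop("predictor column missing from summaries: ", nm)
      out <- out + slopes[[nm]] * df[[nm]]
    }
    out
  }
  withr::with_seed(spec$seed, {
    quality <- spec$quality_intercept + lincomb(spec$quality_slopes) +
      rnorm(n, sd = spec$quality_noise_sd)
    pdiss <- plogis(spec$dissolution_intercept + lincomb(spec$dissolution_slopes))
    dissolved <- rbinom(n, 1, pdiss)
    years <- spec$covariate_generators$years_together(n)
    q0 <- spec$covariate_generators$quality_initial(n)
    data.frame(dyad_id = df$dyad_id, quality_final = quality,
               dissolved = dissolved, years_together = years,
               quality_initial = q0, stringsAsFactors = FALSE)
  })
}
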