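#' Canonical affect variable order and dynamic-parameter labels
#'
#' All four-variable objects in the package use one fixed variable order:
#' female positive affect, female negative affect, male positive affect,
#' male negative affect (`"f_pa"`, `"f_na"`, `"m_pa"`, `"m_na"`).  The 16
#' dynamic parameters (entries of the lag-1 coefficient matrix) are labelled
#' `"source -> target"`, where the source is the lagged predictor and the
#' target the response, and are reported in a fixed order: targets grouped as
#' Male PA, Male NA, Female PA, Female NA, and within each target the sources
#' in canonical variable order.
#'
#' @return `affect_vars()` returns the four variable codes in canonical
#'   order.  `param_labels()` returns a 16-row data frame with columns
#'   `source`, `target` (variable codes), `key` (machine label used in CSV
#'   column names, e.g. `"fpa_mpa"`), and `label` (display label, e.g.
#'   `"Female PA -> Male PA"`).
#' @examples
#' affect_vars()
#' head(param_labels())
#' @export
affect_vars <- function() c("f_pa", "f_na", "m_pa", "m_na")

#' @rdname affect_vars
#' @export
affect_var_names <- function() {
  c(f_pa = "Female PA", f_na = "Female NA", m_pa = "Male PA", m_na = "Male NA")
}

#' @rdname affect_vars
#' @export
param_labels <- function() {
  vars <- affect_vars()
  disp <- affect_var_names()
  targets <- c("m_pa", "m_na", "f_pa", "f_na")
  out <- do.call(rbind, lapply(targets, function(tg) {
    data.frame(source = vars, target = tg, stringsAsFactors = FALSE)
  }))
  out$key <- paste0(sub("_", "", out$source), "_", sub("_", "", out$target))
  out$label <- paste(disp[out$source], "->", disp[out$target])
  rownames(out) <- NULL
  out
}

#' Names of the 32 dynamics-summary predictors
#'
#' Mean and standard-deviation summaries of each of the 16 dynamic-parameter
#' trajectories, as used in the outcome regressions.
#'
#' @return character vector of 32 column names (`mean_*` then `sd_*`, in
#'   parameter-label order).
#' @export
predictor_names <- function() {
  keys <- param_labels()$key
  c(paste0("mean_", keys), paste0("sd_", keys))
}
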