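#' One couple's daily diary affect record
#'
#' Container for a single dyad's four affect series (female PA, female NA,
#' male PA, male NA) on the composite 1-5 affect scale, with an explicit
#' day index and missingness mask.  Unobserved cells are stored as `NA` in
#' `values` and `FALSE` in `observed`.
#'
#' @param dyad_id identifier (coerced to character).
#' @param days strictly increasing integer day index.
#' @param values numeric matrix, `length(days)` x 4, columns in canonical
#'   variable order ([affect_vars()]).
#' @param observed logical matrix of the same shape; defaults to
#'   `!is.na(values)`.
#' @param likert if `TRUE`, observed values are checked to lie in \[1, 5\].
#' @return an object of class `dyad_series` with elements `dyad_id`, `days`,
#'   `values`, `observed`.
#' @export
dyad_series <- function(dyad_id, days, values, observed = NULL, likert = FALSE) {
  days <- as.integer(days)
  values <- as.matrix(values)
  if (ncol(values) != 4) stop("values must have 4 columns (f_pa, f_na, m_pa, m_na)")
  if (nrow(values) != length(days)) stop("values must have one row per day")
  if (anyDuplicated(days)) stop("duplicate day in index: ",
                                paste(unique(days[duplicated(days)]), collapse = ", "))
  if (is.unsorted(days, strictly = TRUE)) stop("days must be strictly increasing")
  if (is.null(observed)) observed <- !is.na(values)
  observed <- as.matrix(observed)
  if (!identical(dim(observed), dim(values))) stop("observed mask shape mismatch")
  if (any(observed & !is.finite(values)))
    stop("values must be finite wherever observed")
  if (likert && any(observed & (values < 1 | values > 5)))
    stop("likert series must have observed values in [1, 5]")
  values[!observed] <- NA_real_
  colnames(values) <- colnames(observed) <- affect_vars()
  structure(list(dyad_id = as.character(dyad_id), days = days,
                 values = values, observed = observed),
            class = "dyad_series")
}

#' @export
print.dyad_series <- function(x, ...) {
  n_obs <- sum(x$observed)
  cat(sprintf("<dyad_series %s: days %d..%d (%d rows), %.1f%% cells observed>\n",
              x$dyad_id, min(x$days), max(x$days), length(x$days),
              100 * n_obs / length(x$observed)))
  invisible(x)
}

#' @export
as.data.frame.dyad_series <- function(x, ...) {
  data.frame(dyad_id = x$dyad_id, day = x$days,
             as.data.frame(x$values), stringsAsFactors = FALSE)
}

# Number of diary days with at least one recorded value (inclusion-floor count).
n_observed_days <- function(series) sum(rowSums(series$observed) > 0)
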