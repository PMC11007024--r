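#' Read and write dyad diary CSV files
#'
#' The canonical cohort format is a stacked wide CSV with columns `dyad_id`,
#' `day`, `f_pa`, `f_na`, `m_pa`, `m_na`; a single-dyad file may omit
#' `dyad_id`.  Empty cells are missing observations.  Writing then reading
#' reproduces values and mask exactly.
#'
#' @param path file path.
#' @return `read_dyad_csv()` returns a named list of [dyad_series()] (one
#'   element per dyad, in file order).
#' @export
read_dyad_csv <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  vars <- affect_vars()
  need <- c("day", vars)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"dyad_id" %in% names(raw)) raw$dyad_id <- "dyad1"
  num <- function(col, what) {
    x <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(x))
    bad <- which(nzchar(x) & is.na(out))
    if (length(bad))
      stop(sprintf("%s: non-numeric %s value '%s' at data row %d",
                   path, what, x[bad[1]], bad[1]))
    out
  }
  day <- num("day", "day")
  if (any(is.na(day))) stop(path, ": empty day cell at data row ", which(is.na(day))[1])
  vals <- matrix(NA_real_, nrow(raw), 4, dimnames = list(NULL, vars))
  for (v in vars) vals[, v] <- num(v, "affect")
  out <- list()
  for (id in unique(raw$dyad_id)) {
    idx <- which(raw$dyad_id == id)
    d <- day[idx]
    if (anyDuplicated(d))
      stop(sprintf("%s: duplicate day %d for dyad %s", path,
                   as.integer(d[duplicated(d)][1]), id))
    ord <- order(d)
    out[[id]] <- dyad_series(id, d[ord], vals[idx[ord], , drop = FALSE])
  }
  out
}

#' @rdname read_dyad_csv
#' @param series a [dyad_series()] or list of them.
#' @export
write_dyad_csv <- function(series, path) {
  if (inherits(series, "dyad_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write the per-dyad outcome table
#'
#' Columns: `dyad_id`, `quality_final`, `dissolved` (0/1), `years_together`,
#' `quality_initial`.
#'
#' @param path file path.
#' @return data frame of outcome rows.
#' @export
read_outcomes_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dyad_id", "quality_final", "dissolved", "years_together",
            "quality_initial")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols))
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(out$dyad_id))
    stop(path, ": duplicate dyad_id ", out$dyad_id[duplicated(out$dyad_id)][1])
  if (!all(out$dissolved %in% c(0, 1)))
    stop(path, ": dissolved must be coded 0/1")
  out$dyad_id <- as.character(out$dyad_id)
  out
}

#' @rdname read_outcomes_csv
#' @param outcomes outcome data frame.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  write.csv(outcomes, path, row.names = FALSE, na = "")
  invisible(path)
}
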