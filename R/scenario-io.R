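#' Read and write simulation scenario configuration files
#'
#' A scenario file is YAML mirroring the [simulation_spec()] fields: `T`,
#' `seed`, `missing_rate`, `clip_to_likert`, optional `initial_state`,
#' `innovation_covariance` (list of 4 rows), `intercepts` (list of 4
#' trajectory specs) and `coefficients` (list of 16 trajectory specs in
#' row-major response-by-predictor order).  Each trajectory spec is a map
#' with a `shape` key plus that shape's parameters, e.g.
#' `{shape: sine, level: 0, amplitude: 0.4, period: 40, phase: 0}`.
#'
#' @param path file path.
#' @return `read_simulation_spec()` returns a [simulation_spec()];
#'   `write_simulation_spec()` invisibly returns `path`.
#' @export
read_simulation_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("T", "intercepts", "coefficients", "innovation_covariance")
  missing_fields <- setdiff(need, names(cfg))
  if (length(missing_fields))
    stop(path, ": missing scenario field(s): ",
         paste(missing_fields, collapse = ", "))
  traj <- function(x) {
    if (is.numeric(x) && length(x) == 1) return(as_trajectory(x))
    do.call(trajectory_spec, x)
  }
  intercepts <- lapply(cfg$intercepts, traj)
  if (length(cfg$coefficients) != 16)
    stop(path, ": coefficients must list 16 trajectory specs (row-major)")
  cf <- matrix(vector("list", 16), 4, 4)
  for (i in 1:4) for (j in 1:4)
    cf[[i, j]] <- traj(cfg$coefficients[[(i - 1) * 4 + j]])
  V <- do.call(rbind, lapply(cfg$innovation_covariance, as.numeric))
  simulation_spec(T = cfg$T, intercepts = intercepts, coefficients = cf,
                  innovation_covariance = V,
                  initial_state = cfg$initial_state,
                  missing_rate = cfg$missing_rate %||% 0,
                  clip_to_likert = isTRUE(cfg$clip_to_likert),
                  seed = cfg$seed %||% 1L)
}

#' @rdname read_simulation_spec
#' @param spec a [simulation_spec()].
#' @export
write_simulation_spec <- function(spec, path) {
  stopifnot(inherits(spec, "simulation_spec"))
  traj_out <- function(tr) Filter(Negate(is.null), unclass(tr))
  cfg <- list(
    T = spec$T, seed = spec$seed, missing_rate = spec$missing_rate,
    clip_to_likert = spec$clip_to_likert,
    initial_state = spec$initial_state,
    innovation_covariance = lapply(seq_len(4), function(i)
      as.numeric(spec$innovation_covariance[i, ])),
    intercepts = lapply(spec$intercepts, traj_out),
    coefficients = lapply(seq_len(16), function(r) {
      i <- (r - 1) %/% 4 + 1; j <- (r - 1) %% 4 + 1
      traj_out(spec$coefficients[[i, j]])
    }))
  yaml::write_yaml(Filter(Negate(is.null), cfg), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
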