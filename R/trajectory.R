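#' Parameter trajectory specifications
#'
#' A trajectory specification describes how one generating parameter of the
#' time-varying VAR (an intercept or an entry of the lag-1 coefficient
#' matrix) evolves over the diary period.  Supported shapes:
#'
#' * `constant`: `level` at every day.
#' * `linear`: `level + delta * (t - 1) / (T - 1)`, a ramp whose total change
#'   over the period is `delta`.
#' * `sine`: `level + amplitude * sin(2 * pi * (t - 1) / period + phase)`.
#' * `sigmoid`: `level + delta / (1 + exp(-steepness * (t - midpoint)))`, a
#'   smooth switch of size `delta` centred at `midpoint` days.
#' * `grid`: an arbitrary sequence `grid_values` of length `T`.
#'
#' @param shape one of `"constant"`, `"linear"`, `"sine"`, `"sigmoid"`,
#'   `"grid"`.
#' @param level baseline value (the constant value for `shape = "constant"`).
#' @param delta total change (linear / sigmoid shapes).
#' @param amplitude sine amplitude.
#' @param period sine period in days; must be positive.
#' @param phase sine phase in radians.
#' @param midpoint sigmoid midpoint in days.
#' @param steepness sigmoid steepness (1/days); must be positive.
#' @param grid_values numeric vector of explicit values (`grid` shape only).
#' @return an object of class `trajectory_spec`.
#' @examples
#' evaluate_trajectory(trajectory_spec("linear", level = 0, delta = 1), 11)
#' @export
trajectory_spec <- function(shape = c("constant", "linear", "sine", "sigmoid", "grid"),
                            level = 0, delta = 0, amplitude = 0,
                            period = NULL, phase = 0,
                            midpoint = NULL, steepness = NULL,
                            grid_values = NULL) {
  shape <- match.arg(shape)
  if (shape == "sine") {
    if (is.null(period) || period <= 0) stop("sine shape requires period > 0")
  }
  if (shape == "sigmoid") {
    if (is.null(steepness) || steepness <= 0) stop("sigmoid shape requires steepness > 0")
    if (is.null(midpoint)) stop("sigmoid shape requires a midpoint")
  }
  if (shape == "grid" && is.null(grid_values)) stop("grid shape requires grid_values")
  structure(list(shape = shape, level = level, delta = delta,
                 amplitude = amplitude, period = period, phase = phase,
                 midpoint = midpoint, steepness = steepness,
                 grid_values = grid_values),
            class = "trajectory_spec")
}

#' Evaluate a trajectory on days 1..T
#'
#' @param spec a [trajectory_spec()].
#' @param T integer number of days (>= 1).
#' @return numeric vector of length `T` with the parameter value at each day.
#' @export
evaluate_trajectory <- function(spec, T) {
  stopifnot(inherits(spec, "trajectory_spec"), T >= 1)
  t <- seq_len(T)
  switch(spec$shape,
    constant = rep(spec$level, T),
    linear = if (T == 1) spec$level else spec$level + spec$delta * (t - 1) / (T - 1),
    sine = spec$level + spec$amplitude * sin(2 * pi * (t - 1) / spec$period + spec$phase),
    sigmoid = spec$level + spec$delta / (1 + exp(-spec$steepness * (t - spec$midpoint))),
    grid = {
      if (length(spec$grid_values) != T)
        stop(sprintf("grid_values has length %d but T = %d",
                     length(spec$grid_values), T))
      as.numeric(spec$grid_values)
    })
}

# Coerce a numeric scalar (or trajectory_spec) to a trajectory_spec.
as_trajectory <- function(x) {
  if (inherits(x, "trajectory_spec")) return(x)
  if (is.numeric(x) && length(x) == 1) return(trajectory_spec("constant", level = x))
  stop("expected a trajectory_spec or a single number")
}
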