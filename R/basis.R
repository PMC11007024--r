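#' Spline basis specification for time-varying coefficients
#'
#' Each time-varying intercept and coefficient is expanded in `k` B-spline
#' basis functions of (rescaled) calendar day with a difference penalty on
#' the basis coefficients (a P-spline).  The default is a cubic B-spline
#' basis of dimension 10 with a first-order difference penalty.  The
#' first-order penalty's null space is the constant function, so (i) the
#' stationary, constant-in-time part of a coefficient is never shrunk, and
#' (ii) an effectively constant coefficient is smoothed down to about one
#' effective degree of freedom, which makes the `edf > 2` time-varying
#' detection rule a genuine non-constancy criterion.  A second-order
#' penalty (affine null space, edf floor 2) is available via
#' `penalty_order = 2`.
#'
#' @param family basis family.  Only `"bspline_psline"` is implemented; the
#'   other enum values are reserved.
#' @param k basis dimension (>= 3; the spline degree is `min(3, k - 1)`).
#' @param penalty_order difference order of the penalty, 1 or 2.
#' @param knot_placement `"even"` (default) or `"quantile"` interior knots.
#' @return an object of class `basis_spec`.
#' @export
basis_spec <- function(family = c("bspline_psline", "cubic_regression", "thinplate"),
                       k = 10, penalty_order = 1,
                       knot_placement = c("even", "quantile")) {
  family <- match.arg(family)
  knot_placement <- match.arg(knot_placement)
  if (family != "bspline_psline")
    stop("basis family '", family, "' is reserved but not implemented")
  stopifnot(k >= 3, penalty_order %in% c(1, 2))
  structure(list(family = family, k = as.integer(k),
                 penalty_order = as.integer(penalty_order),
                 knot_placement = knot_placement),
            class = "basis_spec")
}

#' Build the spline basis and wiggliness penalty
#'
#' Evaluates the `k` B-spline basis functions at the design days (after an
#' affine map of the observed day span to \[0, 1\] for conditioning) and
#' returns the `k x k` difference penalty.  The penalty is symmetric positive
#' semidefinite; its null space contains the constant coefficient sequence
#' (and, for `penalty_order = 2`, linear sequences).
#'
#' @param days_used numeric vector of design days (>= 2 values).
#' @param spec a [basis_spec()].
#' @param day_range optional day span used for the affine rescaling (defaults
#'   to `range(days_used)`); pass the full observed span so that design rows
#'   and evaluation grids share one mapping.
#' @return a list of class `tv_basis` with elements `B` (n x k basis matrix),
#'   `S` (k x k penalty), the knot layout, and an `eval(days)` closure
#'   evaluating the same basis at new days.
#' @export
build_basis_and_penalty <- function(days_used, spec = basis_spec(),
                                    day_range = NULL) {
  if (length(days_used) < 2) stop("insufficient data: need at least 2 design points")
  if (is.null(day_range)) day_range <- range(days_used)
  span <- diff(day_range)
  if (span <= 0) stop("insufficient data: degenerate day span")
  k <- spec$k
  degree <- min(3L, k - 1L)
  n_interior <- k - degree - 1L
  interior <- if (n_interior > 0) {
    if (spec$knot_placement == "even") {
      seq(0, 1, length.out = n_interior + 2)[-c(1, n_interior + 2)]
    } else {
      x <- (days_used - day_range[1]) / span
      as.numeric(quantile(x, probs = seq_len(n_interior) / (n_interior + 1),
                          type = 7, names = FALSE))
    }
  } else numeric(0)
  eval_basis <- function(days) {
    x <- (days - day_range[1]) / span
    B <- splines::bs(x, knots = interior, degree = degree, intercept = TRUE,
                     Boundary.knots = c(0, 1))
    B <- matrix(as.numeric(B), nrow = length(x))
    colnames(B) <- paste0("b", seq_len(ncol(B)))
    B
  }
  D <- diff(diag(k), differences = spec$penalty_order)
  S <- crossprod(D)
  structure(list(B = eval_basis(days_used), S = S, k = k, degree = degree,
                 interior_knots = interior, day_range = day_range,
                 eval = eval_basis, spec = spec),
            class = "tv_basis")
}
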