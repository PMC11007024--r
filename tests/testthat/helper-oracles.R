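# Independent oracles used across the test suite.  These deliberately avoid
# the package's own solver paths: dense base-R linear algebra and textbook
# recursions only.

# Dense generalized-ridge solve: minimizes ||y - X a||^2 + sum_b lambda_b a' S~_b a
# with S embedded blockwise (blocks of k consecutive columns).
oracle_ridge_solve <- function(X, y, lambdas, S) {
  k <- ncol(S)
  p <- ncol(X)
  P <- matrix(0, p, p)
  for (b in seq_along(lambdas)) {
    idx <- (b - 1) * k + seq_len(k)
    P[idx, idx] <- P[idx, idx] + lambdas[b] * S
  }
  solve(crossprod(X) + P, crossprod(X, y))
}

# Definitional GCV via the explicit influence matrix A = X (X'X + P)^{-1} X'.
oracle_gcv <- function(X, y, lambdas, S) {
  k <- ncol(S)
  p <- ncol(X)
  P <- matrix(0, p, p)
  for (b in seq_along(lambdas)) {
    idx <- (b - 1) * k + seq_len(k)
    P[idx, idx] <- P[idx, idx] + lambdas[b] * S
  }
  A <- X %*% solve(crossprod(X) + P, t(X))
  n <- nrow(X)
  rss <- sum((y - A %*% y)^2)
  n * rss / (n - sum(diag(A)))^2
}

# Textbook Cox-de Boor recursion for one B-spline basis function.
deboor_one <- function(x, knots, degree, i) {
  if (degree == 0) return(as.numeric(x >= knots[i] & x < knots[i + 1]))
  left <- 0
  if (knots[i + degree] > knots[i])
    left <- (x - knots[i]) / (knots[i + degree] - knots[i]) *
      deboor_one(x, knots, degree - 1, i)
  right <- 0
  if (knots[i + degree + 1] > knots[i + 1])
    right <- (knots[i + degree + 1] - x) / (knots[i + degree + 1] - knots[i + 1]) *
      deboor_one(x, knots, degree - 1, i + 1)
  left + right
}

deboor_basis <- function(x, interior, degree) {
  knots <- c(rep(0, degree + 1), interior, rep(1, degree + 1))
  k <- length(knots) - degree - 1
  vapply(seq_len(k), function(i) deboor_one(x, knots, degree, i), numeric(length(x)))
}

# Random small varying-coefficient problem built with the package's own
# assembly (the solver under test never sees how lambdas are chosen here).
random_toy_problem <- function(seed) {
  set.seed(seed)
  k <- sample(3:6, 1)
  n <- sample((5 * k + 2):40, 1)
  days <- sort(sample(1:(3 * n), n))
  rows <- data.frame(day = days)
  for (v in affect_vars()) rows[[paste0("x_", v)]] <- rnorm(n)
  bas <- build_basis_and_penalty(rows$day, basis_spec(k = k))
  des <- assemble_varying_coefficient_design(rows, bas$B)
  y <- rnorm(n)
  lambdas <- 10^runif(5, -2, 4)
  list(design = des, y = y, lambdas = lambdas, S = bas$S, k = k, n = n)
}

# Synthetic outcome-modelling dataset: 32 noise predictors plus outcomes,
# optionally with signal injected by the caller afterwards.
synthetic_outcome_data <- function(n, seed = 1) {
  set.seed(seed)
  df <- data.frame(dyad_id = sprintf("d%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (nm in predictor_names()) df[[nm]] <- rnorm(n)
  df$years_together <- rlnorm(n, 0.4, 1.1)
  df$quality_initial <- rnorm(n, 6.3, 0.6)
  df$quality_final <- rnorm(n, 5.9, 0.8)
  df$dissolved <- rbinom(n, 1, 0.23)
  df
}

# A fabricated converged tvvar_fit with fully controlled trajectories and
# smooth statistics, for testing the summary layer in isolation.
fake_tvvar_fit <- function(coefs, pvals = matrix(1, 4, 4),
                           edfs = matrix(1, 4, 4), dyad_id = "fake") {
  n_days <- dim(coefs)[1]
  eqs <- lapply(1:4, function(v) {
    list(smooth_pvalues = c(1, pvals[v, ]), edf_per_smooth = c(1, edfs[v, ]))
  })
  names(eqs) <- affect_vars()
  structure(list(dyad_id = dyad_id, equation_fits = eqs,
                 eval_days = seq_len(n_days), intercepts = matrix(0, n_days, 4),
                 coefficients = coefs, n_used = n_days, converged = TRUE,
                 failure_reason = NULL),
            class = "tvvar_fit")
}
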