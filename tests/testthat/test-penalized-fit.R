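test_that("zero penalty reproduces unpenalized least squares", {
  toy <- random_toy_problem(11)
  fit <- fit_penalized_equation(toy$design, toy$y, rep(0, 5), toy$S)
  ls <- qr.coef(qr(toy$design$X), toy$y)
  expect_equal(unname(fit$coefficients), unname(ls), tolerance = 1e-8)
  expect_equal(fit$total_edf, ncol(toy$design$X), tolerance = 1e-6)
})

test_that("penalized solve matches the dense generalized-ridge oracle", {
  for (seed in 1:10) {
    toy <- random_toy_problem(seed)
    fit <- fit_penalized_equation(toy$design, toy$y, toy$lambdas, toy$S)
    oracle <- oracle_ridge_solve(toy$design$X, toy$y, toy$lambdas, toy$S)
    expect_lt(max(abs(fit$coefficients - drop(oracle))), 1e-8)
  }
})

test_that("a 12-row k=4 toy at unit lambdas matches the oracle", {
  set.seed(4)
  rows <- data.frame(day = sort(sample(1:40, 12)))
  for (v in affect_vars()) rows[[paste0("x_", v)]] <- rnorm(12)
  bas <- build_basis_and_penalty(rows$day, basis_spec(k = 4))
  des <- assemble_varying_coefficient_design(rows, bas$B)
  y <- rnorm(12)
  fit <- fit_penalized_equation(des, y, rep(1, 5), bas$S)
  oracle <- oracle_ridge_solve(des$X, y, rep(1, 5), bas$S)
  expect_lt(max(abs(fit$coefficients - drop(oracle))), 1e-8)
})

test_that("total edf equals the influence-matrix trace and bounds hold", {
  for (seed in c(2, 21)) {
    toy <- random_toy_problem(seed)
    fit <- fit_penalized_equation(toy$design, toy$y, toy$lambdas, toy$S)
    P <- matrix(0, ncol(toy$design$X), ncol(toy$design$X))
    for (b in 1:5) {
      idx <- toy$design$blocks[[b]]
      P[idx, idx] <- P[idx, idx] + toy$lambdas[b] * toy$S
    }
    A <- toy$design$X %*% solve(crossprod(toy$design$X) + P, t(toy$design$X))
    expect_lt(abs(fit$total_edf - sum(diag(A))), 1e-8)
    expect_equal(fit$total_edf, sum(fit$edf_per_smooth), tolerance = 1e-8)
    expect_true(all(fit$edf_per_smooth >= -1e-10))
    expect_true(all(fit$edf_per_smooth <= lengths(toy$design$blocks) + 1e-10))
  }
})

test_that("per-block edf is non-increasing in that block's lambda", {
  toy <- random_toy_problem(33)
  for (b in c(1, 3)) {
    lam <- rep(5, 5)
    edfs <- vapply(10^seq(-2, 6, by = 1), function(l) {
      lam[b] <- l
      fit_penalized_equation(toy$design, toy$y, lam, toy$S)$edf_per_smooth[[b]]
    }, 0.0)
    expect_true(all(diff(edfs) <= 1e-8))
  }
})

test_that("infinite smoothing with a first-order penalty collapses to the OLS VAR", {
  s <- simulate_dyad(scenario_constant(T = 80, seed = 8), "d")
  rows <- build_lagged_rows(s)
  bas <- build_basis_and_penalty(rows$day, basis_spec(k = 10, penalty_order = 1))
  des <- assemble_varying_coefficient_design(rows, bas$B)
  Bev <- bas$eval(rows$day)
  for (v in c(1, 3)) {
    y <- rows[[paste0("y_", affect_vars()[v])]]
    fit <- fit_penalized_equation(des, y, rep(1e12, 5), bas$S)
    ols <- coef(lm(y ~ rows$x_f_pa + rows$x_f_na + rows$x_m_pa + rows$x_m_na))
    for (b in 2:5) {
      traj <- drop(Bev %*% fit$coefficients[des$blocks[[b]]])
      expect_lt(max(abs(traj - ols[b])), 1e-4)   # flat at the OLS value
    }
  }
})

test_that("infinite smoothing with a second-order penalty leaves the affine null space", {
  s <- simulate_dyad(scenario_constant(T = 80, seed = 9), "d")
  rows <- build_lagged_rows(s)
  bas <- build_basis_and_penalty(rows$day, basis_spec(k = 10, penalty_order = 2))
  des <- assemble_varying_coefficient_design(rows, bas$B)
  fit <- fit_penalized_equation(des, rows$y_f_na, rep(1e9, 5), bas$S)
  # the selected coefficient sequence collapses to the penalty null space:
  # linear in the basis index, i.e. vanishing second differences
  a <- fit$coefficients[des$blocks$phi_f_na]
  expect_lt(max(abs(diff(diff(a)))), 1e-6 * max(abs(a)))
  expect_equal(fit$edf_per_smooth[["phi_f_na"]], 2, tolerance = 1e-3)
})

test_that("a singular penalty-free system raises a labelled non-convergence error", {
  toy <- random_toy_problem(17)
  small <- toy$design
  keep <- seq_len(ncol(small$X) - 5)  # fewer rows than columns
  small$X <- small$X[seq_len(10), ]
  expect_error(
    fit_penalized_equation(small, toy$y[seq_len(10)], rep(0, 5), toy$S),
    class = "tvvar_nonconvergence")
})
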