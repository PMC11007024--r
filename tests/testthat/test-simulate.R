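test_that("noise-free fixed point: zero dynamics reproduce the intercepts", {
  spec <- simulation_spec(T = 30, intercepts = c(3, 1.5, 3.5, 1.2),
                          coefficients = matrix(0, 4, 4),
                          innovation_covariance = matrix(0, 4, 4), seed = 7)
  s <- simulate_dyad(spec)
  for (t in 2:30)
    expect_equal(unname(s$values[t, ]), c(3, 1.5, 3.5, 1.2))
})

test_that("identical specs give bit-identical series", {
  spec <- scenario_constant(T = 60, seed = 99)
  a <- simulate_dyad(spec, "x")
  b <- simulate_dyad(spec, "x")
  expect_identical(a, b)
})

test_that("OLS on a long simulated series recovers the generating matrix", {
  Phi <- matrix(c(0.4, 0.1, 0, 0.1,
                  -0.2, 0.3, 0.1, 0,
                  0.1, 0, 0.35, -0.1,
                  0, 0.15, 0, 0.25), 4, 4, byrow = TRUE)
  expect_lt(max(Mod(eigen(Phi)$values)), 0.6)
  spec <- simulation_spec(T = 2000, intercepts = rep(0, 4), coefficients = Phi,
                          innovation_covariance = diag(0.25, 4), seed = 123)
  s <- simulate_dyad(spec)
  rows <- build_lagged_rows(s)
  for (v in 1:4) {
    f <- lm(rows[[paste0("y_", affect_vars()[v])]] ~
              rows$x_f_pa + rows$x_f_na + rows$x_m_pa + rows$x_m_na)
    est <- coef(f)[-1]
    se <- coef(summary(f))[-1, 2]
    expect_true(all(abs(est - Phi[v, ]) < 3 * se),
                info = paste("equation", v))
  }
})

test_that("missingness mask hits its nominal rate and keeps the day index", {
  spec <- scenario_constant(T = 10000, seed = 5)
  spec$missing_rate <- 0.04
  s <- simulate_dyad(spec)
  frac <- mean(!s$observed)
  expect_gt(frac, 0.035)
  expect_lt(frac, 0.045)
  expect_identical(s$days, 1:10000)
  expect_equal(nrow(s$values), 10000)
})

test_that("long-run sample mean matches the stationary mean (I - Phi)^-1 c", {
  Phi <- diag(0.3, 4); Phi[1, 3] <- 0.2
  cvec <- c(2.4, 1.0, 2.5, 0.9)
  spec <- simulation_spec(T = 5000, intercepts = cvec, coefficients = Phi,
                          innovation_covariance = diag(0.16, 4), seed = 31)
  s <- simulate_dyad(spec)
  mu <- solve(diag(4) - Phi, cvec)
  for (v in 1:4) {
    x <- s$values[, v]
    # MC standard error of the mean of an AR(1)-ish series
    se <- sd(x) / sqrt(length(x)) * sqrt((1 + 0.3) / (1 - 0.3))
    expect_lt(abs(mean(x) - mu[v]), 3 * se)
  }
})

test_that("unstable constant dynamics trigger a stationarity warning", {
  spec <- simulation_spec(T = 20, intercepts = rep(0, 4),
                          coefficients = diag(1.05, 4),
                          innovation_covariance = diag(0.01, 4), seed = 2)
  expect_warning(simulate_dyad(spec), "spectral radius")
})

test_that("clipping keeps simulated values on the 1-5 scale", {
  spec <- scenario_constant(T = 200, seed = 3)
  spec$clip_to_likert <- TRUE
  s <- simulate_dyad(spec)
  expect_true(all(s$values >= 1 & s$values <= 5))
})

test_that("simulation_spec rejects invalid covariances", {
  bad <- matrix(0.5, 4, 4); bad[1, 2] <- 9
  expect_error(simulation_spec(10, rep(0, 4), matrix(0, 4, 4), bad), "symmetric")
  neg <- diag(c(1, 1, 1, -0.5))
  expect_error(simulation_spec(10, rep(0, 4), matrix(0, 4, 4), neg),
               "semidefinite")
})
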