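complete_series <- function(T, seed = 1) {
  simulate_dyad(scenario_constant(T = T, seed = seed), "d")
}

test_that("complete data loses exactly one row to the lag", {
  s <- complete_series(60)
  expect_equal(nrow(build_lagged_rows(s)), 59)
})

test_that("one missing cell removes both lag pairs it touches", {
  s <- complete_series(60)
  s$observed[30, 2] <- FALSE
  s$values[30, 2] <- NA
  rows <- build_lagged_rows(s)
  expect_equal(nrow(rows), 57)
  expect_false(any(rows$day %in% c(30, 31)))
})

test_that("a calendar gap breaks the lag pair", {
  s <- complete_series(4)
  # keep days 1, 2, 4: day 4 has no day-3 predecessor
  keep <- c(1, 2, 4)
  s2 <- dyad_series("d", keep, s$values[keep, ], s$observed[keep, ])
  rows <- build_lagged_rows(s2)
  expect_equal(rows$day, 2)
})

test_that("lagged rows carry response at t and predictors at t-1", {
  s <- complete_series(10)
  rows <- build_lagged_rows(s)
  expect_equal(rows$y_f_pa, s$values[2:10, 1])
  expect_equal(rows$x_m_na, s$values[1:9, 4])
})

test_that("varying-coefficient design has one k-block per smooth", {
  s <- complete_series(80)
  rows <- build_lagged_rows(s)
  bas <- build_basis_and_penalty(rows$day, basis_spec(k = 10))
  des <- assemble_varying_coefficient_design(rows, bas$B)
  expect_equal(ncol(des$X), 50)
  expect_length(des$blocks, 5)
  expect_true(all(lengths(des$blocks) == 10))
  # block columns equal basis times the lagged predictor, elementwise
  for (r in c(1, 3, nrow(rows)))
    expect_equal(unname(des$X[r, des$blocks$phi_m_pa]),
                 unname(bas$B[r, ] * rows$x_m_pa[r]))
  # intercept block is the raw basis
  expect_equal(des$X[, des$blocks$intercept], bas$B, ignore_attr = TRUE)
})

test_that("a zero lagged predictor zeroes its design block", {
  s <- complete_series(40)
  rows <- build_lagged_rows(s)
  rows$x_f_na <- 0
  bas <- build_basis_and_penalty(rows$day, basis_spec(k = 6))
  des <- assemble_varying_coefficient_design(rows, bas$B)
  expect_true(all(des$X[, des$blocks$phi_f_na] == 0))
})
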