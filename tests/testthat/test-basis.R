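test_that("B-spline basis is a partition of unity with k columns", {
  days <- 1:60
  bas <- build_basis_and_penalty(days, basis_spec(k = 10))
  expect_equal(ncol(bas$B), 10)
  expect_equal(rowSums(bas$B), rep(1, 60))
  # also at arbitrary evaluation points, including the boundaries
  Bev <- bas$eval(c(1, 17.5, 60))
  expect_equal(rowSums(Bev), rep(1, 3))
})

test_that("difference penalties annihilate their null spaces", {
  bas1 <- build_basis_and_penalty(1:40, basis_spec(k = 8, penalty_order = 1))
  const <- rep(2.5, 8)
  expect_equal(drop(t(const) %*% bas1$S %*% const), 0)
  bas2 <- build_basis_and_penalty(1:40, basis_spec(k = 8, penalty_order = 2))
  lin <- 0.3 + 0.7 * seq_len(8)  # linear-in-index coefficient sequence
  expect_equal(drop(t(lin) %*% bas2$S %*% lin), 0)
  expect_gt(drop(t(lin) %*% bas1$S %*% lin), 0)
  # penalties are symmetric positive semidefinite
  for (S in list(bas1$S, bas2$S)) {
    expect_equal(S, t(S))
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  }
})

test_that("basis values match the textbook de Boor recursion", {
  days <- 1:50
  bas <- build_basis_and_penalty(days, basis_spec(k = 9))
  x <- c(0.12, 0.35, 0.5, 0.71, 0.93)  # interior points on the mapped scale
  oracle <- deboor_basis(x, bas$interior_knots, bas$degree)
  ours <- bas$eval(1 + x * 49)
  expect_equal(ours, oracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("quantile knot placement follows the design days", {
  days <- c(1:10, 40:60)  # uneven density
  bas <- build_basis_and_penalty(days, basis_spec(k = 10, knot_placement = "quantile"))
  expect_equal(ncol(bas$B), 10)
  expect_equal(rowSums(bas$B), rep(1, length(days)))
  expect_false(isTRUE(all.equal(
    bas$interior_knots,
    build_basis_and_penalty(days, basis_spec(k = 10))$interior_knots)))
})

test_that("degenerate inputs are rejected", {
  expect_error(build_basis_and_penalty(5, basis_spec()), "insufficient")
  expect_error(build_basis_and_penalty(c(3, 3), basis_spec()), "insufficient")
  expect_error(basis_spec(k = 2), "k >= 3")
  expect_error(basis_spec(family = "thinplate"), "reserved")
})
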