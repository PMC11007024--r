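make_coefs <- function(T = 101, fill = 0) array(fill, c(T, 4, 4))

test_that("constant and linear trajectories summarize to closed forms", {
  coefs <- make_coefs(101, 0.3)
  # Female PA -> Female NA: response f_na (2), source f_pa (1), linear 0 -> 1
  coefs[, 2, 1] <- seq(0, 1, length.out = 101)
  su <- summarize_dynamics(fake_tvvar_fit(coefs))
  expect_equal(unname(su$means[su$keys == "mpa_mpa"]), 0.3)
  expect_equal(unname(su$sds[su$keys == "mpa_mpa"]), 0)
  i <- which(su$keys == "fpa_fna")
  expect_equal(unname(su$means[i]), 0.5)
  # closed form: sqrt(sum((x - 0.5)^2) / 100) on the equally spaced grid
  expect_equal(unname(su$sds[i]), sqrt(85850) / 1000, tolerance = 1e-12)
  expect_equal(unname(su$sds[i]), 0.2930, tolerance = 1e-4)
})

test_that("the time-varying flag needs significance AND edf > 2", {
  pv <- matrix(1, 4, 4); ed <- matrix(1, 4, 4)
  pv[2, 1] <- 0.01; ed[2, 1] <- 1.4   # significant but effectively linear
  pv[3, 4] <- 0.20; ed[3, 4] <- 3.5   # wiggly but not significant
  pv[1, 2] <- 0.01; ed[1, 2] <- 2.6   # both conditions hold
  su <- summarize_dynamics(fake_tvvar_fit(make_coefs(), pv, ed))
  expect_false(su$timevarying_flags[["fpa_fna"]])
  expect_false(su$timevarying_flags[["mna_mpa"]])
  expect_true(su$timevarying_flags[["fna_fpa"]])
  expect_equal(su$n_timevarying, 1L)
})

test_that("flags are monotone in alpha", {
  set.seed(21)
  pv <- matrix(runif(16), 4, 4); ed <- matrix(runif(16, 1, 4), 4, 4)
  fit <- fake_tvvar_fit(make_coefs(), pv, ed)
  grid <- c(0.01, 0.05, 0.1, 0.3)
  flags <- lapply(grid, function(a) summarize_dynamics(fit, a)$timevarying_flags)
  for (i in seq_along(grid)[-1])
    expect_true(all(flags[[i - 1]] <= flags[[i]]))
})

test_that("summaries refuse non-converged fits", {
  bad <- structure(list(dyad_id = "x", converged = FALSE,
                        failure_reason = "insufficient number of timepoints"),
                   class = "tvvar_fit")
  expect_error(summarize_dynamics(bad), "non-converged")
})

test_that("cohort table aggregates across dyads in fixed label order", {
  c1 <- make_coefs(51, 0); c1[, 2, 3] <- 0.1  # Male PA -> Female NA
  c2 <- make_coefs(51, 0); c2[, 2, 3] <- 0.3
  s1 <- summarize_dynamics(fake_tvvar_fit(c1, dyad_id = "a"))
  s2 <- summarize_dynamics(fake_tvvar_fit(c2, dyad_id = "b"))
  tab <- tabulate_cohort(list(s1, s2))
  expect_equal(nrow(tab$table), 32)
  row <- tab$table[tab$table$statistic == "mean" &
                     tab$table$parameter == "Male PA -> Female NA", ]
  expect_equal(row$mean, 0.2)
  expect_equal(row$min, 0.1)
  expect_equal(row$max, 0.3)
  # single dyad: across-dyad SD column is all zero
  tab1 <- tabulate_cohort(list(s1))
  expect_true(all(tab1$table$sd == 0))
  # permutation invariance
  expect_identical(tab$table, tabulate_cohort(list(s2, s1))$table)
})

test_that("label order follows the fixed reporting convention", {
  lab <- param_labels()
  expect_equal(lab$label[1], "Female PA -> Male PA")
  expect_equal(lab$label[3], "Male PA -> Male PA")
  expect_equal(lab$label[16], "Male NA -> Female NA")
  expect_equal(nrow(lab), 16)
  expect_length(predictor_names(), 32)
})
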