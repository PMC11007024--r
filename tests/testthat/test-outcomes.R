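test_that("an exact line is recovered exactly", {
  d <- synthetic_outcome_data(40, 2)
  d$quality_final <- 2 + 3 * d$mean_fpa_fpa
  m <- suppressWarnings(fit_linear(d, "mean_fpa_fpa"))  # exact fit warns in summary.lm
  expect_equal(unname(m$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(m$r_squared, 1)
})

test_that("linear coefficients match a hand normal-equations solve", {
  d <- data.frame(dyad_id = letters[1:6],
                  mean_fpa_fpa = c(0.1, 0.4, -0.2, 0.3, 0.0, 0.5),
                  sd_mna_fna = c(0.2, 0.1, 0.5, 0.3, 0.4, 0.0),
                  quality_final = c(5.1, 6.0, 4.2, 5.8, 5.0, 6.3))
  m <- fit_linear(d, c("mean_fpa_fpa", "sd_mna_fna"))
  X <- cbind(1, d$mean_fpa_fpa, d$sd_mna_fna)
  beta <- solve(t(X) %*% X, t(X) %*% d$quality_final)
  expect_equal(unname(m$coefficients), drop(beta), tolerance = 1e-10)
})

test_that("the null linear model predicts the mean with R2 = 0", {
  d <- synthetic_outcome_data(30, 3)
  m <- fit_linear(d, character(0))
  expect_equal(unname(m$coefficients), mean(d$quality_final))
  expect_equal(m$r_squared, 0)
  expect_equal(m$null_comparison$lr_statistic, 0, tolerance = 1e-10)
})

test_that("exact collinearity raises a rank-deficiency error", {
  d <- synthetic_outcome_data(30, 4)
  d$sd_fpa_fpa <- d$mean_fpa_fpa
  expect_error(fit_linear(d, c("mean_fpa_fpa", "sd_fpa_fpa")), "collinear")
})

test_that("intercept-only logistic accuracy is the majority-class rate", {
  d <- synthetic_outcome_data(127, 5)
  d$dissolved <- c(rep(1, 29), rep(0, 98))
  m <- fit_logistic(d, character(0))
  expect_lt(max(abs(fitted(m$model) - 29 / 127)), 1e-12)
  expect_equal(m$classification_accuracy, 98 / 127, tolerance = 1e-12)
  expect_equal(m$cox_snell_r2, 0, tolerance = 1e-10)
  expect_equal(m$nagelkerke_r2, 0, tolerance = 1e-10)
})

test_that("a single binary predictor matches the 2x2-table log odds ratio", {
  d <- data.frame(dyad_id = as.character(1:10),
                  mean_fpa_fpa = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                  dissolved    = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 1))
  m <- fit_logistic(d, "mean_fpa_fpa")
  # exposed: 3 events / 1 non-event; unexposed: 2 / 4
  hand <- log((3 / 1) / (2 / 4))
  expect_equal(unname(m$coefficients["mean_fpa_fpa"]), hand, tolerance = 1e-6)
  expect_equal(m$odds_ratios, exp(m$coefficients), tolerance = 1e-10)
})

test_that("pseudo R2 statistics respect their defining identities", {
  d <- synthetic_outcome_data(150, 6)
  d$dissolved <- rbinom(150, 1, plogis(-1 + 1.5 * d$sd_mpa_fna))
  m <- fit_logistic(d, c("sd_mpa_fna", "mean_fna_fna"))
  n <- m$n
  ll0 <- as.numeric(logLik(glm(dissolved ~ 1, binomial, d)))
  ll1 <- as.numeric(logLik(m$model))
  cs <- 1 - exp(-2 * (ll1 - ll0) / n)
  expect_equal(m$cox_snell_r2, cs, tolerance = 1e-10)
  expect_lte(m$cox_snell_r2, 1 - exp(2 * ll0 / n) + 1e-10)
  expect_gte(m$nagelkerke_r2, m$cox_snell_r2)
})

test_that("perfect separation is reported with the separating term", {
  d <- synthetic_outcome_data(40, 7)
  d$dissolved <- as.integer(d$sd_fna_mpa > 0)
  expect_error(fit_logistic(d, "sd_fna_mpa"), "sd_fna_mpa")
})

test_that("AIC stepwise improves monotonically and matches stats::step", {
  d <- synthetic_outcome_data(120, 8)
  d$quality_final <- 5.9 + 0.9 * d$mean_fpa_fna - 1.1 * d$sd_fpa_mpa +
    rnorm(120, sd = 0.5)
  m <- stepwise_select(d, "quality")
  expect_true(all(diff(m$path$criterion) < 0))
  expect_true(all(c("mean_fpa_fna", "sd_fpa_mpa") %in% m$selected_terms))
  # independent route: stats::step from the null model over the same scope
  scope <- as.formula(paste("~", paste(sort(predictor_names()), collapse = "+")))
  ref <- step(lm(quality_final ~ 1, data = d), scope = list(upper = scope),
              direction = "both", trace = 0)
  expect_setequal(m$selected_terms, attr(terms(ref), "term.labels"))
})

test_that("stepwise logistic recovers an injected dissolution signal", {
  d <- synthetic_outcome_data(200, 9)
  d$dissolved <- rbinom(200, 1, plogis(-1.2 + 2 * d$sd_mpa_fna))
  m <- stepwise_select(d, "dissolution")
  expect_true("sd_mpa_fna" %in% m$selected_terms)
  expect_gt(m$coefficients[["sd_mpa_fna"]], 0)
})

test_that("p-value stepwise honours its entry and stay thresholds", {
  d <- synthetic_outcome_data(150, 10)
  d$quality_final <- 5.9 + 1.2 * d$mean_mna_mna + rnorm(150, sd = 0.4)
  m <- stepwise_select(d, "quality", criterion = "pvalue")
  expect_true("mean_mna_mna" %in% m$selected_terms)
  expect_true(all(m$p_values[m$selected_terms] <= 0.10 + 1e-9))
})

test_that("adjusted refits keep the selected terms and add covariates", {
  d <- synthetic_outcome_data(150, 11)
  d$quality_final <- 5.9 + 1.0 * d$mean_fpa_fna + rnorm(150, sd = 0.5)
  m <- stepwise_select(d, "quality")
  adj <- adjusted_refit(d, m)
  expect_true(all(m$selected_terms %in% adj$selected_terms))
  expect_true(all(c("years_together", "quality_initial") %in% adj$selected_terms))
  expect_gte(adj$r_squared, m$r_squared - 1e-10)  # nested least squares
  # orthogonal covariates barely move the selected coefficients
  for (tm in m$selected_terms) {
    delta <- abs(adj$coefficients[[tm]] - m$coefficients[[tm]])
    expect_lt(delta, 2 * m$standard_errors[[tm]])
  }
  # a covariate duplicating a term is rank deficient
  d$quality_initial <- d$mean_fpa_fna
  expect_error(adjusted_refit(d, m), "collinear")
})
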