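# Location-scale maximum-likelihood fitter: design construction, oracle
# equivalences, diagnostics and information criteria.

test_that("design matrices encode covariates as specified", {
  records <- data.frame(
    animal_id = c("a1", "a2"), strain = c("wistar", "sprague_dawley"),
    sex = c("male", "female"), mass_g = c(300, 250),
    peep_cmH2O = c(3, 0), raw = c(40, 50), g = c(500, 600),
    h = c(2500, 3000), eelv_ml = c(8, 6), stringsAsFactors = FALSE
  )
  d <- build_design(records, default_design("raw"))
  expect_equal(unname(d$mu_design[1, ]),
               c(1, sqrt(300), 1, 1, 0, 0, 1, 0, 0), tolerance = 1e-10)
  expect_equal(unname(d$mu_design[2, ]),
               c(1, sqrt(250), 0, 0, 0, 0, 0, 0, 0), tolerance = 1e-10)
  # sigma design carries untransformed mass for EELV's default design
  d2 <- build_design(records, default_design("eelv"))
  expect_equal(unname(d2$sigma_design[1, "mass"]), 300)
  expect_equal(d$response, log(c(40, 50)))
  expect_equal(d2$response, c(8, 6))
})

test_that("rows with missing response are dropped and counted", {
  cohort <- simulate_cohort(cohort_config(seed = 3,
                                          p_missing_eelv_top_peep = 0.5))
  d <- build_design(cohort, default_design("eelv"))
  n_missing <- sum(is.na(cohort$eelv_ml))
  expect_gt(n_missing, 0)
  expect_equal(d$n_dropped, n_missing)
  expect_equal(nrow(d$mu_design), nrow(cohort) - n_missing)

  all_missing <- cohort
  all_missing$eelv_ml <- NA_real_
  expect_error(build_design(all_missing, default_design("eelv")),
               class = "ratlungref_error_empty_design")
})

test_that("homoscedastic fit reproduces the least-squares oracle", {
  cohort <- make_balanced_cohort(150, seed = 21)
  spec <- design_spec("raw", mu_terms = c("sqrt_mass", "strain", "sex",
                                          "peep"),
                      sigma_terms = character(0))
  fit <- fit_location_scale(cohort, spec)
  expect_true(fit$converged)

  ols <- lm(log(raw) ~ sqrt(mass_g) + I(strain == "wistar") +
              I(sex == "male") + factor(peep_cmH2O), data = cohort)
  expect_equal(unname(fit$mu_coef), unname(coef(ols)), tolerance = 1e-6)

  # with sigma intercept-only, fitted sigma is the ML residual SD
  sd_ml <- sqrt(mean(residuals(ols)^2))
  expect_equal(exp(fit$sigma_coef[["intercept"]]), sd_ml,
               tolerance = 1e-8)
  expect_equal(unique(round(fit$sigma_fitted, 10)),
               round(sd_ml, 10))
})

test_that("heteroscedastic fit agrees with an independent location-scale fitter", {
  # mgcv's gaulss family models (mu, log(sigma - b)); with b ~ 0 its
  # second linear predictor coincides with this package's log-sigma scale.
  library(mgcv)
  cohort <- make_balanced_cohort(400, seed = 31)
  spec <- design_spec("raw", sigma_terms = c("strain", "peep"))
  fit <- fit_location_scale(cohort, spec)
  expect_true(fit$converged)

  dat <- data.frame(
    y = log(cohort$raw), sm = sqrt(cohort$mass_g),
    wis = as.numeric(cohort$strain == "wistar"),
    male = as.numeric(cohort$sex == "male"),
    peep = factor(cohort$peep_cmH2O)
  )
  gfit <- gam(list(y ~ sm + wis + male + peep, ~ wis + peep),
              family = gaulss(b = 1e-7), data = dat)
  gc_mu <- coef(gfit)[1:9]
  gc_sigma <- coef(gfit)[10:16]
  expect_equal(unname(fit$mu_coef), unname(gc_mu), tolerance = 1e-4)
  expect_equal(unname(fit$sigma_coef), unname(gc_sigma), tolerance = 1e-3)
  expect_equal(fit$log_likelihood, as.numeric(logLik(gfit)),
               tolerance = 1e-6)
})

test_that("fitting recovers generating coefficients with error shrinking in n", {
  true_a1 <- -0.07261
  rec_err <- function(n_animals, seeds) {
    sapply(seeds, function(s) {
      cohort <- make_balanced_cohort(n_animals, seed = s)
      fit <- fit_location_scale(cohort, default_design("raw"))
      expect_true(fit$converged)
      fit$mu_coef[["sqrt_mass"]] - true_a1
    })
  }
  err_small <- rec_err(100, seeds = 101:106)
  err_large <- rec_err(1600, seeds = 201:206)
  # unbiased within Monte Carlo noise, and RMSE shrinks roughly as 1/sqrt(n)
  expect_lt(abs(mean(err_large)), 0.003)
  rmse_small <- sqrt(mean(err_small^2))
  rmse_large <- sqrt(mean(err_large^2))
  expect_lt(rmse_large, rmse_small)
  expect_lt(rmse_large, 2 * rmse_small / sqrt(16))
})

test_that("standardized residuals of a correctly specified fit are standard normal", {
  cohort <- make_balanced_cohort(500, seed = 41)
  fit <- fit_location_scale(cohort, default_design("raw"))
  zr <- fit$standardized_residuals
  n <- length(zr)
  expect_lt(abs(mean(zr)), 4 / sqrt(n))
  expect_lt(abs(sd(zr) - 1), 4 / sqrt(2 * n))
})

test_that("under-determined and rank-deficient designs are rejected", {
  cohort <- make_balanced_cohort(200, seed = 51)
  expect_error(fit_location_scale(cohort[1:5, ], default_design("raw")),
               class = "ratlungref_error_underdetermined")
  one_strain <- cohort[cohort$strain == "wistar", ]
  expect_error(fit_location_scale(one_strain, default_design("raw")),
               class = "ratlungref_error_rank_deficient")
})

test_that("Cox-Snell R2 follows its closed form and stays in [0, 1)", {
  cohort <- make_balanced_cohort(200, seed = 61)
  fit <- fit_location_scale(cohort, default_design("raw"))
  null_spec <- design_spec("raw", character(0), character(0))
  null_fit <- fit_location_scale(cohort, null_spec)
  r2 <- cox_snell_r2(fit, null_fit)
  expect_equal(r2, 1 - exp((2 / fit$n_obs) *
                             (null_fit$log_likelihood -
                                fit$log_likelihood)),
               tolerance = 1e-12)
  expect_identical(r2, fit$r2_cox_snell)
  expect_gt(r2, 0); expect_lt(r2, 1)
  # equal likelihoods give 0; a likelihood gain of n/2 gives 1 - 1/e
  expect_equal(cox_snell_r2(null_fit, null_fit), 0)
  fake <- null_fit
  fake$log_likelihood <- null_fit$log_likelihood + null_fit$n_obs / 2
  expect_equal(cox_snell_r2(fake, null_fit), 1 - exp(-1),
               tolerance = 1e-12)

  short_fit <- fit_location_scale(cohort[1:300, ], default_design("raw"))
  expect_error(cox_snell_r2(fit, short_fit),
               class = "ratlungref_error_r2_mismatch")
})

test_that("GAIC penalises parameters and nested deviance is monotone", {
  cohort <- make_balanced_cohort(150, seed = 71)
  full <- fit_location_scale(cohort, default_design("raw"))
  reduced <- fit_location_scale(cohort,
                                design_spec("raw", c("sqrt_mass", "peep"),
                                            "peep"))
  expect_equal(gaic(full, 2),
               -2 * full$log_likelihood + 2 * full$n_par)
  expect_equal(gaic(full, 0), -2 * full$log_likelihood)
  # the larger nested model never has larger deviance
  expect_lte(-2 * full$log_likelihood, -2 * reduced$log_likelihood)
})

test_that("residual diagnostics compute moments and guard degenerate cases", {
  cohort <- make_balanced_cohort(400, seed = 81)
  fit <- fit_location_scale(cohort, default_design("raw"))
  d <- residual_diagnostics(fit)
  # correctly specified Gaussian residuals: near-zero skew and excess kurtosis
  expect_lt(abs(d$skewness), 0.25)
  expect_lt(abs(d$excess_kurtosis), 0.5)
  expect_equal(nrow(d$qq_points), fit$n_obs)
  expect_false(is.unsorted(d$qq_points$empirical))

  # hand sample via a fake fit: symmetric residuals have zero skewness
  fake <- fit
  fake$residuals_transformed <- c(-1, 0, 1, -2, 2)
  fake$standardized_residuals <- c(-1, 0, 1, -2, 2)
  dh <- residual_diagnostics(fake)
  expect_equal(dh$mean, 0)
  expect_equal(dh$skewness, 0)

  fake$residuals_transformed <- rep(0, 10)
  fake$standardized_residuals <- rep(0, 10)
  dz <- residual_diagnostics(fake)
  expect_true(dz$degenerate)
  expect_true(is.na(dz$skewness))

  fake$residuals_transformed <- c(0, 1)
  expect_error(residual_diagnostics(fake),
               class = "ratlungref_error_too_few_residuals")
})

test_that("fit reports round-trip through the coefficient document schema", {
  cohort <- make_balanced_cohort(150, seed = 91)
  fit <- fit_location_scale(cohort, default_design("raw"))
  path <- tempfile(fileext = ".json")
  write_fit_report(fit, path)
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(report$coefficients$mu$sqrt_mass,
               fit$mu_coef[["sqrt_mass"]], tolerance = 1e-12)
  expect_equal(report$r2_cox_snell, fit$r2_cox_snell, tolerance = 1e-12)
  # coefficient block loads back as a reference model
  doc_path <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(raw = report$coefficients),
                              auto_unbox = TRUE, digits = NA), doc_path)
  model <- load_reference_coefficients(doc_path)$raw
  covs <- covariate_set(250, "wistar", "male", 4)
  expect_equal(compute_mu(model, covs),
               sum(fit$mu_coef * c(1, sqrt(250), 1, 1, 0, 0, 0, 1, 0)),
               tolerance = 1e-10)
})
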