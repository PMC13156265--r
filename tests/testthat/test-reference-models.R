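# Prediction equations: mu, sigma, predicted median, z-scores, normal
# ranges and effect sizes under the bundled published coefficients.

test_that("bundled coefficients reproduce the published table at printed precision", {
  fmt <- function(x) sprintf("%.5f", x)
  raw <- bundled_models$raw$coefficients
  expect_identical(fmt(raw$mu$intercept), "5.36400")
  expect_identical(fmt(raw$mu$sqrt_mass), "-0.07261")
  expect_identical(fmt(raw$mu$strain_wistar), "-0.07227")
  expect_identical(fmt(raw$mu$sex_male), "0.24217")
  expect_identical(unname(fmt(raw$mu$peep)),
                   c("0.00000", "-0.20376", "-0.36403", "-0.51259",
                     "-0.65403", "-0.96527"))
  expect_identical(fmt(raw$sigma$intercept), "-1.17594")
  expect_identical(fmt(raw$sigma$strain_wistar), "-0.12428")
  expect_null(raw$sigma$mass)      # excluded terms are absent, not zero
  expect_null(raw$sigma$sex_male)
  expect_identical(unname(fmt(raw$sigma$peep)),
                   c("0.00000", "-0.19736", "-0.21221", "-0.16229",
                     "-0.05226", "0.06301"))

  g <- bundled_models$g$coefficients
  expect_identical(fmt(g$mu$intercept), "7.87594")
  expect_identical(fmt(g$mu$sqrt_mass), "-0.06022")
  expect_identical(fmt(g$sigma$sex_male), "0.12800")
  expect_null(g$sigma$strain_wistar)

  h <- bundled_models$h$coefficients
  expect_identical(fmt(h$mu$intercept), "9.98623")
  expect_identical(fmt(h$sigma$mass), "0.00078")
  expect_identical(fmt(h$sigma$sex_male), "-0.07682")
  expect_null(h$sigma$peep)        # H sigma model has no PEEP effects

  eelv <- bundled_models$eelv$coefficients
  expect_identical(fmt(eelv$mu$intercept), "-5.29284")
  expect_identical(fmt(eelv$mu$sqrt_mass), "0.58809")
  expect_identical(fmt(eelv$sigma$mass), "0.00413")
  expect_identical(unname(fmt(eelv$mu$peep)),
                   c("0.00000", "0.82506", "1.57536", "2.47960",
                     "3.46782", "5.32320"))
  expect_identical(unname(fmt(eelv$sigma$peep)),
                   c("0.00000", "0.02265", "0.13399", "0.27625",
                     "0.45725", "0.70147"))

  expect_identical(bundled_models$raw$spec$mu_transform, "log")
  expect_identical(bundled_models$g$spec$mu_transform, "log")
  expect_identical(bundled_models$h$spec$mu_transform, "log")
  expect_identical(bundled_models$eelv$spec$mu_transform, "identity")
})

test_that("mu and sigma match hand-computed values from the equations", {
  # closed-form oracle: direct arithmetic on the printed coefficients
  covs <- covariate_set(250, "sprague_dawley", "female", 2)
  expect_equal(compute_mu(bundled_models$raw, covs),
               5.36400 - 0.07261 * sqrt(250) - 0.36403, tolerance = 1e-12)
  expect_equal(compute_sigma(bundled_models$raw, covs),
               exp(-1.17594 - 0.21221), tolerance = 1e-12)
  expect_equal(predicted_median(bundled_models$raw, covs),
               exp(5.36400 - 0.07261 * sqrt(250) - 0.36403),
               tolerance = 1e-12)

  covs_w <- covariate_set(300, "wistar", "male", 6)
  expect_equal(compute_mu(bundled_models$eelv, covs_w),
               -5.29284 + 0.58809 * sqrt(300) - 0.16721 - 0.27947 + 5.32320,
               tolerance = 1e-12)
  expect_equal(compute_sigma(bundled_models$eelv, covs_w),
               exp(-0.87845 + 0.00413 * 300 - 0.13945 - 0.41105 + 0.70147),
               tolerance = 1e-12)
  # identity transform: predicted median equals mu
  expect_identical(predicted_median(bundled_models$eelv, covs_w),
                   compute_mu(bundled_models$eelv, covs_w))

  # reference category: all indicator and PEEP terms vanish
  covs_ref <- covariate_set(211, "sprague_dawley", "female", 0)
  expect_equal(compute_mu(bundled_models$raw, covs_ref),
               5.36400 - 0.07261 * sqrt(211), tolerance = 1e-12)
})

test_that("z-scores, percentiles and classification follow the reference distribution", {
  covs <- covariate_set(250, "sprague_dawley", "female", 2)
  res <- z_score(bundled_models$raw, covs, 60)
  expect_equal(res$z, (log(60) - 3.851905) / 0.2495365, tolerance = 1e-4)
  expect_equal(res$percentile, 100 * pnorm(res$z), tolerance = 1e-12)
  expect_identical(res$classification, "within_range")

  # observed at the predicted median: z = 0, percentile 50
  med <- predicted_median(bundled_models$raw, covs)
  res0 <- z_score(bundled_models$raw, covs, med)
  expect_equal(res0$z, 0, tolerance = 1e-12)
  expect_equal(res0$percentile, 50, tolerance = 1e-10)

  # classification threshold at the default 1.645
  mu <- compute_mu(bundled_models$raw, covs)
  sg <- compute_sigma(bundled_models$raw, covs)
  expect_identical(z_score(bundled_models$raw, covs,
                           exp(mu + 1.70 * sg))$classification,
                   "above_range")
  expect_identical(z_score(bundled_models$raw, covs,
                           exp(mu - 1.70 * sg))$classification,
                   "below_range")

  expect_error(z_score(bundled_models$raw, covs, -1),
               class = "ratlungref_error_nonpositive_observed")
})

test_that("z-score of the value at the p-th percentile returns percentile p", {
  grid <- covariate_grid()
  for (nm in names(bundled_models)) {
    model <- bundled_models[[nm]]
    mu <- compute_mu(model, grid)
    sg <- compute_sigma(model, grid)
    for (p in c(2.5, 25, 50, 90, 97.5)) {
      val <- if (model$spec$mu_transform == "log") {
        exp(mu + qnorm(p / 100) * sg)
      } else {
        mu + qnorm(p / 100) * sg
      }
      expect_equal(z_score(model, grid, val)$percentile,
                   rep(p, nrow(grid)), tolerance = 1e-9)
    }
  }
})

test_that("sigma is strictly positive for every covariate combination and outcome", {
  grid <- covariate_grid(masses = c(160, 200, 300, 500, 750))
  for (nm in names(bundled_models)) {
    sg <- suppressWarnings(compute_sigma(bundled_models[[nm]], grid))
    expect_true(all(sg > 0))
  }
})

test_that("z-score of the predicted median is zero for all covariates and outcomes", {
  grid <- covariate_grid()
  for (nm in names(bundled_models)) {
    model <- bundled_models[[nm]]
    med <- predicted_median(model, grid)
    expect_equal(z_score(model, grid, med)$z, rep(0, nrow(grid)),
                 tolerance = 1e-12)
  }
})

test_that("normal range brackets the median and widens monotonically", {
  covs <- covariate_set(250, "sprague_dawley", "female", 2)
  rng <- normal_range(bundled_models$raw, covs, 0.90)
  expect_equal(rng$lower, exp(3.851905 - qnorm(0.95) * 0.2495365),
               tolerance = 1e-4)
  expect_equal(rng$upper, exp(3.851905 + qnorm(0.95) * 0.2495365),
               tolerance = 1e-4)

  med <- predicted_median(bundled_models$raw, covs)
  widths <- sapply(c(0.05, 0.2, 0.5, 0.8, 0.9, 0.95, 0.99), function(cm) {
    r <- normal_range(bundled_models$raw, covs, cm)
    expect_lt(r$lower, med)
    expect_gt(r$upper, med)
    r$upper - r$lower
  })
  expect_true(all(diff(widths) > 0))

  # tiny central mass collapses onto the median
  r0 <- normal_range(bundled_models$raw, covs, 1e-9)
  expect_equal(r0$lower, med, tolerance = 1e-6)
  expect_equal(r0$upper, med, tolerance = 1e-6)

  expect_error(normal_range(bundled_models$raw, covs, 1.2),
               class = "ratlungref_error_central_mass")
  expect_error(normal_range(bundled_models$raw, covs, 0),
               class = "ratlungref_error_central_mass")
})

test_that("effect sizes convert coefficients to percent changes and d classes", {
  es <- effect_sizes(bundled_models$g, "strain")
  expect_equal(es$percent_change_mu, 100 * (exp(-0.05717) - 1),
               tolerance = 1e-12)
  expect_true(is.na(es$percent_change_sigma))  # G sigma has no strain term

  es_sex <- effect_sizes(bundled_models$g, "sex")
  expect_equal(es_sex$percent_change_sigma, 100 * (exp(0.12800) - 1),
               tolerance = 1e-12)
  # standardizer: mean sigma over PEEP at reference covariates (SD female,
  # cohort median mass 258 g), computed here independently
  sig_ref <- mean(exp(-1.85751 +
                        c(0, -0.25486, -0.29300, -0.23964, -0.26472,
                          -0.32089)))
  expect_equal(es_sex$d_value, 0.16888 / sig_ref, tolerance = 1e-12)

  expect_identical(ratlungref:::classify_d(0.9), "large")
  expect_identical(ratlungref:::classify_d(0), "below_small")
  expect_identical(ratlungref:::classify_d(0.6), "medium")
  expect_identical(ratlungref:::classify_d(1.5), "very_large")
})

test_that("covariate validation rejects bad inputs and warns on extrapolation", {
  m <- bundled_models$raw
  expect_error(compute_mu(m, covariate_set(250, "sprague_dawley",
                                           "female", 5)),
               class = "ratlungref_error_peep_level")
  expect_error(covariate_set(-10, "wistar", "male", 2),
               class = "ratlungref_error_covariates")
  expect_error(covariate_set(250, "long_evans", "male", 2),
               class = "ratlungref_error_covariates")
  # 900 g exceeds every group range: extrapolation warns but still predicts
  expect_warning(compute_mu(m, covariate_set(900, "sprague_dawley",
                                             "male", 2)),
                 class = "ratlungref_warning_mass_range")
})

test_that("coefficient documents round-trip and reject malformed input", {
  path <- tempfile(fileext = ".json")
  write_reference_coefficients(bundled_models, path)
  reread <- load_reference_coefficients(path)
  grid <- covariate_grid()
  for (nm in names(bundled_models)) {
    expect_equal(compute_mu(reread[[nm]], grid),
                 compute_mu(bundled_models[[nm]], grid), tolerance = 1e-12)
    expect_equal(compute_sigma(reread[[nm]], grid),
                 compute_sigma(bundled_models[[nm]], grid),
                 tolerance = 1e-12)
  }

  bad <- tempfile(fileext = ".json")
  writeLines('{"frc": {"mu": {}, "sigma": {}}}', bad)
  expect_error(load_reference_coefficients(bad),
               class = "ratlungref_error_coefficient_schema")

  # missing mu key is named in the error
  writeLines(paste0('{"raw": {"mu": {"intercept": 1, "peep": {"0": 0}},',
                    ' "sigma": {"intercept": 0}}}'), bad)
  expect_error(load_reference_coefficients(bad), "sqrt_mass")

  # nonzero reference PEEP effect is rejected
  writeLines(paste0('{"raw": {"mu": {"intercept": 1, "sqrt_mass": 0, ',
                    '"strain_wistar": 0, "sex_male": 0, ',
                    '"peep": {"0": 0.5}}, "sigma": {"intercept": 0}}}'), bad)
  expect_error(load_reference_coefficients(bad),
               class = "ratlungref_error_coefficient_schema")
})
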