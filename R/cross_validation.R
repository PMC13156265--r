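# Monte Carlo cross-validation of the location-scale reference models:
# repeated random train/test splits, test-set z-scores pooled across
# iterations, and per-iteration RMSE/MAE on the original measurement scale.

#' Cross-validation configuration
#'
#' @param n_iterations Number of random splits (default 50).
#' @param test_fraction Fraction of the split unit assigned to the test set
#'   (default 0.30).
#' @param seed Integer seed.
#' @param split_unit `"animal"` (all PEEP rows of an animal travel
#'   together; default, avoids leakage of animal-level information) or
#'   `"row"`.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_iterations = 50, test_fraction = 0.30, seed = 1L,
                      split_unit = c("animal", "row")) {
  if (!(is_scalar_number(test_fraction) && test_fraction > 0 &&
        test_fraction < 1)) {
    rlr_error("test_fraction must lie strictly between 0 and 1", "config")
  }
  if (!(is_scalar_number(n_iterations) && n_iterations >= 1)) {
    rlr_error("n_iterations must be a positive integer", "config")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 split_unit = match.arg(split_unit)),
            class = "cv_config")
}

#' Coverage of z-scores within a symmetric bound
#'
#' Fraction of z-scores with `|z| <= bound`; with bound 1.645 this is the
#' empirical counterpart of the central 90% of the reference distribution,
#' with 1.96 of the central 95%.
#'
#' @param z Numeric vector of z-scores (non-empty; `NA` dropped).
#' @param bound Positive bound.
#' @return Proportion in `[0, 1]`.
#' @export
coverage <- function(z, bound) {
  z <- z[!is.na(z)]
  if (!length(z)) rlr_error("no z-scores supplied", "empty_input")
  stopifnot(is_scalar_number(bound), bound > 0)
  mean(abs(z) <= bound)
}

#' Root-mean-square error
#'
#' @param measured,predicted Equal-length numeric vectors on the original
#'   measurement scale.
#' @return `sqrt(mean((measured - predicted)^2))`.
#' @export
rmse <- function(measured, predicted) {
  check_paired(measured, predicted)
  sqrt(mean((measured - predicted)^2))
}

#' Mean absolute error
#'
#' @inheritParams rmse
#' @return `mean(abs(measured - predicted))`.
#' @export
mae <- function(measured, predicted) {
  check_paired(measured, predicted)
  mean(abs(measured - predicted))
}

check_paired <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    rlr_error("measured and predicted must have equal length",
              "length_mismatch")
  }
  if (!length(measured)) rlr_error("empty input", "empty_input")
  invisible(TRUE)
}

#' Monte Carlo cross-validation of a location-scale design
#'
#' Repeatedly splits the cohort into train/test sets, fits the
#' location-scale model on the training set, and evaluates on the test
#' set: z-scores `(T(y) - mu_hat) / sigma_hat` on the modelling scale, and
#' predictions back-transformed to original units for RMSE/MAE. z-score
#' statistics (mean, SD, range, 90%/95% coverage) are pooled over all
#' iterations' test sets; RMSE and MAE are computed per iteration and
#' summarised as mean, SD and range. Iterations whose training fit fails
#' to converge are excluded and counted, never silently averaged.
#'
#' @param records Cohort data frame.
#' @param spec A [design_spec()].
#' @param config A [cv_config()].
#' @param control A [fit_control()].
#' @return An object of class `cv_metrics`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(seed = 7))
#' cv <- monte_carlo_cv(cohort, default_design("raw"),
#'                      cv_config(n_iterations = 10, seed = 7))
#' cv$coverage_90
#' }
#' @export
monte_carlo_cv <- function(records, spec, config = cv_config(),
                           control = fit_control()) {
  stopifnot(inherits(spec, "design_spec"), inherits(config, "cv_config"))
  ycol <- outcome_column(spec$outcome$name)
  usable <- records[!is.na(records[[ycol]]), , drop = FALSE]
  if (!nrow(usable)) rlr_error("no usable rows", "empty_design")

  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  z_all <- numeric(0)
  rmse_it <- numeric(0)
  mae_it <- numeric(0)
  n_failed <- 0L

  # sorted ids make animal-level splits invariant to row order
  units <- if (config$split_unit == "animal") sort(unique(records$animal_id))
           else seq_len(nrow(records))
  n_test <- max(1L, round(config$test_fraction * length(units)))

  for (it in seq_len(config$n_iterations)) {
    test_units <- sample(units, n_test)
    in_test <- if (config$split_unit == "animal") {
      records$animal_id %in% test_units
    } else {
      seq_len(nrow(records)) %in% test_units
    }
    train <- records[!in_test, , drop = FALSE]
    test <- records[in_test & !is.na(records[[ycol]]), , drop = FALSE]
    if (!nrow(test)) next

    fit <- tryCatch(fit_location_scale(train, spec, control),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    covs <- covariate_set(test$mass_g, test$strain, test$sex,
                          test$peep_cmH2O)
    mu <- mu_linear_predictor(fit$coefficients, covs)
    sigma <- exp(sigma_linear_predictor(fit$coefficients, covs))
    ty <- transform_observed(spec$outcome, test[[ycol]])
    z_all <- c(z_all, (ty - mu) / sigma)
    pred <- backtransform_mu(spec$outcome, mu)
    rmse_it <- c(rmse_it, rmse(test[[ycol]], pred))
    mae_it <- c(mae_it, mae(test[[ycol]], pred))
  }

  if (!length(z_all)) {
    rlr_error("every cross-validation iteration failed", "cv_failed")
  }
  structure(list(
    outcome = spec$outcome$name,
    n_iterations = config$n_iterations,
    n_iterations_used = length(rmse_it),
    n_failed = n_failed,
    n_z = length(z_all),
    z_mean = mean(z_all),
    z_sd = stats::sd(z_all),
    z_range = range(z_all),
    coverage_90 = coverage(z_all, 1.645),
    coverage_95 = coverage(z_all, 1.96),
    rmse_mean = mean(rmse_it), rmse_sd = stats::sd(rmse_it),
    rmse_range = range(rmse_it),
    mae_mean = mean(mae_it), mae_sd = stats::sd(mae_it),
    mae_range = range(mae_it)
  ), class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("Monte Carlo cross-validation: %s (%d/%d iterations used)\n",
              x$outcome, x$n_iterations_used, x$n_iterations))
  cat(sprintf("  pooled z: mean %.3f, sd %.3f, range %.3f to %.3f (n = %d)\n",
              x$z_mean, x$z_sd, x$z_range[1], x$z_range[2], x$n_z))
  cat(sprintf("  coverage: %.1f%% within 1.645, %.1f%% within 1.96\n",
              100 * x$coverage_90, 100 * x$coverage_95))
  cat(sprintf("  RMSE: %.3f (sd %.3f, range %.3f-%.3f)\n",
              x$rmse_mean, x$rmse_sd, x$rmse_range[1], x$rmse_range[2]))
  cat(sprintf("  MAE:  %.3f (sd %.3f, range %.3f-%.3f)\n",
              x$mae_mean, x$mae_sd, x$mae_range[1], x$mae_range[2]))
  invisible(x)
}

#' Serialise cross-validation metrics to a flat list
#'
#' @param metrics A `cv_metrics` object.
#' @return Named list suitable for JSON output.
#' @export
cv_metrics_to_list <- function(metrics) {
  list(
    outcome = metrics$outcome,
    n_iterations = metrics$n_iterations,
    n_iterations_used = metrics$n_iterations_used,
    n_failed = metrics$n_failed,
    z_mean = metrics$z_mean, z_sd = metrics$z_sd,
    z_min = metrics$z_range[1], z_max = metrics$z_range[2],
    coverage_90 = metrics$coverage_90, coverage_95 = metrics$coverage_95,
    rmse_mean = metrics$rmse_mean, rmse_sd = metrics$rmse_sd,
    rmse_min = metrics$rmse_range[1], rmse_max = metrics$rmse_range[2],
    mae_mean = metrics$mae_mean, mae_sd = metrics$mae_sd,
    mae_min = metrics$mae_range[1], mae_max = metrics$mae_range[2]
  )
}
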