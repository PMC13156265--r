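# Reference models: published prediction equations for rat lung function,
# and the derived quantities used to interpret an individual measurement
# (predicted median, sigma, z-score, percentile, normal range, effect size).

# Body-mass ranges of the study cohort per strain x sex (grams); predictions
# outside these ranges are extrapolations and trigger a warning.
.MASS_RANGES <- list(
  sprague_dawley.female = c(164, 376),
  sprague_dawley.male   = c(170, 750),
  wistar.female         = c(162, 366),
  wistar.male           = c(156, 530)
)

# Cohort median body mass per strain x sex (grams), used as default
# evaluation points for effect sizes.
.MASS_MEDIANS <- c(
  sprague_dawley.female = 258,
  sprague_dawley.male   = 317,
  wistar.female         = 260,
  wistar.male           = 310
)

#' Reference model for one outcome
#'
#' Bundles an outcome specification with a location-scale coefficient set
#' and the applicability (body-mass) ranges of the underlying cohort.
#'
#' @param spec An [outcome_spec()] (or outcome name).
#' @param coefficients A [location_scale_coefficients()] object.
#' @param applicability Named list of `c(min, max)` body-mass ranges (g) per
#'   `strain.sex` combination; defaults to the study cohort ranges.
#' @return An object of class `reference_model`.
#' @seealso [load_reference_coefficients()] for the bundled published models.
#' @export
reference_model <- function(spec, coefficients,
                            applicability = .MASS_RANGES) {
  if (is.character(spec)) spec <- outcome_spec(spec)
  stopifnot(inherits(spec, "outcome_spec"),
            inherits(coefficients, "location_scale_coefficients"))
  structure(
    list(spec = spec, coefficients = coefficients,
         applicability = applicability),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("Reference model for %s\n", x$spec$label))
  cat(sprintf("  mu scale: %s; sigma link: log\n", x$spec$mu_transform))
  cat(sprintf("  PEEP levels: %s cmH2O\n",
              paste(peep_levels_of(x$coefficients), collapse = ", ")))
  sig <- x$coefficients$sigma
  cat(sprintf("  sigma terms: %s\n",
              paste(setdiff(names(sig), "intercept") %||% "intercept only",
                    collapse = ", ")))
  invisible(x)
}

#' Assemble and validate a covariate set
#'
#' Builds the covariate frame used by all prediction functions. Inputs are
#' recycled to a common length. Unknown strain, sex or PEEP values are
#' rejected; body mass outside the cohort's applicability range raises a
#' warning (extrapolation), not an error.
#'
#' @param mass_g Body mass in grams (positive).
#' @param strain `"sprague_dawley"` or `"wistar"`.
#' @param sex `"female"` or `"male"`.
#' @param peep_cmH2O PEEP level in cmH2O; one of 0, 1, 2, 3, 4, 6.
#' @return A `data.frame` with validated columns `mass_g`, `strain`, `sex`,
#'   `peep_cmH2O`.
#' @examples
#' covariate_set(250, "sprague_dawley", "female", 2)
#' @export
covariate_set <- function(mass_g, strain, sex, peep_cmH2O) {
  n <- max(length(mass_g), length(strain), length(sex), length(peep_cmH2O))
  covs <- data.frame(
    mass_g = rep_len(as.numeric(mass_g), n),
    strain = rep_len(as.character(strain), n),
    sex = rep_len(as.character(sex), n),
    peep_cmH2O = rep_len(as.numeric(peep_cmH2O), n),
    stringsAsFactors = FALSE
  )
  if (any(is.na(covs$mass_g)) || any(covs$mass_g <= 0)) {
    rlr_error("mass_g must be positive", "covariates")
  }
  bad_strain <- setdiff(unique(covs$strain), .STRAINS)
  if (length(bad_strain)) {
    rlr_error(paste0("unknown strain: ", paste(bad_strain, collapse = ", ")),
              "covariates")
  }
  bad_sex <- setdiff(unique(covs$sex), .SEXES)
  if (length(bad_sex)) {
    rlr_error(paste0("unknown sex: ", paste(bad_sex, collapse = ", ")),
              "covariates")
  }
  covs
}

# Covariate validation against a specific model: PEEP must be a modelled
# level; mass outside the applicability range warns.
validate_covariates <- function(model, covs) {
  if (!is.data.frame(covs)) {
    rlr_error("covariates must be a data.frame (see covariate_set())",
              "covariates")
  }
  covs <- covariate_set(covs$mass_g, covs$strain, covs$sex, covs$peep_cmH2O)
  levels_ok <- peep_levels_of(model$coefficients)
  bad_peep <- setdiff(unique(covs$peep_cmH2O), levels_ok)
  if (length(bad_peep)) {
    rlr_error(
      sprintf("unknown PEEP level(s) %s; modelled levels are %s",
              paste(bad_peep, collapse = ", "),
              paste(levels_ok, collapse = ", ")),
      "peep_level"
    )
  }
  key <- paste(covs$strain, covs$sex, sep = ".")
  rng <- model$applicability[key]
  lo <- vapply(rng, `[`, numeric(1), 1L)
  hi <- vapply(rng, `[`, numeric(1), 2L)
  outside <- covs$mass_g < lo | covs$mass_g > hi
  if (any(outside)) {
    rlr_warning(
      sprintf(paste0("%d covariate row(s) have body mass outside the ",
                     "cohort applicability range; prediction is an ",
                     "extrapolation"),
              sum(outside)),
      "mass_range"
    )
  }
  covs
}

#' Predicted mean on the modelling scale
#'
#' Evaluates the mu submodel
#' `a0 + a1*sqrt(mass_g) + a2*I(strain == wistar) + a3*I(sex == male) +
#' PEEP_effect` on the modelling scale (natural log for Raw/G/H, original
#' units for EELV).
#'
#' @param model A [reference_model()].
#' @param covs Covariate frame from [covariate_set()].
#' @return Numeric vector of mu values, one per covariate row.
#' @examples
#' m <- load_reference_coefficients()$raw
#' compute_mu(m, covariate_set(250, "sprague_dawley", "female", 2))
#' @export
compute_mu <- function(model, covs) {
  covs <- validate_covariates(model, covs)
  mu_linear_predictor(model$coefficients, covs)
}

#' Predicted standard deviation on the modelling scale
#'
#' Evaluates the sigma submodel
#' `exp(b0 + b1*mass_g + b2*I(strain == wistar) + b3*I(sex == male) +
#' PEEP_effect)`. Note the sigma submodel uses untransformed body mass,
#' unlike the mu submodel's square root. Terms excluded from a final model
#' contribute exactly 0. The log link guarantees a strictly positive result.
#'
#' @inheritParams compute_mu
#' @return Numeric vector of positive sigma values.
#' @export
compute_sigma <- function(model, covs) {
  covs <- validate_covariates(model, covs)
  exp(sigma_linear_predictor(model$coefficients, covs))
}

#' Predicted median in original units
#'
#' Back-transforms mu: `exp(mu)` for the log-scale outcomes (Raw, G, H),
#' `mu` itself for EELV. Under the Gaussian location-scale model on the
#' transformed scale this is the predicted 50th percentile in original
#' units.
#'
#' @inheritParams compute_mu
#' @return Numeric vector in the outcome's original units.
#' @export
predicted_median <- function(model, covs) {
  backtransform_mu(model$spec, compute_mu(model, covs))
}

#' Z-score of observed measurements under a reference model
#'
#' Computes `z = (T(observed) - mu) / sigma` where `T` is the natural log
#' for Raw/G/H and the identity for EELV, together with the percentile
#' `100 * pnorm(z)` and a normal-range classification. The default
#' classification bounds of +/-1.645 delimit the central 90% of the
#' reference distribution (5th-95th percentiles).
#'
#' @inheritParams compute_mu
#' @param observed Observed values in original units (recycled against the
#'   covariate rows); must be positive for log-scale outcomes.
#' @param z_limits Symmetric classification bound on the z scale
#'   (default 1.645).
#' @return A `data.frame` of class `z_score_result` with columns `mu`,
#'   `sigma`, `predicted_median`, `observed`, `z`, `percentile`,
#'   `classification`.
#' @examples
#' m <- load_reference_coefficients()$raw
#' z_score(m, covariate_set(250, "sprague_dawley", "female", 2), 60)
#' @export
z_score <- function(model, covs, observed, z_limits = 1.645) {
  covs <- validate_covariates(model, covs)
  observed <- rep_len(as.numeric(observed), nrow(covs))
  ty <- transform_observed(model$spec, observed)
  mu <- mu_linear_predictor(model$coefficients, covs)
  sigma <- exp(sigma_linear_predictor(model$coefficients, covs))
  z <- (ty - mu) / sigma
  classification <- ifelse(z < -z_limits, "below_range",
                           ifelse(z > z_limits, "above_range",
                                  "within_range"))
  classification[is.na(z)] <- NA_character_
  res <- data.frame(
    mu = mu,
    sigma = sigma,
    predicted_median = backtransform_mu(model$spec, mu),
    observed = observed,
    z = z,
    percentile = 100 * stats::pnorm(z),
    classification = classification,
    stringsAsFactors = FALSE
  )
  class(res) <- c("z_score_result", "data.frame")
  attr(res, "z_limits") <- z_limits
  res
}

#' Normal range in original units
#'
#' Limits of the central `central_mass` interval of the reference
#' distribution, `mu +/- z* sigma` back-transformed to original units,
#' where `z* = qnorm((1 + central_mass) / 2)`. The default 0.90 yields the
#' 5th-95th percentile interval.
#'
#' @inheritParams compute_mu
#' @param central_mass Central probability mass in (0, 1); default 0.90.
#' @return A `data.frame` with columns `lower` and `upper` in original
#'   units (`lower < upper` whenever `central_mass > 0`).
#' @export
normal_range <- function(model, covs, central_mass = 0.90) {
  if (!is_scalar_number(central_mass) || central_mass <= 0 ||
      central_mass >= 1) {
    rlr_error("central_mass must lie strictly between 0 and 1",
              "central_mass")
  }
  covs <- validate_covariates(model, covs)
  mu <- mu_linear_predictor(model$coefficients, covs)
  sigma <- exp(sigma_linear_predictor(model$coefficients, covs))
  zstar <- stats::qnorm((1 + central_mass) / 2)
  data.frame(
    lower = backtransform_mu(model$spec, mu - zstar * sigma),
    upper = backtransform_mu(model$spec, mu + zstar * sigma)
  )
}

.D_CLASS_BREAKS <- c(small = 0.2, medium = 0.5, large = 0.8,
                     very_large = 1.2)

classify_d <- function(d) {
  d <- abs(d)
  if (d < 0.2) "below_small"
  else if (d < 0.5) "small"
  else if (d < 0.8) "medium"
  else if (d < 1.2) "large"
  else "very_large"
}

#' Effect size of strain or sex under a reference model
#'
#' Summarises the strain (Wistar vs Sprague Dawley) or sex (male vs female)
#' coefficient as (i) a percentage change of the predicted median for
#' log-scale outcomes (`100 * (exp(coef) - 1)`), with the analogous
#' percentage change of sigma when the term is present in the sigma
#' submodel, and (ii) a standardized effect size analogous to Cohen's d:
#' the absolute mu coefficient divided by the model sigma evaluated at
#' reference covariates (Sprague Dawley female by default, at the cohort
#' median body mass of that group) averaged over the modelled PEEP levels.
#' The d classes use thresholds 0.2 (small), 0.5 (medium), 0.8 (large) and
#' 1.2 (very large).
#'
#' @inheritParams compute_mu
#' @param covariate `"strain"` or `"sex"`.
#' @param ref_strain,ref_sex Reference covariates at which sigma is
#'   evaluated for the standardizer.
#' @param mass_g Body mass (g) for the standardizer; defaults to the cohort
#'   median of the reference strain/sex group.
#' @return An object of class `effect_size_report`.
#' @examples
#' effect_sizes(load_reference_coefficients()$g, "strain")
#' @export
effect_sizes <- function(model, covariate = c("strain", "sex"),
                         ref_strain = "sprague_dawley", ref_sex = "female",
                         mass_g = NULL) {
  covariate <- match.arg(covariate)
  coefs <- model$coefficients
  mu_key <- if (covariate == "strain") "strain_wistar" else "sex_male"
  mu_coef <- coefs$mu[[mu_key]]
  sigma_coef <- coefs$sigma[[mu_key]]
  if (is.null(mass_g)) {
    mass_g <- unname(.MASS_MEDIANS[paste(ref_strain, ref_sex, sep = ".")])
  }
  pct_mu <- if (model$spec$mu_transform == "log") {
    100 * (exp(mu_coef) - 1)
  } else {
    NA_real_  # identity scale: coefficient is an additive shift, not a ratio
  }
  pct_sigma <- if (!is.null(sigma_coef)) 100 * (exp(sigma_coef) - 1) else NA_real_
  peeps <- peep_levels_of(coefs)
  ref_covs <- covariate_set(mass_g, ref_strain, ref_sex, peeps)
  sigma_ref <- mean(exp(sigma_linear_predictor(coefs, ref_covs)))
  d <- abs(mu_coef) / sigma_ref
  structure(
    list(outcome = model$spec$name, covariate = covariate,
         mu_coefficient = mu_coef,
         percent_change_mu = pct_mu,
         percent_change_sigma = pct_sigma,
         d_value = d, d_class = classify_d(d),
         standardizer = list(strain = ref_strain, sex = ref_sex,
                             mass_g = mass_g, sigma = sigma_ref)),
    class = "effect_size_report"
  )
}

#' @export
print.effect_size_report <- function(x, ...) {
  cat(sprintf("Effect of %s on %s\n", x$covariate, x$outcome))
  if (!is.na(x$percent_change_mu)) {
    cat(sprintf("  predicted median change: %+.2f%%\n", x$percent_change_mu))
  } else {
    cat(sprintf("  mu shift: %+.4f (original units)\n", x$mu_coefficient))
  }
  if (!is.na(x$percent_change_sigma)) {
    cat(sprintf("  sigma change: %+.2f%%\n", x$percent_change_sigma))
  }
  cat(sprintf("  standardized d: %.3f (%s)\n", x$d_value, x$d_class))
  invisible(x)
}
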