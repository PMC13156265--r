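# Location-scale coefficient sets and the coefficient-document (JSON)
# interchange format.
#
# A coefficient set holds the published prediction-equation coefficients for
# one outcome:
#   mu    = a0 + a1*sqrt(mass_g) + a2*I_wistar + a3*I_male + PEEP_effect
#   sigma = exp(b0 + b1*mass_g + b2*I_wistar + b3*I_male + PEEP_effect)
# Terms absent from a final model contribute exactly 0 and are represented by
# a missing key (not a zero), mirroring the published table's "--" entries.

.MU_TERM_KEYS <- c("intercept", "sqrt_mass", "strain_wistar", "sex_male")
.SIGMA_TERM_KEYS <- c("intercept", "mass", "strain_wistar", "sex_male")

#' Construct a location-scale coefficient set
#'
#' @param mu Named list with required entries `intercept`, `sqrt_mass`,
#'   `strain_wistar`, `sex_male` and `peep` (a named numeric vector of PEEP
#'   effects whose reference level `"0"` must equal 0).
#' @param sigma Named list with required entry `intercept`; optional entries
#'   `mass`, `strain_wistar`, `sex_male` and `peep` (absent entries
#'   contribute 0 to the linear predictor).
#' @return An object of class `location_scale_coefficients`.
#' @export
location_scale_coefficients <- function(mu, sigma) {
  missing_mu <- setdiff(c(.MU_TERM_KEYS, "peep"), names(mu))
  if (length(missing_mu)) {
    rlr_error(
      paste0("mu submodel is missing required keys: ",
             paste(missing_mu, collapse = ", ")),
      "coefficient_schema"
    )
  }
  if (!("intercept" %in% names(sigma))) {
    rlr_error("sigma submodel is missing required key: intercept",
              "coefficient_schema")
  }
  bad_sigma <- setdiff(names(sigma), c(.SIGMA_TERM_KEYS, "peep"))
  if (length(bad_sigma)) {
    rlr_error(
      paste0("sigma submodel has unknown keys: ",
             paste(bad_sigma, collapse = ", ")),
      "coefficient_schema"
    )
  }
  mu$peep <- check_peep_effects(mu$peep, "mu")
  if (!is.null(sigma$peep)) {
    sigma$peep <- check_peep_effects(sigma$peep, "sigma")
  }
  for (k in .MU_TERM_KEYS) {
    if (!is_scalar_number(mu[[k]])) {
      rlr_error(sprintf("mu coefficient '%s' must be a finite number", k),
                "coefficient_schema")
    }
  }
  for (k in intersect(names(sigma), .SIGMA_TERM_KEYS)) {
    if (!is_scalar_number(sigma[[k]])) {
      rlr_error(sprintf("sigma coefficient '%s' must be a finite number", k),
                "coefficient_schema")
    }
  }
  structure(
    list(mu = mu[c(.MU_TERM_KEYS, "peep")],
         sigma = sigma[intersect(c(.SIGMA_TERM_KEYS, "peep"), names(sigma))]),
    class = "location_scale_coefficients"
  )
}

check_peep_effects <- function(peep, submodel) {
  vals <- unlist(peep)
  if (is.null(names(vals)) || any(!nzchar(names(vals)))) {
    rlr_error(sprintf("%s PEEP effects must be named by PEEP level", submodel),
              "coefficient_schema")
  }
  lv <- suppressWarnings(as.numeric(names(vals)))
  if (any(is.na(lv))) {
    rlr_error(sprintf("%s PEEP effect names must be numeric levels", submodel),
              "coefficient_schema")
  }
  if (!("0" %in% names(vals)) || vals[["0"]] != 0) {
    rlr_error(
      sprintf("%s PEEP effect at the reference level 0 must be exactly 0",
              submodel),
      "coefficient_schema"
    )
  }
  vals[order(lv)]
}

# Linear predictors, vectorised over rows of a validated covariate frame.
mu_linear_predictor <- function(coefs, covs) {
  m <- coefs$mu
  m$intercept +
    m$sqrt_mass * sqrt(covs$mass_g) +
    m$strain_wistar * (covs$strain == "wistar") +
    m$sex_male * (covs$sex == "male") +
    unname(m$peep[as.character(covs$peep_cmH2O)])
}

sigma_linear_predictor <- function(coefs, covs) {
  s <- coefs$sigma
  lp <- rep.int(s$intercept, nrow(covs))
  if (!is.null(s$mass)) lp <- lp + s$mass * covs$mass_g
  if (!is.null(s$strain_wistar)) {
    lp <- lp + s$strain_wistar * (covs$strain == "wistar")
  }
  if (!is.null(s$sex_male)) lp <- lp + s$sex_male * (covs$sex == "male")
  if (!is.null(s$peep)) lp <- lp + unname(s$peep[as.character(covs$peep_cmH2O)])
  lp
}

peep_levels_of <- function(coefs) as.numeric(names(coefs$mu$peep))

#' Load reference models from a coefficient document
#'
#' Reads a JSON coefficient document (one object per outcome, each with `mu`
#' and `sigma` blocks) and returns the corresponding reference models. With
#' no argument, the bundled coefficient set — the published final models for
#' Raw, G, H and EELV — is loaded.
#'
#' @param path Path to a coefficient JSON document, or `NULL` for the
#'   bundled published coefficients.
#' @return Named list of [reference_model()] objects, one per outcome.
#' @examples
#' models <- load_reference_coefficients()
#' models$raw$coefficients$mu$intercept
#' @export
load_reference_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_coefficients.json",
                        package = "ratlungref")
  }
  if (!file.exists(path)) {
    rlr_error(sprintf("coefficient document not found: %s", path), "io")
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  unknown <- setdiff(names(doc), .OUTCOME_NAMES)
  if (length(unknown)) {
    rlr_error(
      paste0("unknown outcome name(s) in coefficient document: ",
             paste(unknown, collapse = ", ")),
      "coefficient_schema"
    )
  }
  out <- lapply(names(doc), function(nm) {
    entry <- doc[[nm]]
    if (!all(c("mu", "sigma") %in% names(entry))) {
      rlr_error(
        sprintf("outcome '%s' must provide 'mu' and 'sigma' blocks", nm),
        "coefficient_schema"
      )
    }
    mu <- entry$mu
    sigma <- entry$sigma
    mu$peep <- unlist(mu$peep)
    if (!is.null(sigma$peep)) sigma$peep <- unlist(sigma$peep)
    reference_model(outcome_spec(nm),
                    location_scale_coefficients(mu, sigma))
  })
  names(out) <- names(doc)
  out[intersect(.OUTCOME_NAMES, names(out))]
}

# Serialise coefficients back to the document schema (named lists only).
coefficients_to_document <- function(coefs) {
  mu <- coefs$mu
  sigma <- coefs$sigma
  mu$peep <- as.list(mu$peep)
  if (!is.null(sigma$peep)) sigma$peep <- as.list(sigma$peep)
  list(mu = mu, sigma = sigma)
}

#' Write reference models to a coefficient document
#'
#' @param models Named list of [reference_model()] objects (names are
#'   outcome names).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_reference_coefficients <- function(models, path) {
  doc <- lapply(models, function(m) coefficients_to_document(m$coefficients))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
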