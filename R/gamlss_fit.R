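# Gaussian location-scale model fitting by full maximum likelihood.
#
# Model: T(y_i) ~ Normal(mu_i, sigma_i), with
#   mu_i    = x_i' beta      (x: intercept, sqrt(mass), strain, sex, PEEP dummies)
#   sigma_i = exp(s_i' gamma) (s: intercept, mass, strain, sex, PEEP dummies)
# where T is the natural log for Raw/G/H and the identity for EELV.
# Both submodels are estimated jointly by quasi-Newton maximization of the
# exact log-likelihood, followed by Newton polishing with the analytic
# Hessian; standard errors come from the observed information at the
# optimum.

.MU_TERMS <- c("sqrt_mass", "strain", "sex", "peep")
.SIGMA_TERMS <- c("mass", "strain", "sex", "peep")

#' Design specification for a location-scale fit
#'
#' Declares which candidate terms enter the mu and sigma submodels.
#' Intercepts are always included. The mu submodel uses the square root of
#' body mass; the sigma submodel uses untransformed mass. PEEP enters as
#' dummy variables against the reference level 0 cmH2O.
#'
#' @param outcome Outcome name or [outcome_spec()].
#' @param mu_terms Subset of `c("sqrt_mass", "strain", "sex", "peep")`.
#' @param sigma_terms Subset of `c("mass", "strain", "sex", "peep")`.
#' @return An object of class `design_spec`.
#' @seealso [default_design()] for the published final designs.
#' @export
design_spec <- function(outcome,
                        mu_terms = .MU_TERMS,
                        sigma_terms = character(0)) {
  if (is.character(outcome)) outcome <- outcome_spec(outcome)
  bad <- setdiff(mu_terms, .MU_TERMS)
  if (length(bad)) {
    rlr_error(paste0("unknown mu term(s): ", paste(bad, collapse = ", ")),
              "design")
  }
  bad <- setdiff(sigma_terms, .SIGMA_TERMS)
  if (length(bad)) {
    rlr_error(paste0("unknown sigma term(s): ", paste(bad, collapse = ", ")),
              "design")
  }
  structure(list(outcome = outcome, mu_terms = unique(mu_terms),
                 sigma_terms = unique(sigma_terms)),
            class = "design_spec")
}

#' Published final design per outcome
#'
#' Returns the [design_spec()] matching the published final model for an
#' outcome: all four mu terms for every outcome, and the sigma terms
#' retained in each final model (strain + PEEP for Raw, sex + PEEP for G,
#' mass + sex for H, all four for EELV).
#'
#' @param outcome Outcome name.
#' @export
default_design <- function(outcome) {
  outcome <- outcome_spec(outcome)
  sigma_terms <- switch(outcome$name,
    raw  = c("strain", "peep"),
    g    = c("sex", "peep"),
    h    = c("mass", "sex"),
    eelv = c("mass", "strain", "sex", "peep")
  )
  design_spec(outcome, .MU_TERMS, sigma_terms)
}

#' Build design matrices and response for a location-scale fit
#'
#' Constructs the mu design (intercept, sqrt(mass), strain and sex
#' indicators, PEEP dummies for levels 1, 2, 3, 4, 6), the sigma design
#' (same structure with untransformed mass) and the response on the
#' modelling scale. Rows with a missing response are dropped and counted.
#'
#' @param records Cohort data frame with columns `animal_id`, `strain`,
#'   `sex`, `mass_g`, `peep_cmH2O` and the outcome column (`raw`, `g`, `h`
#'   or `eelv_ml`).
#' @param spec A [design_spec()].
#' @return List with elements `mu_design`, `sigma_design`, `response`,
#'   `records_used`, `n_dropped`.
#' @export
build_design <- function(records, spec) {
  stopifnot(inherits(spec, "design_spec"))
  ycol <- outcome_column(spec$outcome$name)
  need <- c("strain", "sex", "mass_g", "peep_cmH2O", ycol)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    rlr_error(paste0("cohort table is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "cohort_schema")
  }
  keep <- !is.na(records[[ycol]])
  n_dropped <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) {
    rlr_error("no usable rows: every response value is missing",
              "empty_design")
  }
  covs <- covariate_set(records$mass_g, records$strain, records$sex,
                        records$peep_cmH2O)
  y <- transform_observed(spec$outcome, records[[ycol]])

  peep_dummies <- function() {
    lv <- setdiff(.PEEP_LEVELS, 0)
    m <- sapply(lv, function(p) as.numeric(covs$peep_cmH2O == p))
    colnames(m) <- paste0("peep_", lv)
    m
  }
  X <- cbind(intercept = rep(1, nrow(covs)))
  if ("sqrt_mass" %in% spec$mu_terms) X <- cbind(X, sqrt_mass = sqrt(covs$mass_g))
  if ("strain" %in% spec$mu_terms) {
    X <- cbind(X, strain_wistar = as.numeric(covs$strain == "wistar"))
  }
  if ("sex" %in% spec$mu_terms) {
    X <- cbind(X, sex_male = as.numeric(covs$sex == "male"))
  }
  if ("peep" %in% spec$mu_terms) X <- cbind(X, peep_dummies())

  S <- cbind(intercept = rep(1, nrow(covs)))
  if ("mass" %in% spec$sigma_terms) S <- cbind(S, mass = covs$mass_g)
  if ("strain" %in% spec$sigma_terms) {
    S <- cbind(S, strain_wistar = as.numeric(covs$strain == "wistar"))
  }
  if ("sex" %in% spec$sigma_terms) {
    S <- cbind(S, sex_male = as.numeric(covs$sex == "male"))
  }
  if ("peep" %in% spec$sigma_terms) S <- cbind(S, peep_dummies())

  list(mu_design = X, sigma_design = S, response = y,
       records_used = records, n_dropped = n_dropped)
}

outcome_column <- function(name) {
  c(raw = "raw", g = "g", h = "h", eelv = "eelv_ml")[[name]]
}

#' Control parameters for the location-scale fitter
#'
#' @param reltol Relative log-likelihood convergence tolerance for the
#'   quasi-Newton stage (default 1e-10).
#' @param grad_tol Max-norm gradient tolerance declaring convergence
#'   (default 1e-6).
#' @param maxit Maximum quasi-Newton iterations.
#' @param newton_maxit Maximum Newton polishing steps.
#' @export
fit_control <- function(reltol = 1e-10, grad_tol = 1e-6, maxit = 1000,
                        newton_maxit = 50) {
  list(reltol = reltol, grad_tol = grad_tol, maxit = maxit,
       newton_maxit = newton_maxit)
}

# Negative log-likelihood, gradient and Hessian for theta = c(beta, gamma).
ls_nll <- function(theta, X, S, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  s <- drop(S %*% theta[-seq_len(p)])
  r <- y - eta
  0.5 * length(y) * log(2 * pi) + sum(s) + 0.5 * sum(r^2 * exp(-2 * s))
}

ls_grad <- function(theta, X, S, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  s <- drop(S %*% theta[-seq_len(p)])
  r <- y - eta
  w <- exp(-2 * s)
  c(-crossprod(X, r * w), crossprod(S, 1 - r^2 * w))
}

ls_hessian <- function(theta, X, S, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  s <- drop(S %*% theta[-seq_len(p)])
  r <- y - eta
  w <- exp(-2 * s)
  Hbb <- crossprod(X, X * w)
  Hbg <- 2 * crossprod(X, S * (r * w))
  Hgg <- 2 * crossprod(S, S * (r^2 * w))
  rbind(cbind(Hbb, Hbg), cbind(t(Hbg), Hgg))
}

#' Fit the Gaussian location-scale model
#'
#' Jointly estimates the mu and sigma submodel coefficients by maximizing
#' the exact Gaussian log-likelihood with `sigma_i = exp(s_i' gamma)`.
#' Starting values are the ordinary-least-squares coefficients for mu and
#' the log of the maximum-likelihood residual standard deviation for the
#' sigma intercept (zeros elsewhere). A BFGS stage is followed by Newton
#' steps with the analytic Hessian until the gradient max-norm falls below
#' `control$grad_tol`; the `converged` flag reports whether that was
#' achieved. Standard errors are computed from the observed information.
#'
#' @param records Cohort data frame (see [build_design()]).
#' @param spec A [design_spec()].
#' @param control A [fit_control()] list.
#' @return An object of class `location_scale_fit` with elements
#'   `coefficients` (a [location_scale_coefficients()]), `mu_coef`,
#'   `sigma_coef`, `standard_errors`, `log_likelihood`, `n_obs`, `n_par`,
#'   `converged`, `r2_cox_snell`, `fitted` (original units), `residuals`
#'   (original units, observed - fitted), `residuals_transformed`
#'   (modelling scale, observed - fitted), `standardized_residuals`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(seed = 1))
#' fit <- fit_location_scale(cohort, default_design("raw"))
#' fit$mu_coef
#' }
#' @export
fit_location_scale <- function(records, spec, control = fit_control()) {
  d <- build_design(records, spec)
  X <- d$mu_design; S <- d$sigma_design; y <- d$response
  n <- length(y)
  npar <- ncol(X) + ncol(S)
  if (n <= npar) {
    rlr_error(sprintf("under-determined fit: %d observations for %d parameters",
                      n, npar),
              "underdetermined")
  }
  if (qr(X)$rank < ncol(X) || qr(S)$rank < ncol(S)) {
    rlr_error("rank-deficient design matrix", "rank_deficient")
  }

  # OLS start for beta; ML residual SD for the sigma intercept.
  ols <- stats::lm.fit(X, y)
  beta0 <- ols$coefficients
  sd_ml <- sqrt(mean(ols$residuals^2))
  gamma0 <- c(log(max(sd_ml, 1e-8)), rep(0, ncol(S) - 1L))
  theta0 <- c(beta0, gamma0)
  nll0 <- ls_nll(theta0, X, S, y)

  opt <- stats::optim(theta0, ls_nll, ls_grad, X = X, S = S, y = y,
                      method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  theta <- opt$par

  # Newton polish with step halving and ridge fallback.
  for (it in seq_len(control$newton_maxit)) {
    g <- ls_grad(theta, X, S, y)
    if (max(abs(g)) < control$grad_tol) break
    H <- ls_hessian(theta, X, S, y)
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-6 * max(abs(diag(H))), nrow(H)), g)
    })
    f_cur <- ls_nll(theta, X, S, y)
    lambda <- 1
    repeat {
      cand <- theta - lambda * step
      f_new <- ls_nll(cand, X, S, y)
      if (is.finite(f_new) && f_new <= f_cur + 1e-12) { theta <- cand; break }
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    if (lambda < 1e-10) break
  }
  g <- ls_grad(theta, X, S, y)
  converged <- max(abs(g)) < control$grad_tol
  ll <- -ls_nll(theta, X, S, y)
  stopifnot(ll >= -nll0 - 1e-8)  # optimizer never worsens the start

  H <- ls_hessian(theta, X, S, y)
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, npar))

  p <- ncol(X)
  beta <- stats::setNames(theta[seq_len(p)], colnames(X))
  gamma <- stats::setNames(theta[-seq_len(p)], colnames(S))
  mu_hat <- drop(X %*% beta)
  sigma_hat <- exp(drop(S %*% gamma))
  fitted_orig <- backtransform_mu(spec$outcome, mu_hat)
  observed_orig <- backtransform_mu(spec$outcome, y)

  fit <- structure(list(
    spec = spec,
    coefficients = coefficients_from_vectors(beta, gamma),
    mu_coef = beta,
    sigma_coef = gamma,
    standard_errors = list(
      mu = stats::setNames(se[seq_len(p)], colnames(X)),
      sigma = stats::setNames(se[-seq_len(p)], colnames(S))
    ),
    log_likelihood = ll,
    n_obs = n,
    n_par = npar,
    n_dropped = d$n_dropped,
    converged = converged,
    gradient_max = max(abs(g)),
    fitted = fitted_orig,
    residuals = observed_orig - fitted_orig,
    residuals_transformed = y - mu_hat,
    standardized_residuals = (y - mu_hat) / sigma_hat,
    sigma_fitted = sigma_hat,
    r2_cox_snell = NA_real_
  ), class = "location_scale_fit")

  # Cox-Snell R2 against the intercepts-only null on the same observations.
  if (length(spec$mu_terms) || length(spec$sigma_terms)) {
    null_spec <- design_spec(spec$outcome, character(0), character(0))
    null_fit <- fit_location_scale(d$records_used, null_spec, control)
    fit$r2_cox_snell <- cox_snell_r2(fit, null_fit)
  } else {
    fit$r2_cox_snell <- 0
  }
  fit
}

# Map fitted coefficient vectors back to the coefficient-document structure.
coefficients_from_vectors <- function(beta, gamma) {
  peep_of <- function(v) {
    idx <- grep("^peep_", names(v))
    if (!length(idx)) return(NULL)
    eff <- c("0" = 0, stats::setNames(unname(v[idx]),
                                      sub("^peep_", "", names(v)[idx])))
    eff
  }
  mu <- list(
    intercept = unname(beta[["intercept"]]),
    sqrt_mass = unname(beta["sqrt_mass"]) %0% 0,
    strain_wistar = unname(beta["strain_wistar"]) %0% 0,
    sex_male = unname(beta["sex_male"]) %0% 0,
    peep = peep_of(beta) %||% c("0" = 0)
  )
  sigma <- list(intercept = unname(gamma[["intercept"]]))
  if ("mass" %in% names(gamma)) sigma$mass <- unname(gamma[["mass"]])
  if ("strain_wistar" %in% names(gamma)) {
    sigma$strain_wistar <- unname(gamma[["strain_wistar"]])
  }
  if ("sex_male" %in% names(gamma)) sigma$sex_male <- unname(gamma[["sex_male"]])
  sp <- peep_of(gamma)
  if (!is.null(sp)) sigma$peep <- sp
  location_scale_coefficients(mu, sigma)
}

# NA-to-zero helper for optional design columns.
`%0%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' @export
print.location_scale_fit <- function(x, ...) {
  cat(sprintf("Gaussian location-scale fit: %s\n", x$spec$outcome$label))
  cat(sprintf("  n = %d (%d dropped), parameters = %d, logLik = %.3f\n",
              x$n_obs, x$n_dropped, x$n_par, x$log_likelihood))
  cat(sprintf("  converged: %s (|grad| = %.2e), Cox-Snell R2 = %.3f\n",
              x$converged, x$gradient_max, x$r2_cox_snell))
  cat("  mu coefficients:\n")
  print(round(x$mu_coef, 5))
  cat("  sigma coefficients (log scale):\n")
  print(round(x$sigma_coef, 5))
  invisible(x)
}

#' @export
logLik.location_scale_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_par, class = "logLik")
}

#' Cox-Snell pseudo-R-squared
#'
#' `1 - exp((2/n) * (l0 - l1))` where `l0` and `l1` are the null and
#' fitted log-likelihoods on the same observations.
#'
#' @param fitted,null_fitted `location_scale_fit` objects on identical
#'   observations; the null model has intercepts only in both submodels.
#' @return A value in `[0, 1)`.
#' @export
cox_snell_r2 <- function(fitted, null_fitted) {
  if (fitted$n_obs != null_fitted$n_obs) {
    rlr_error("models were fitted on different numbers of observations",
              "r2_mismatch")
  }
  n <- fitted$n_obs
  r2 <- 1 - exp((2 / n) * (null_fitted$log_likelihood - fitted$log_likelihood))
  max(0, r2)
}

#' Generalized Akaike information criterion
#'
#' `-2 * logLik + penalty * n_parameters`; `penalty = 2` is the ordinary
#' AIC.
#'
#' @param fitted A `location_scale_fit`.
#' @param penalty Positive penalty per parameter (default 2).
#' @export
gaic <- function(fitted, penalty = 2) {
  stopifnot(is_scalar_number(penalty), penalty >= 0)
  -2 * fitted$log_likelihood + penalty * fitted$n_par
}

#' Residual diagnostics for a location-scale fit
#'
#' Moments of the observed-minus-fitted residuals on the modelling scale
#' (log scale for Raw/G/H, original units for EELV), plus normal Q-Q points
#' for the standardized residuals.
#'
#' @param fitted A `location_scale_fit`.
#' @return An object of class `residual_diagnostics` with `mean`, `sd`,
#'   `skewness`, `excess_kurtosis`, `degenerate` flag, and `qq_points`
#'   (columns `theoretical`, `empirical`).
#' @export
residual_diagnostics <- function(fitted) {
  r <- fitted$residuals_transformed
  if (length(r) < 4L) {
    rlr_error("at least 4 residuals are required for moment diagnostics",
              "too_few_residuals")
  }
  s <- stats::sd(r)
  degenerate <- !is.finite(s) || s == 0
  zr <- sort(fitted$standardized_residuals)
  nq <- length(zr)
  qq <- data.frame(
    theoretical = stats::qnorm(stats::ppoints(nq)),
    empirical = zr
  )
  structure(list(
    mean = mean(r),
    sd = s,
    skewness = if (degenerate) NA_real_ else sample_skewness(r),
    excess_kurtosis = if (degenerate) NA_real_ else sample_excess_kurtosis(r),
    degenerate = degenerate,
    qq_points = qq
  ), class = "residual_diagnostics")
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat(sprintf(
    "Residuals (modelling scale): mean %.4f, sd %.4f, skew %.3f, ex.kurt %.3f\n",
    x$mean, x$sd, x$skewness, x$excess_kurtosis))
  if (x$degenerate) cat("  (degenerate residual spread; moments undefined)\n")
  invisible(x)
}

#' Write a fit report as JSON
#'
#' Serialises coefficients (coefficient-document schema), standard errors,
#' log-likelihood, GAIC, Cox-Snell R2 and residual diagnostics.
#'
#' @param fitted A `location_scale_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fitted, path) {
  diag <- residual_diagnostics(fitted)
  report <- list(
    outcome = fitted$spec$outcome$name,
    coefficients = coefficients_to_document(fitted$coefficients),
    standard_errors = lapply(fitted$standard_errors, as.list),
    log_likelihood = fitted$log_likelihood,
    n_obs = fitted$n_obs,
    n_dropped = fitted$n_dropped,
    n_par = fitted$n_par,
    converged = fitted$converged,
    gaic = gaic(fitted),
    r2_cox_snell = fitted$r2_cox_snell,
    residual_diagnostics = list(
      mean = diag$mean, sd = diag$sd, skewness = diag$skewness,
      excess_kurtosis = diag$excess_kurtosis
    )
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
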