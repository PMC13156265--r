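# Synthetic rat cohorts with the covariate structure the reference models
# assume: four strain x sex groups with right-skewed body-mass
# distributions matching the study's printed medians and ranges, and
# outcomes drawn from the Gaussian location-scale model on the modelling
# scale at each PEEP level.

#' Body-mass specification for one strain x sex group
#'
#' @param strain,sex Group identity.
#' @param n Number of animals.
#' @param median_g,min_g,max_g Median and range of body mass in grams
#'   (`min_g < median_g < max_g`).
#' @return An object of class `group_mass_spec`.
#' @export
group_mass_spec <- function(strain, sex, n, median_g, min_g, max_g) {
  strain <- match.arg(strain, .STRAINS)
  sex <- match.arg(sex, .SEXES)
  if (!(is_scalar_number(n) && n >= 1)) {
    rlr_error("n must be a positive integer", "group_spec")
  }
  if (!(min_g < median_g && median_g < max_g)) {
    rlr_error("group mass spec requires min_g < median_g < max_g",
              "group_spec")
  }
  if (min_g <= 0) rlr_error("min_g must be positive", "group_spec")
  structure(list(strain = strain, sex = sex, n = as.integer(n),
                 median_g = median_g, min_g = min_g, max_g = max_g),
            class = "group_mass_spec")
}

#' Default study-cohort group specifications
#'
#' The four strain x sex groups with the study's group sizes, median body
#' masses and mass ranges: 52 male Sprague Dawley (317 g, 170-750 g),
#' 46 female Sprague Dawley (258 g, 164-376 g), 53 male Wistar (310 g,
#' 156-530 g) and 31 female Wistar (260 g, 162-366 g); 182 animals in
#' total.
#'
#' @return List of four [group_mass_spec()] objects.
#' @export
default_group_specs <- function() {
  list(
    group_mass_spec("sprague_dawley", "male", 52, 317, 170, 750),
    group_mass_spec("sprague_dawley", "female", 46, 258, 164, 376),
    group_mass_spec("wistar", "male", 53, 310, 156, 530),
    group_mass_spec("wistar", "female", 31, 260, 162, 366)
  )
}

#' Sample right-skewed body masses for one group
#'
#' Draws from a log-normal distribution truncated to `[min_g, max_g]`, with
#' location `log(median_g)` (median-preserving before truncation) and scale
#' set so the central 95% of the untruncated distribution spans the printed
#' range: `sdlog = (log(max_g) - log(min_g)) / (2 * 1.96)`. Sampling is by
#' inverse CDF, so output is fully determined by the R random-number state.
#'
#' @param spec A [group_mass_spec()].
#' @param n Number of draws (default `spec$n`).
#' @return Numeric vector of body masses in grams, all inside
#'   `[min_g, max_g]`.
#' @export
sample_body_mass <- function(spec, n = spec$n) {
  stopifnot(inherits(spec, "group_mass_spec"))
  meanlog <- log(spec$median_g)
  sdlog <- (log(spec$max_g) - log(spec$min_g)) / (2 * stats::qnorm(0.975))
  plo <- stats::plnorm(spec$min_g, meanlog, sdlog)
  phi <- stats::plnorm(spec$max_g, meanlog, sdlog)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qlnorm(u, meanlog, sdlog), spec$min_g), spec$max_g)
}

#' Cohort simulation configuration
#'
#' @param group_specs List of [group_mass_spec()]; defaults to the study
#'   groups ([default_group_specs()]).
#' @param peep_levels PEEP levels measured per animal; default all six
#'   study levels.
#' @param seed Integer seed; fully determines the simulated cohort.
#' @param p_missing_eelv_top_peep Probability that EELV is missing at the
#'   highest PEEP level (emulating animals without usable breathing efforts
#'   there); default 0.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_specs = default_group_specs(),
                          peep_levels = .PEEP_LEVELS,
                          seed = 1L,
                          p_missing_eelv_top_peep = 0) {
  bad_peep <- setdiff(peep_levels, .PEEP_LEVELS)
  if (length(bad_peep)) {
    rlr_error(paste0("unsupported PEEP level(s): ",
                     paste(bad_peep, collapse = ", ")),
              "config")
  }
  if (p_missing_eelv_top_peep < 0 || p_missing_eelv_top_peep > 1) {
    rlr_error("p_missing_eelv_top_peep must be in [0, 1]", "config")
  }
  structure(list(group_specs = group_specs,
                 peep_levels = sort(unique(peep_levels)),
                 seed = as.integer(seed),
                 p_missing_eelv_top_peep = p_missing_eelv_top_peep),
            class = "cohort_config")
}

#' Generate outcome measurements for a table of animals
#'
#' For each animal x PEEP combination draws `T(y) ~ Normal(mu, sigma)`
#' under the supplied reference models and back-transforms (`exp` for
#' Raw/G/H). Measurement noise is independent across PEEP levels within an
#' animal. EELV at the highest PEEP level is set missing with probability
#' `p_missing_eelv_top_peep`.
#'
#' @param animals Data frame with columns `animal_id`, `strain`, `sex`,
#'   `mass_g`.
#' @param models Named list of [reference_model()] objects covering all
#'   four outcomes (e.g. [load_reference_coefficients()]).
#' @param peep_levels PEEP levels to measure.
#' @param p_missing_eelv_top_peep See [cohort_config()].
#' @return Cohort data frame with columns `animal_id`, `strain`, `sex`,
#'   `mass_g`, `peep_cmH2O`, `raw`, `g`, `h`, `eelv_ml`.
#' @export
generate_measurements <- function(animals, models,
                                  peep_levels = .PEEP_LEVELS,
                                  p_missing_eelv_top_peep = 0) {
  need <- setdiff(.OUTCOME_NAMES, names(models))
  if (length(need)) {
    rlr_error(paste0("models must cover all outcomes; missing: ",
                     paste(need, collapse = ", ")),
              "config")
  }
  peep_levels <- sort(unique(peep_levels))
  rows <- merge(animals, data.frame(peep_cmH2O = peep_levels), by = NULL)
  rows <- rows[order(match(rows$animal_id, animals$animal_id),
                     rows$peep_cmH2O), , drop = FALSE]
  covs <- covariate_set(rows$mass_g, rows$strain, rows$sex, rows$peep_cmH2O)
  for (nm in .OUTCOME_NAMES) {
    model <- models[[nm]]
    mu <- mu_linear_predictor(model$coefficients, covs)
    sigma <- exp(sigma_linear_predictor(model$coefficients, covs))
    ty <- stats::rnorm(nrow(covs), mu, sigma)
    rows[[outcome_column(nm)]] <- backtransform_mu(model$spec, ty)
  }
  if (p_missing_eelv_top_peep > 0) {
    top <- rows$peep_cmH2O == max(peep_levels)
    drop <- top & stats::runif(nrow(rows)) < p_missing_eelv_top_peep
    rows$eelv_ml[drop] <- NA_real_
  }
  rownames(rows) <- NULL
  rows
}

#' Simulate a complete synthetic cohort
#'
#' Samples body masses per group, assigns animal ids, and generates all
#' four outcomes at every configured PEEP level. The configuration seed
#' fully determines the result.
#'
#' @param config A [cohort_config()].
#' @param models Named list of reference models; defaults to the bundled
#'   published models.
#' @return Cohort data frame (see [generate_measurements()]).
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 42))
#' head(cohort)
#' @export
simulate_cohort <- function(config = cohort_config(),
                            models = load_reference_coefficients()) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  animals <- do.call(rbind, lapply(config$group_specs, function(gs) {
    data.frame(strain = gs$strain, sex = gs$sex,
               mass_g = sample_body_mass(gs),
               stringsAsFactors = FALSE)
  }))
  animals$animal_id <- sprintf("rat_%03d", seq_len(nrow(animals)))
  animals <- animals[c("animal_id", "strain", "sex", "mass_g")]
  generate_measurements(animals, models, config$peep_levels,
                        config$p_missing_eelv_top_peep)
}

.COHORT_COLUMNS <- c("animal_id", "strain", "sex", "mass_g", "peep_cmH2O",
                     "raw", "g", "h", "eelv_ml")

#' Write a cohort table to delimited text
#'
#' Comma-separated, stable column order, empty cells for missing values.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(.COHORT_COLUMNS, names(cohort))
  if (length(missing_cols)) {
    rlr_error(paste0("cohort table is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "cohort_schema")
  }
  utils::write.csv(cohort[.COHORT_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read and validate a cohort table
#'
#' Reads a comma-separated cohort table, enforcing the column schema,
#' strain/sex/PEEP enumerations and positivity constraints. Violations are
#' reported with row and column.
#'
#' @param path Input path.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    rlr_error(sprintf("cohort file not found: %s", path), "io")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing_cols <- setdiff(.COHORT_COLUMNS, names(df))
  if (length(missing_cols)) {
    rlr_error(paste0("cohort table is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "cohort_schema")
  }
  v <- validate_cohort(df)
  if (nrow(v)) {
    rlr_error(paste0("invalid cohort table: ",
                     paste(utils::head(sprintf("row %d, %s: %s", v$row,
                                               v$column, v$message), 5),
                           collapse = "; "),
                     if (nrow(v) > 5) sprintf(" (and %d more)", nrow(v) - 5)
                     else ""),
              "cohort_schema")
  }
  df
}

# Per-row schema validation; returns a data.frame of violations.
validate_cohort <- function(df) {
  violations <- list()
  add <- function(rows, column, message) {
    if (length(rows)) {
      violations[[length(violations) + 1L]] <<-
        data.frame(row = rows, column = column, message = message,
                   stringsAsFactors = FALSE)
    }
  }
  add(which(!(df$strain %in% .STRAINS)), "strain", "unknown strain")
  add(which(!(df$sex %in% .SEXES)), "sex", "unknown sex")
  add(which(is.na(df$mass_g) | df$mass_g <= 0), "mass_g",
      "must be a positive number")
  add(which(!(df$peep_cmH2O %in% .PEEP_LEVELS)), "peep_cmH2O",
      "not a study PEEP level (0, 1, 2, 3, 4, 6)")
  for (col in c("raw", "g", "h")) {
    add(which(!is.na(df[[col]]) & df[[col]] <= 0), col,
        "must be positive when present")
  }
  if (length(violations)) do.call(rbind, violations)
  else data.frame(row = integer(0), column = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}
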