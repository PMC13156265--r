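# Shared fixtures: bundled models and small simulated cohorts.

bundled_models <- load_reference_coefficients()

# Balanced synthetic cohort with uniform masses, for parameter-recovery
# tests (covariates span the full applicability range).
make_balanced_cohort <- function(n_animals, seed, models = bundled_models,
                                 mass_range = c(160, 750)) {
  set.seed(seed)
  animals <- data.frame(
    animal_id = sprintf("a%04d", seq_len(n_animals)),
    strain = rep(c("sprague_dawley", "wistar"), length.out = n_animals),
    sex = rep(c("female", "female", "male", "male"),
              length.out = n_animals),
    mass_g = stats::runif(n_animals, mass_range[1], mass_range[2]),
    stringsAsFactors = FALSE
  )
  generate_measurements(animals, models)
}

# A small grid of valid covariate combinations across the whole domain.
covariate_grid <- function(masses = c(180, 250, 350)) {
  expand.grid(mass_g = masses,
              strain = c("sprague_dawley", "wistar"),
              sex = c("female", "male"),
              peep_cmH2O = c(0, 1, 2, 3, 4, 6),
              stringsAsFactors = FALSE)
}
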