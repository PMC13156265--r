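# Plethysmographic end-expiratory lung volume (EELV).
#
# During a 10-15 s tracheal occlusion the animal makes spontaneous
# inspiratory efforts against the closed airway. Boyle-Mariotte
# compression/decompression of the trapped thoracic gas links the box and
# tracheal pressure swings:
#   EELV = -s * beta * (Vbox - Vrat) - Vds,
# where s = dPbox/dPtrach is the regression slope over inspiratory-effort
# samples, beta = (Patm - PH2O)/Patm corrects alveolar gas for water vapour
# at body temperature, Vrat = mass / body density, and Vds is the
# instrumental dead space of the tracheal cannula.

#' Plethysmograph configuration
#'
#' @param v_box_ml Chamber volume in ml (default 1910).
#' @param p_atm Atmospheric pressure (default 760 mmHg).
#' @param p_h2o Water vapour pressure at body temperature (default 47 mmHg
#'   at 37 C). Must be below `p_atm`; any pressure unit may be used as long
#'   as both fields share it.
#' @param body_density_g_per_cm3 Average rat body density (default 1.025).
#' @param v_ds_ml Instrumental dead space (ml) per cannula outer diameter:
#'   0.53 for the 2.0 mm and 0.65 for the 2.5 mm cannula.
#' @return An object of class `plethysmograph_config`.
#' @export
plethysmograph_config <- function(v_box_ml = 1910, p_atm = 760, p_h2o = 47,
                                  body_density_g_per_cm3 = 1.025,
                                  v_ds_ml = c("2.0" = 0.53, "2.5" = 0.65)) {
  if (p_h2o >= p_atm) {
    rlr_error("p_h2o must be below p_atm", "config")
  }
  if (v_box_ml <= 0 || body_density_g_per_cm3 <= 0) {
    rlr_error("chamber volume and body density must be positive", "config")
  }
  structure(list(v_box_ml = v_box_ml, p_atm = p_atm, p_h2o = p_h2o,
                 body_density_g_per_cm3 = body_density_g_per_cm3,
                 v_ds_ml = v_ds_ml),
            class = "plethysmograph_config")
}

#' Water-vapour correction factor
#'
#' `beta = (p_atm - p_h2o) / p_atm`, in (0, 1); a pure ratio, invariant to
#' the pressure unit.
#'
#' @param config A [plethysmograph_config()].
#' @export
beta_factor <- function(config = plethysmograph_config()) {
  (config$p_atm - config$p_h2o) / config$p_atm
}

#' Occlusion pressure trace
#'
#' Paired tracheal and box pressure time series sampled uniformly during a
#' tracheal occlusion.
#'
#' @param time_s Sample times in seconds (uniform spacing).
#' @param p_trach,p_box Tracheal and box pressures (cmH2O), one per sample.
#' @param sampling_rate_hz Sampling rate (default 256).
#' @return An object of class `occlusion_trace`.
#' @export
occlusion_trace <- function(time_s, p_trach, p_box,
                            sampling_rate_hz = 256) {
  if (length(time_s) != length(p_trach) ||
      length(time_s) != length(p_box)) {
    rlr_error("time, tracheal and box pressure vectors must have equal length",
              "trace_schema")
  }
  if (length(time_s) > 2) {
    dt <- diff(time_s)
    if (max(dt) - min(dt) > 1e-6 * mean(dt)) {
      rlr_error("sampling must be uniform", "trace_schema")
    }
  }
  structure(list(time_s = time_s, p_trach = p_trach, p_box = p_box,
                 sampling_rate_hz = sampling_rate_hz),
            class = "occlusion_trace")
}

#' Detect inspiratory-effort samples
#'
#' Identifies samples belonging to inspiratory efforts against the closed
#' trachea: baseline tracheal pressure is the median of the first
#' `baseline_s` seconds (pre-effort occlusion baseline), and a sample is
#' selected when its inspiratory deflection (baseline minus tracheal
#' pressure; occluded inspiratory efforts lower tracheal pressure) exceeds
#' the threshold. The automatic threshold is `auto_fraction` (default 0.20)
#' of the maximal deflection, which excludes low-amplitude cardiogenic
#' oscillations.
#'
#' @param trace An [occlusion_trace()].
#' @param threshold Numeric threshold in cmH2O, or `"auto"`.
#' @param baseline_s Seconds of the initial trace segment used for the
#'   baseline median (default 1).
#' @param auto_fraction Fraction of the maximal deflection used by the
#'   automatic threshold.
#' @return Integer vector of selected sample indices.
#' @export
detect_effort_samples <- function(trace, threshold = "auto",
                                  baseline_s = 1, auto_fraction = 0.20) {
  stopifnot(inherits(trace, "occlusion_trace"))
  base_idx <- trace$time_s <= trace$time_s[1] + baseline_s
  baseline <- stats::median(trace$p_trach[base_idx])
  deflection <- baseline - trace$p_trach
  if (identical(threshold, "auto")) {
    peak <- max(deflection)
    if (peak <= 0) {
      rlr_error("no inspiratory deflection found in trace (no usable effort)",
                "no_effort")
    }
    threshold <- auto_fraction * peak
  }
  idx <- which(deflection > threshold)
  if (!length(idx)) {
    rlr_error("no samples exceed the effort threshold (no usable effort)",
              "no_effort")
  }
  idx
}

#' Regress box pressure on tracheal pressure
#'
#' Least-squares regression of `p_box` on `p_trach` over the selected
#' samples; the slope `s = dPbox/dPtrach` enters the EELV formula and the
#' r-squared quantifies the linearity check.
#'
#' @param trace An [occlusion_trace()].
#' @param indices Sample indices from [detect_effort_samples()].
#' @return List with `slope`, `intercept`, `r2`, `n`.
#' @export
regress_box_vs_tracheal <- function(trace, indices) {
  if (length(indices) < 3L) {
    rlr_error("at least 3 samples are required for the regression",
              "too_few_samples")
  }
  x <- trace$p_trach[indices]
  y <- trace$p_box[indices]
  if (stats::var(x) == 0) {
    rlr_error("tracheal pressure has zero variance over selected samples",
              "degenerate_variance")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  list(slope = unname(slope), intercept = unname(fit$coefficients[1]),
       r2 = r2, n = length(indices))
}

#' Compute EELV from the regression slope
#'
#' Boyle-Mariotte relation:
#' `EELV = -slope * beta * (v_box - v_rat) - v_ds`, with `v_rat = mass_g /
#' body density`. A non-positive result is flagged invalid.
#'
#' @param slope Regression slope `dPbox/dPtrach`.
#' @param config A [plethysmograph_config()].
#' @param mass_g Body mass in grams.
#' @param cannula Cannula outer diameter, `"2.0"` or `"2.5"` mm.
#' @return List with `eelv_ml`, `v_rat_ml`, `beta`, `v_ds_ml`, `valid`.
#' @examples
#' compute_eelv(-0.007, plethysmograph_config(), mass_g = 300,
#'              cannula = "2.5")
#' @export
compute_eelv <- function(slope, config = plethysmograph_config(), mass_g,
                         cannula = c("2.0", "2.5")) {
  cannula <- match.arg(as.character(cannula), names(config$v_ds_ml))
  if (mass_g <= 0) rlr_error("mass_g must be positive", "covariates")
  v_rat <- mass_g / config$body_density_g_per_cm3
  if (v_rat >= config$v_box_ml) {
    rlr_error("animal volume equals or exceeds chamber volume", "config")
  }
  v_ds <- unname(config$v_ds_ml[[cannula]])
  eelv <- -slope * beta_factor(config) * (config$v_box_ml - v_rat) - v_ds
  list(eelv_ml = eelv, v_rat_ml = v_rat, beta = beta_factor(config),
       v_ds_ml = v_ds, valid = eelv > 0)
}

#' Full EELV measurement pipeline on a trace
#'
#' Detects inspiratory-effort samples, regresses box on tracheal pressure,
#' verifies linearity (`r2 >= r2_min`), and evaluates the Boyle-Mariotte
#' formula. The EELV value is reported only when the linearity check
#' passes.
#'
#' @inheritParams detect_effort_samples
#' @inheritParams compute_eelv
#' @param r2_min Minimum r-squared accepted by the linearity check
#'   (default 0.95).
#' @return An object of class `eelv_result` with `slope_s`, `r2_linearity`,
#'   `eelv_ml` (NA when linearity fails), `n_points_used`, `valid`.
#' @export
measure_eelv <- function(trace, config = plethysmograph_config(), mass_g,
                         cannula = c("2.0", "2.5"), threshold = "auto",
                         baseline_s = 1, r2_min = 0.95) {
  idx <- detect_effort_samples(trace, threshold, baseline_s)
  reg <- regress_box_vs_tracheal(trace, idx)
  linear_ok <- reg$r2 >= r2_min
  vol <- compute_eelv(reg$slope, config, mass_g, cannula)
  structure(list(
    slope_s = reg$slope,
    r2_linearity = reg$r2,
    eelv_ml = if (linear_ok) vol$eelv_ml else NA_real_,
    n_points_used = reg$n,
    valid = linear_ok && vol$valid
  ), class = "eelv_result")
}

#' @export
print.eelv_result <- function(x, ...) {
  cat(sprintf("EELV: %s ml (slope %.5f, r2 %.4f, %d samples)%s\n",
              ifelse(is.na(x$eelv_ml), "NA", sprintf("%.2f", x$eelv_ml)),
              x$slope_s, x$r2_linearity, x$n_points_used,
              if (!x$valid) " [invalid]" else ""))
  invisible(x)
}

#' Simulate an occluded-breathing trace at a known EELV
#'
#' Inverts the Boyle-Mariotte formula to obtain the box-to-tracheal slope
#' implied by `eelv_true_ml`, `slope = -(eelv + v_ds) / (beta * (v_box -
#' v_rat))`, and synthesises a trace at 256 Hz: an initial effort-free
#' baseline segment, sinusoid-like negative tracheal deflections
#' (inspiratory efforts against the closed airway), the implied linear box
#' response, and optional cardiogenic ripple and sensor noise.
#'
#' @inheritParams compute_eelv
#' @param eelv_true_ml True EELV in ml (> 0).
#' @param effort_amplitude_cmH2O Peak inspiratory deflection (default 8).
#' @param n_efforts Number of efforts (default 10).
#' @param duration_s Trace duration in seconds (default 12, within the
#'   10-15 s occlusion window).
#' @param baseline_s Effort-free initial segment (default 1 s).
#' @param cardiogenic_amplitude_cmH2O Amplitude of a 5 Hz cardiogenic
#'   ripple added to the tracheal signal (default 0).
#' @param noise_sd_cmH2O Gaussian sensor noise SD added to both channels
#'   (default 0).
#' @return An [occlusion_trace()].
#' @export
simulate_occlusion <- function(eelv_true_ml,
                               config = plethysmograph_config(),
                               mass_g, cannula = c("2.0", "2.5"),
                               effort_amplitude_cmH2O = 8,
                               n_efforts = 10, duration_s = 12,
                               baseline_s = 1,
                               cardiogenic_amplitude_cmH2O = 0,
                               noise_sd_cmH2O = 0) {
  if (eelv_true_ml <= 0) rlr_error("eelv_true_ml must be positive", "config")
  cannula <- match.arg(as.character(cannula), names(config$v_ds_ml))
  v_rat <- mass_g / config$body_density_g_per_cm3
  v_ds <- unname(config$v_ds_ml[[cannula]])
  slope <- -(eelv_true_ml + v_ds) /
    (beta_factor(config) * (config$v_box_ml - v_rat))

  fs <- 256
  t <- seq(0, duration_s, by = 1 / fs)
  p_trach_clean <- numeric(length(t))
  effort_window <- duration_s - baseline_s
  effort_period <- effort_window / n_efforts
  effort_duration <- 0.6 * effort_period  # inspiratory phase of each cycle
  for (k in seq_len(n_efforts)) {
    t0 <- baseline_s + (k - 1) * effort_period
    in_effort <- t >= t0 & t < t0 + effort_duration
    phase <- (t[in_effort] - t0) / effort_duration
    p_trach_clean[in_effort] <- -effort_amplitude_cmH2O * sin(pi * phase)
  }
  p_box_clean <- slope * p_trach_clean

  p_trach <- p_trach_clean
  if (cardiogenic_amplitude_cmH2O > 0) {
    p_trach <- p_trach +
      cardiogenic_amplitude_cmH2O * sin(2 * pi * 5 * t)
  }
  if (noise_sd_cmH2O > 0) {
    p_trach <- p_trach + stats::rnorm(length(t), 0, noise_sd_cmH2O)
    p_box_clean <- p_box_clean +
      stats::rnorm(length(t), 0, abs(slope) * noise_sd_cmH2O)
  }
  occlusion_trace(t, p_trach, p_box_clean, fs)
}

#' Read / write an occlusion trace as delimited text
#'
#' Columns: `time_s`, `p_trach_cmH2O`, `p_box_cmH2O` (comma-separated).
#'
#' @param path File path.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    rlr_error(sprintf("trace file not found: %s", path), "io")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "p_trach_cmH2O", "p_box_cmH2O")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    rlr_error(paste0("trace file is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "trace_schema")
  }
  rate <- if (nrow(df) > 1) 1 / stats::median(diff(df$time_s)) else 256
  occlusion_trace(df$time_s, df$p_trach_cmH2O, df$p_box_cmH2O, rate)
}

#' @rdname read_trace
#' @param trace An [occlusion_trace()].
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace$time_s, p_trach_cmH2O = trace$p_trach,
               p_box_cmH2O = trace$p_box),
    path, row.names = FALSE)
  invisible(path)
}
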