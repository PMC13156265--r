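# Constant-phase model of respiratory input impedance:
#   Zrs(f) = Raw + i*omega*Iaw + (G - i*H) / omega^alpha,
#   omega = 2*pi*f,  alpha = (2/pi) * atan(H/G).
# Includes spectrum synthesis, equipment-impedance subtraction, ensemble
# averaging, and a relative-error least-squares fit.

#' Forced-oscillation frequency grid
#'
#' The default grid contains 23 components in 0.5-20.75 Hz, each a prime
#' multiple of the 0.25 Hz base frequency (primes 2-83). Distinct prime
#' multiples are pairwise non-harmonic: no component is an integer multiple
#' of another, which keeps harmonic distortion products of one component
#' from contaminating another in a pseudorandom forcing signal.
#'
#' @param frequencies_hz Optional explicit frequency vector (positive,
#'   strictly increasing). Default: the 23-component prime-multiple grid.
#' @param base_hz Base frequency in Hz (default 0.25).
#' @return An object of class `frequency_grid` with fields
#'   `frequencies_hz`, `base_hz`, `omega` (rad/s).
#' @export
frequency_grid <- function(frequencies_hz = NULL, base_hz = 0.25) {
  if (is.null(frequencies_hz)) {
    primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47,
                53, 59, 61, 67, 71, 73, 79, 83)
    frequencies_hz <- primes * base_hz
  }
  frequencies_hz <- as.numeric(frequencies_hz)
  if (any(frequencies_hz <= 0)) {
    rlr_error("frequencies must be strictly positive", "frequency")
  }
  if (is.unsorted(frequencies_hz, strictly = TRUE)) {
    rlr_error("frequencies must be strictly increasing", "frequency")
  }
  structure(list(frequencies_hz = frequencies_hz, base_hz = base_hz,
                 omega = 2 * pi * frequencies_hz),
            class = "frequency_grid")
}

#' Complex respiratory input impedance over a frequency grid
#'
#' @param grid A [frequency_grid()].
#' @param z Complex vector of impedance values (cmH2O.s/l), one per
#'   frequency.
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(grid, z) {
  stopifnot(inherits(grid, "frequency_grid"))
  z <- as.complex(z)
  if (length(z) != length(grid$frequencies_hz)) {
    rlr_error("impedance vector length must match the frequency grid",
              "grid_mismatch")
  }
  structure(list(grid = grid, z = z), class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: %d frequencies, %.2f-%.2f Hz\n",
              length(x$z), min(x$grid$frequencies_hz),
              max(x$grid$frequencies_hz)))
  invisible(x)
}

#' Constant-phase exponent from tissue parameters
#'
#' `alpha = (2/pi) * atan(h/g)`, strictly inside (0, 1) for positive
#' arguments; equals 0.5 exactly when `g == h`.
#'
#' @param g Tissue damping (> 0), cmH2O/l.
#' @param h Tissue elastance (> 0), cmH2O/l.
#' @export
alpha_from_gh <- function(g, h) {
  if (any(g <= 0) || any(h <= 0)) {
    rlr_error("g and h must be strictly positive", "params")
  }
  (2 / pi) * atan(h / g)
}

#' Constant-phase model parameters
#'
#' @param raw Newtonian airway resistance (>= 0), cmH2O.s/l.
#' @param iaw Airway inertance (>= 0), cmH2O.s^2/l.
#' @param g Tissue damping (> 0), cmH2O/l.
#' @param h Tissue elastance (> 0), cmH2O/l.
#' @return Object of class `constant_phase_params`; `alpha` is always
#'   recomputed from `g` and `h`, never stored independently.
#' @export
constant_phase_params <- function(raw, iaw, g, h) {
  if (raw < 0 || iaw < 0) {
    rlr_error("raw and iaw must be non-negative", "params")
  }
  structure(list(raw = raw, iaw = iaw, g = g, h = h,
                 alpha = alpha_from_gh(g, h)),
            class = "constant_phase_params")
}

#' @export
print.constant_phase_params <- function(x, ...) {
  cat(sprintf(
    "Constant-phase parameters: Raw %.4g, Iaw %.4g, G %.4g, H %.4g (alpha %.4f)\n",
    x$raw, x$iaw, x$g, x$h, x$alpha))
  invisible(x)
}

#' Synthesize model impedance on a frequency grid
#'
#' Evaluates `Z = raw + i*omega*iaw + (g - i*h)/omega^alpha` per frequency.
#'
#' @param params A [constant_phase_params()].
#' @param grid A [frequency_grid()].
#' @return An [impedance_spectrum()].
#' @export
model_impedance <- function(params, grid = frequency_grid()) {
  stopifnot(inherits(params, "constant_phase_params"),
            inherits(grid, "frequency_grid"))
  w <- grid$omega
  z <- params$raw + 1i * w * params$iaw +
    (params$g - 1i * params$h) / w^params$alpha
  impedance_spectrum(grid, z)
}

check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$grid$frequencies_hz, b$grid$frequencies_hz))) {
    rlr_error("spectra are on different frequency grids", "grid_mismatch")
  }
}

#' Subtract equipment impedance from a measured spectrum
#'
#' Elementwise complex subtraction of the separately measured impedance of
#' the endotracheal tube and connections.
#'
#' @param spectrum,equipment_spectrum [impedance_spectrum()] objects on the
#'   same grid.
#' @export
subtract_reference_impedance <- function(spectrum, equipment_spectrum) {
  check_same_grid(spectrum, equipment_spectrum)
  impedance_spectrum(spectrum$grid, spectrum$z - equipment_spectrum$z)
}

#' Ensemble-average impedance spectra
#'
#' Complex mean per frequency over consecutive recordings.
#'
#' @param spectra Non-empty list of [impedance_spectrum()] objects on a
#'   common grid.
#' @export
ensemble_average <- function(spectra) {
  if (!length(spectra)) rlr_error("no spectra to average", "empty_input")
  for (s in spectra[-1]) check_same_grid(spectra[[1]], s)
  zm <- Reduce(`+`, lapply(spectra, `[[`, "z")) / length(spectra)
  impedance_spectrum(spectra[[1]]$grid, zm)
}

# Relative residual vector: (Re, Im) differences scaled by |Z_meas|; its
# sum of squares is sum(|Z_meas - Z_model|^2 / |Z_meas|^2).
cp_residuals <- function(par, w, zm, zmod_abs) {
  raw <- par[1]; iaw <- par[2]; g <- exp(par[3]); h <- exp(par[4])
  alpha <- (2 / pi) * atan(h / g)
  zmodel <- raw + 1i * w * iaw + (g - 1i * h) / w^alpha
  d <- (zm - zmodel) / zmod_abs
  c(Re(d), Im(d))
}

#' Fit the constant-phase model to an impedance spectrum
#'
#' Minimizes the relative least-squares objective
#' `sum(|Z_meas - Z_model|^2 / |Z_meas|^2)` over `(raw, iaw, g, h)` with
#' `raw, iaw >= 0` (box bounds) and `g, h > 0` (log parameterisation),
#' using Levenberg-Marquardt. Default initialisation reads the asymptotes:
#' the tissue parameters from the lowest-frequency point with `alpha`
#' seeded at 0.8, and `raw`/`iaw` from the highest-frequency real and
#' imaginary parts after removing the seeded tissue contribution.
#'
#' @param spectrum An [impedance_spectrum()] with at least 4 frequencies
#'   and no zero-magnitude points.
#' @param init Optional [constant_phase_params()] starting values.
#' @return List with `params` ([constant_phase_params()]) and `quality`
#'   (class `fit_quality`: `relative_rms_error`, `objective`, `converged`,
#'   `n_freq`).
#' @examples
#' truth <- constant_phase_params(raw = 50, iaw = 0.2, g = 1000, h = 4500)
#' fit <- fit_constant_phase(model_impedance(truth))
#' fit$params
#' @export
fit_constant_phase <- function(spectrum, init = NULL) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  w <- spectrum$grid$omega
  zm <- spectrum$z
  if (length(zm) < 4L) {
    rlr_error("at least 4 frequencies are required to fit 4 parameters",
              "too_few_frequencies")
  }
  zabs <- Mod(zm)
  if (any(zabs == 0)) {
    rlr_error("degenerate spectrum: zero-magnitude impedance point",
              "degenerate_spectrum")
  }

  if (is.null(init)) {
    a0 <- 0.8
    n <- length(w)
    g0 <- max(Re(zm[1]) * w[1]^a0, 1e-6 * zabs[1])
    h0 <- max(-Im(zm[1]) * w[1]^a0, 1e-6 * zabs[1])
    raw0 <- max(Re(zm[n]) - g0 / w[n]^a0, 1e-3 * zabs[1])
    iaw0 <- max((Im(zm[n]) + h0 / w[n]^a0) / w[n], 0)
    start <- c(raw0, iaw0, log(g0), log(h0))
  } else {
    stopifnot(inherits(init, "constant_phase_params"))
    start <- c(init$raw, init$iaw, log(init$g), log(init$h))
  }

  fit <- minpack.lm::nls.lm(
    par = start, fn = cp_residuals, w = w, zm = zm, zmod_abs = zabs,
    lower = c(0, 0, -30, -30), upper = c(Inf, Inf, 30, 30),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15, gtol = 0)
  )
  par <- fit$par
  objective <- sum(cp_residuals(par, w, zm, zabs)^2)
  obj_start <- sum(cp_residuals(start, w, zm, zabs)^2)
  converged <- fit$info %in% 1:4 && objective <= obj_start + 1e-12
  params <- constant_phase_params(par[1], par[2], exp(par[3]), exp(par[4]))
  quality <- structure(list(
    relative_rms_error = sqrt(objective / length(zm)),
    objective = objective,
    converged = converged,
    n_freq = length(zm)
  ), class = "fit_quality")
  list(params = params, quality = quality)
}

#' Read / write an impedance spectrum as delimited text
#'
#' Columns: `frequency_hz`, `z_real`, `z_imag` (comma-separated).
#'
#' @param path File path.
#' @return [impedance_spectrum()] for `read_spectrum`; `path` invisibly
#'   for `write_spectrum`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) {
    rlr_error(sprintf("spectrum file not found: %s", path), "io")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frequency_hz", "z_real", "z_imag")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    rlr_error(paste0("spectrum file is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "spectrum_schema")
  }
  impedance_spectrum(frequency_grid(df$frequency_hz),
                     complex(real = df$z_real, imaginary = df$z_imag))
}

#' @rdname read_spectrum
#' @param spectrum An [impedance_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(
    data.frame(frequency_hz = spectrum$grid$frequencies_hz,
               z_real = Re(spectrum$z), z_imag = Im(spectrum$z)),
    path, row.names = FALSE)
  invisible(path)
}
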