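# Outcome definitions: the four lung-function outcomes covered by the
# reference equations, their units, and the scale on which the mean
# submodel operates (natural log for Raw/G/H, identity for EELV).

.OUTCOME_NAMES <- c("raw", "g", "h", "eelv")

.OUTCOME_UNITS <- c(
  raw  = "cmH2O.s/l",
  g    = "cmH2O/l",
  h    = "cmH2O/l",
  eelv = "ml"
)

.OUTCOME_TRANSFORM <- c(
  raw  = "log",
  g    = "log",
  h    = "log",
  eelv = "identity"
)

.OUTCOME_LABELS <- c(
  raw  = "airway resistance (Raw)",
  g    = "tissue damping (G)",
  h    = "tissue elastance (H)",
  eelv = "end-expiratory lung volume (EELV)"
)

.STRAINS <- c("sprague_dawley", "wistar")
.SEXES <- c("female", "male")
.PEEP_LEVELS <- c(0, 1, 2, 3, 4, 6)

#' Outcome specification
#'
#' Describes one of the four modelled lung-function outcomes: airway
#' resistance (`"raw"`, cmH2O.s/l), tissue damping (`"g"`, cmH2O/l), tissue
#' elastance (`"h"`, cmH2O/l) or end-expiratory lung volume (`"eelv"`, ml).
#' The mean submodel operates on the natural-log scale for Raw, G and H and
#' on the identity scale for EELV; the standard-deviation submodel always
#' uses a log link.
#'
#' @param name One of `"raw"`, `"g"`, `"h"`, `"eelv"`.
#' @return An object of class `outcome_spec` with fields `name`, `units`,
#'   `mu_transform` and `label`.
#' @examples
#' outcome_spec("raw")
#' @export
outcome_spec <- function(name) {
  name <- match.arg(tolower(as.character(name)), .OUTCOME_NAMES)
  structure(
    list(
      name = name,
      units = unname(.OUTCOME_UNITS[name]),
      mu_transform = unname(.OUTCOME_TRANSFORM[name]),
      label = unname(.OUTCOME_LABELS[name])
    ),
    class = "outcome_spec"
  )
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat(sprintf("Outcome: %s [%s], mu on %s scale\n",
              x$label, x$units, x$mu_transform))
  invisible(x)
}

# Forward transform to the modelling scale.
transform_observed <- function(spec, y) {
  if (spec$mu_transform == "log") {
    if (any(!is.na(y) & y <= 0)) {
      rlr_error(
        sprintf("observed %s must be strictly positive for the log scale",
                spec$name),
        "nonpositive_observed"
      )
    }
    log(y)
  } else {
    y
  }
}

# Back-transform from the modelling scale to original units.
backtransform_mu <- function(spec, mu) {
  if (spec$mu_transform == "log") exp(mu) else mu
}
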