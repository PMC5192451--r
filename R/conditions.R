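#' Physiological conditions for transformed Gibbs energies
#'
#' A set of intracellular conditions — pH, ionic strength, temperature —
#' attached to one compartment. Every transformed Gibbs energy in this
#' package is computed under, and tagged with, such a condition set:
#' a transformed energy is meaningless without its pH/I/T.
#'
#' The extended Debye-Huckel activity model used downstream is stated for
#' ionic strengths between 0.005 and 0.25 M. Conditions outside that window
#' are accepted (there is no alternative model) but the object records a
#' warning state in `ionic_strength_in_range` and a warning is signalled.
#'
#' @param ph pH of the compartment (dimensionless).
#' @param ionic_strength Ionic strength in mol/L; must be non-negative.
#' @param temperature Absolute temperature in K; must be positive.
#' @param compartment Compartment label, e.g. `"c"` for cytosol.
#'
#' @return An object of class `thermo_conditions` with fields `ph`,
#'   `ionic_strength`, `temperature`, `compartment` and
#'   `ionic_strength_in_range`.
#' @examples
#' yeast <- conditions(ph = 7, ionic_strength = 0.15)
#' @export
conditions <- function(ph = 7, ionic_strength = 0.15,
                       temperature = 298.15, compartment = "c") {
  stopifnot(is.numeric(ph), length(ph) == 1L, is.finite(ph))
  stopifnot(is.numeric(ionic_strength), length(ionic_strength) == 1L)
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (ionic_strength < 0) {
    stop("ionic_strength must be >= 0, got ", ionic_strength)
  }
  if (temperature <= 0) {
    stop("temperature must be > 0 K, got ", temperature)
  }
  in_range <- ionic_strength >= 0.005 && ionic_strength <= 0.25
  if (!in_range) {
    warning("ionic strength ", ionic_strength,
            " M is outside the 0.005-0.25 M validity range of the ",
            "extended Debye-Huckel model; computing anyway", call. = FALSE)
  }
  structure(
    list(ph = ph, ionic_strength = ionic_strength,
         temperature = temperature, compartment = as.character(compartment),
         ionic_strength_in_range = in_range),
    class = "thermo_conditions"
  )
}

#' @export
print.thermo_conditions <- function(x, ...) {
  cat(sprintf("conditions [%s]: pH %g, I %g M, T %g K%s\n",
              x$compartment, x$ph, x$ionic_strength, x$temperature,
              if (x$ionic_strength_in_range) "" else " (I out of model range)"))
  invisible(x)
}

same_conditions <- function(a, b, tol = 1e-12) {
  abs(a$ph - b$ph) < tol &&
    abs(a$ionic_strength - b$ionic_strength) < tol &&
    abs(a$temperature - b$temperature) < tol
}

#' Decadic log activity coefficient from the extended Debye-Huckel model
#'
#' Computes `log10` of the activity coefficient of an ion of charge `z`
#' at the ionic strength of `conditions`:
#' `log10(gamma) = -A z^2 sqrt(I) / (1 + B sqrt(I))`
#' with A = 0.510651 and B = 1.6 (L/mol)^(1/2). Uncharged species and
#' zero ionic strength give exactly 0.
#'
#' @param charge Integer charge of the ion.
#' @param conditions A [conditions()] object.
#' @return The dimensionless log10 activity coefficient (vectorised over
#'   `charge`).
#' @examples
#' log_activity_coefficient(1, conditions(ionic_strength = 0.15))
#' @export
log_activity_coefficient <- function(charge, conditions) {
  stopifnot(inherits(conditions, "thermo_conditions"))
  sqI <- sqrt(conditions$ionic_strength)
  -DEBYE_A * charge^2 * sqI / (1 + DEBYE_B * sqI)
}

# RT in kJ/mol at the conditions' temperature
rt_of <- function(conditions) R_GAS * conditions$temperature

# the Eq.-(11) ionic-strength coefficient RT ln(10) A; equals the
# conventional literal 2.91482 at 298.15 K and scales with T elsewhere
ionic_coefficient <- function(temperature) {
  R_GAS * temperature * log(10) * DEBYE_A
}
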