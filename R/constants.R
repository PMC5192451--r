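#' Physical constants
#'
#' Constants used throughout the package, on the kJ/mol scale.
#'
#' * `R_GAS`: ideal gas constant, 8.31451e-3 kJ mol^-1 K^-1 (the value that
#'   makes RT ln(10) A equal the conventional 2.91482 ionic-strength
#'   coefficient at 298.15 K).
#' * `FARADAY`: Faraday constant, 96.485 kJ mol^-1 V^-1.
#' * `DEBYE_A`, `DEBYE_B`: extended Debye-Huckel constants at standard
#'   temperature and pressure, A = 0.510651 L^1/2 mol^-1/2 and
#'   B = 1.6 L^1/2 mol^-1/2.
#' * `T_STANDARD`: 298.15 K.
#'
#' @name constants
#' @keywords internal
NULL

R_GAS <- 8.31451e-3 # kJ / (mol K)
FARADAY <- 96.485 # kJ / (mol V)
DEBYE_A <- 0.510651 # L^1/2 mol^-1/2
DEBYE_B <- 1.6 # L^1/2 mol^-1/2
T_STANDARD <- 298.15 # K

# names under which water / protons are recognised in reaction equations;
# water carries its formation energy in dG'0 sums but unit activity in dG',
# protons never appear as reactants (constant-pH convention)
WATER_NAMES <- c("H2O", "h2o", "H2O(l)", "water", "Water", "WATER")
PROTON_NAMES <- c("H+", "h+", "H(+)", "H^+", "proton", "Proton")

is_water <- function(name) name %in% WATER_NAMES
is_proton <- function(name) name %in% PROTON_NAMES
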