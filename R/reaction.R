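#' Define a reaction over reactants
#'
#' A reaction is a signed stoichiometry over reactant names (negative
#' coefficients for substrates), a directionality flag and an optional
#' transport marker. Reactions are stored proton-free: at constant pH it is
#' not necessary to balance hydrogen ions, and any proton entries are
#' stripped with a warning.
#'
#' @param id Reaction label.
#' @param stoichiometry Named numeric vector mapping reactant names to signed
#'   coefficients; at least one nonzero entry after proton stripping.
#' @param directionality One of `"reversible"`, `"forward_only"`,
#'   `"backward_only"`.
#' @param is_transport Logical; `TRUE` for transmembrane transport reactions.
#' @return An object of class `thermo_reaction`.
#' @examples
#' reaction("HEX1", c(Glucose = -1, ATP = -1, `Glucose 6-phosphate` = 1, ADP = 1))
#' @export
reaction <- function(id, stoichiometry,
                     directionality = c("reversible", "forward_only", "backward_only"),
                     is_transport = FALSE) {
  directionality <- match.arg(directionality)
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  if (any(!nzchar(names(stoichiometry)))) stop("unnamed stoichiometry entry in '", id, "'")
  h <- is_proton(names(stoichiometry))
  if (any(h)) {
    warning("reaction '", id, "': proton entries (",
            paste(names(stoichiometry)[h], collapse = ", "),
            ") stripped; pH is held constant", call. = FALSE)
    stoichiometry <- stoichiometry[!h]
  }
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (length(stoichiometry) == 0L) {
    stop("reaction '", id, "' has no nonzero stoichiometric coefficients")
  }
  if (anyDuplicated(names(stoichiometry))) {
    s <- tapply(stoichiometry, names(stoichiometry), sum)
    stoichiometry <- stats::setNames(as.numeric(s), names(s))
    stoichiometry <- stoichiometry[stoichiometry != 0]
    if (length(stoichiometry) == 0L) {
      stop("reaction '", id, "' cancels to an empty stoichiometry")
    }
  }
  structure(
    list(id = id, stoichiometry = stoichiometry,
         directionality = directionality, is_transport = isTRUE(is_transport)),
    class = "thermo_reaction"
  )
}

#' @export
print.thermo_reaction <- function(x, ...) {
  cat(sprintf("%s: %s [%s]%s\n", x$id, format_reaction_equation(x),
              x$directionality, if (x$is_transport) " (transport)" else ""))
  invisible(x)
}

#' Standard transformed Gibbs energy of a reaction
#'
#' Computes the stoichiometric sum
#' \deqn{\Delta_r G'^0 = \sum_i S_{ij} \Delta_f G_i'^0}
#' over reactant-level transformed formation energies. Water, where present
#' in the stoichiometry, contributes its formation energy here (the atoms of
#' water are accounted for in the standard term) even though its activity is
#' fixed at 1 in [reaction_dg()].
#'
#' @param reaction A [reaction()] object.
#' @param energies Named numeric vector of reactant-level transformed
#'   formation energies in kJ/mol, or a named list of `transformed_energy`
#'   objects (e.g. from [reactant_energy()]); names must cover the
#'   stoichiometry.
#' @return Standard transformed reaction Gibbs energy in kJ/mol.
#' @examples
#' energies <- reactant_energies(glycolysis_species(), conditions())
#' vals <- stats::setNames(energies$dfg0_prime_kj_mol, energies$reactant)
#' rxn <- glycolysis_model()[["HEX1"]]
#' reaction_standard_dg(rxn, vals)
#' @export
reaction_standard_dg <- function(reaction, energies) {
  stopifnot(inherits(reaction, "thermo_reaction"))
  energies <- energy_values(energies)
  s <- reaction$stoichiometry
  missing <- setdiff(names(s), names(energies))
  if (length(missing)) {
    stop("no transformed energy for reactant(s): ",
         paste(missing, collapse = ", "), " (reaction '", reaction$id, "')")
  }
  sum(s * energies[names(s)])
}

# accept a named numeric vector, a named list of transformed_energy objects,
# or the data frame produced by reactant_energies()
energy_values <- function(energies) {
  if (is.data.frame(energies)) {
    return(stats::setNames(energies$dfg0_prime_kj_mol, energies$reactant))
  }
  if (is.list(energies)) {
    return(vapply(energies, function(e) {
      if (inherits(e, "transformed_energy")) e$value else as.numeric(e)
    }, numeric(1)))
  }
  stopifnot(is.numeric(energies), !is.null(names(energies)))
  energies
}

#' Actual Gibbs energy of a reaction at given concentrations
#'
#' Evaluates
#' \deqn{\Delta_r G' = \Delta_r G'^0 + RT \sum_i S_{ij} \ln c_i}
#' over the concentration-bearing reactants of a reaction. Water's activity
#' is fixed at 1 (it is excluded from the log term), and protons never
#' appear (constant pH). Net flux proceeds in the direction where the
#' result is negative.
#'
#' @param reaction A [reaction()] object.
#' @param dg0 The standard transformed reaction energy in kJ/mol (from
#'   [reaction_standard_dg()]).
#' @param concentrations Named numeric vector of concentrations in mol/L for
#'   every non-water reactant of the reaction; all must be positive.
#' @param conditions A [conditions()] object (provides the temperature).
#' @return Reaction Gibbs energy in kJ/mol.
#' @export
reaction_dg <- function(reaction, dg0, concentrations, conditions) {
  stopifnot(inherits(reaction, "thermo_reaction"),
            inherits(conditions, "thermo_conditions"),
            is.numeric(dg0), length(dg0) == 1L)
  s <- reaction$stoichiometry
  s <- s[!is_water(names(s))]
  if (length(s) == 0L) return(dg0)
  missing <- setdiff(names(s), names(concentrations))
  if (length(missing)) {
    stop("missing concentration for reactant(s): ",
         paste(missing, collapse = ", "))
  }
  ci <- concentrations[names(s)]
  if (any(ci <= 0)) {
    stop("nonpositive concentration for reactant(s): ",
         paste(names(ci)[ci <= 0], collapse = ", "))
  }
  dg0 + rt_of(conditions) * sum(s * log(ci))
}
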