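#' Define a chemical species (single protonation state)
#'
#' A species is one protonation state of a biochemical reactant, described
#' by its standard Gibbs energy of formation, its charge and its hydrogen
#' atom count. ATP, for instance, is represented near pH 7 by the species
#' ATP4-, HATP3- and H2ATP2-.
#'
#' @param name Species label (non-empty).
#' @param dfg0 Standard Gibbs energy of formation in kJ/mol. May be stated
#'   relative to a reference convention (e.g. NAD set to zero for a redox
#'   pair); use `reference_group` to tag the convention so mixed conventions
#'   can be detected.
#' @param charge Integer charge z.
#' @param n_hydrogen Non-negative integer count of hydrogen atoms N_H.
#' @param reference_group Optional label of the reference convention the
#'   `dfg0` value belongs to (`NA` for absolute values).
#' @return An object of class `thermo_species`.
#' @examples
#' glc <- species("Glucose", -915.9, charge = 0, n_hydrogen = 12)
#' @export
species <- function(name, dfg0, charge, n_hydrogen, reference_group = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(dfg0), length(dfg0) == 1L, is.finite(dfg0))
  stopifnot(length(charge) == 1L, charge == round(charge))
  stopifnot(length(n_hydrogen) == 1L, n_hydrogen == round(n_hydrogen))
  if (n_hydrogen < 0) stop("n_hydrogen must be >= 0 for species '", name, "'")
  structure(
    list(name = name, dfg0 = as.numeric(dfg0), charge = as.integer(charge),
         n_hydrogen = as.integer(n_hydrogen),
         reference_group = as.character(reference_group)),
    class = "thermo_species"
  )
}

#' @export
print.thermo_species <- function(x, ...) {
  cat(sprintf("species %s: dfG0 %.2f kJ/mol, z %+d, N_H %d\n",
              x$name, x$dfg0, x$charge, x$n_hydrogen))
  invisible(x)
}

#' Define a reactant as a pseudoisomer group of species
#'
#' Biochemical reactions are written in terms of reactants (e.g. ATP) that
#' are pools of protonation-state species assumed to be at internal
#' equilibrium. A reactant therefore holds one or more [species()] objects.
#'
#' @param name Reactant label.
#' @param species A single [species()] or a list of them; species names must
#'   be unique within the group.
#' @param compartment Compartment label.
#' @return An object of class `thermo_reactant`.
#' @examples
#' pi <- reactant("Pi", list(
#'   species("HPO4-2", -1096.1, -2, 1),
#'   species("H2PO4-", -1137.3, -1, 2)
#' ))
#' @export
reactant <- function(name, species, compartment = "c") {
  if (inherits(species, "thermo_species")) species <- list(species)
  stopifnot(is.list(species), length(species) >= 1L)
  ok <- vapply(species, inherits, logical(1), "thermo_species")
  if (!all(ok)) stop("all elements of 'species' must be thermo_species objects")
  nm <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate species names in reactant '", name, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  structure(
    list(name = name, species = species, compartment = as.character(compartment)),
    class = "thermo_reactant"
  )
}

#' @export
print.thermo_reactant <- function(x, ...) {
  cat(sprintf("reactant %s [%s]: %d species (%s)\n", x$name, x$compartment,
              length(x$species),
              paste(vapply(x$species, `[[`, character(1), "name"), collapse = ", ")))
  invisible(x)
}

new_transformed_energy <- function(value, conditions, level) {
  structure(list(value = value, conditions = conditions, level = level),
            class = "transformed_energy")
}

#' @export
print.transformed_energy <- function(x, ...) {
  cat(sprintf("dfG'0 = %.4f kJ/mol (%s level; pH %g, I %g M, T %g K)\n",
              x$value, x$level, x$conditions$ph, x$conditions$ionic_strength,
              x$conditions$temperature))
  invisible(x)
}

#' Standard transformed Gibbs energy of formation of a species
#'
#' Applies the Legendre transform that moves a species' standard Gibbs
#' energy of formation to specified pH and ionic strength:
#'
#' \deqn{\Delta_f G'^0 = \Delta_f G^0 - N_H RT \ln(10^{-pH})
#'   - RT \ln(10) A (z^2 - N_H) \frac{\sqrt I}{1 + 1.6 \sqrt I}}
#'
#' The ionic-strength coefficient `RT ln(10) A` equals the conventional
#' literal 2.91482 at 298.15 K and is recomputed from the temperature in
#' `conditions` so other temperatures are supported.
#'
#' @param species A [species()] object.
#' @param conditions A [conditions()] object.
#' @return A `transformed_energy` (species level) recording the value in
#'   kJ/mol together with the conditions it was computed under.
#' @examples
#' transform_species(species("Glucose", -915.9, 0, 12), conditions())
#' @export
transform_species <- function(species, conditions) {
  stopifnot(inherits(species, "thermo_species"),
            inherits(conditions, "thermo_conditions"))
  rt <- rt_of(conditions)
  sqI <- sqrt(conditions$ionic_strength)
  value <- species$dfg0 -
    species$n_hydrogen * rt * log(10^(-conditions$ph)) -
    ionic_coefficient(conditions$temperature) *
      (species$charge^2 - species$n_hydrogen) * sqI / (1 + DEBYE_B * sqI)
  new_transformed_energy(value, conditions, "species")
}

#' Merge species-level transformed energies into a reactant-level value
#'
#' Combines the transformed formation energies of the protonation states of
#' one reactant into the pseudoisomer-group value
#' \deqn{\Delta_f G_j'^0 = -RT \ln \sum_i \exp(-\Delta_f G_i'^0 / RT)}
#' evaluated with a log-sum-exp shift for numerical stability. The result is
#' always at or below the lowest input energy (the pool is more stable than
#' any single state), and approaches it as one state dominates.
#'
#' @param energies A list of species-level `transformed_energy` objects (or a
#'   single one), all computed under the same conditions.
#' @param conditions Optional [conditions()]; defaults to the conditions of
#'   the inputs, and is checked against them.
#' @return A `transformed_energy` (reactant level).
#' @examples
#' cond <- conditions()
#' e <- lapply(list(
#'   species("HPO4-2", -1096.1, -2, 1),
#'   species("H2PO4-", -1137.3, -1, 2)
#' ), transform_species, conditions = cond)
#' merge_pseudoisomers(e)
#' @export
merge_pseudoisomers <- function(energies, conditions = NULL) {
  if (inherits(energies, "transformed_energy")) energies <- list(energies)
  stopifnot(is.list(energies), length(energies) >= 1L)
  ok <- vapply(energies, inherits, logical(1), "transformed_energy")
  if (!all(ok)) stop("'energies' must be transformed_energy objects")
  if (is.null(conditions)) conditions <- energies[[1L]]$conditions
  for (e in energies) {
    if (!same_conditions(e$conditions, conditions)) {
      stop("cannot merge pseudoisomers computed under different conditions; ",
           "transformed energies are condition-specific")
    }
  }
  g <- vapply(energies, `[[`, numeric(1), "value")
  rt <- rt_of(conditions)
  m <- min(g)
  value <- m - rt * log(sum(exp(-(g - m) / rt)))
  new_transformed_energy(value, conditions, "reactant")
}

#' Reactant-level transformed formation energy
#'
#' Transforms every species of a reactant to the given conditions and merges
#' them as a pseudoisomer group. For a single-species reactant this equals
#' [transform_species()].
#'
#' @param reactant A [reactant()] object.
#' @param conditions A [conditions()] object.
#' @return A `transformed_energy` (reactant level), kJ/mol.
#' @export
reactant_energy <- function(reactant, conditions) {
  stopifnot(inherits(reactant, "thermo_reactant"))
  merge_pseudoisomers(
    lapply(reactant$species, transform_species, conditions = conditions),
    conditions
  )
}

#' Transformed formation energies for a collection of reactants
#'
#' Convenience wrapper computing [reactant_energy()] for every reactant in a
#' list (as produced by [read_species_table()]).
#'
#' @param reactants A named list of [reactant()] objects.
#' @param conditions A [conditions()] object.
#' @return A data frame with columns `reactant`, `n_species` and
#'   `dfg0_prime_kj_mol`.
#' @examples
#' reactant_energies(glycolysis_species(), conditions())
#' @export
reactant_energies <- function(reactants, conditions) {
  stopifnot(is.list(reactants))
  vals <- vapply(reactants, function(r) reactant_energy(r, conditions)$value,
                 numeric(1))
  data.frame(
    reactant = vapply(reactants, `[[`, character(1), "name"),
    n_species = vapply(reactants, function(r) length(r$species), integer(1)),
    dfg0_prime_kj_mol = unname(vals),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
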