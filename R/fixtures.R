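#' Bundled yeast glycolysis reference dataset
#'
#' Accessors for the bundled reference dataset: species data (formation
#' energies, charges and hydrogen counts for the 17 glycolytic reactants and
#' their 32 protonation-state species), the ten glycolysis reactions, and
#' the yeast cytosolic conditions (pH 7, ionic strength 0.15 M, 298.15 K)
#' under which the published transformed energies were tabulated.
#'
#' @return `glycolysis_species()` returns a named list of [reactant()]
#'   objects; `glycolysis_model()` a named list of [reaction()] objects;
#'   `glycolysis_conditions()` a [conditions()] object.
#' @examples
#' energies <- reactant_energies(glycolysis_species(), glycolysis_conditions())
#' head(energies)
#' @export
glycolysis_species <- function() {
  read_species_table(system.file("extdata", "glycolysis_species.tsv",
                                 package = "thermonet", mustWork = TRUE))
}

#' @rdname glycolysis_species
#' @export
glycolysis_model <- function() {
  read_model(system.file("extdata", "glycolysis_reactions.tsv",
                         package = "thermonet", mustWork = TRUE))
}

#' @rdname glycolysis_species
#' @export
glycolysis_conditions <- function() {
  read_conditions(system.file("extdata", "conditions_yeast.json",
                              package = "thermonet", mustWork = TRUE))[["c"]]
}

#' Standard transformed Gibbs energies for the glycolysis model
#'
#' Convenience pipeline over the bundled dataset: computes reactant-level
#' transformed formation energies and the standard transformed Gibbs energy
#' of every glycolysis reaction.
#'
#' @param conditions A [conditions()] object; defaults to the bundled yeast
#'   cytosol conditions.
#' @return A data frame with columns `id`, `equation` and `dg0_kj_mol`.
#' @examples
#' glycolysis_dg0()
#' @export
glycolysis_dg0 <- function(conditions = glycolysis_conditions()) {
  energies <- reactant_energies(glycolysis_species(), conditions)
  model <- glycolysis_model()
  data.frame(
    id = names(model),
    equation = vapply(model, format_reaction_equation, character(1)),
    dg0_kj_mol = vapply(model, reaction_standard_dg, numeric(1),
                        energies = energies),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
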