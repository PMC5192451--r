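#' Lump antiparallel reaction pairs into single reversible reactions
#'
#' Thermodynamic network analysis requires that a conversion catalysed by
#' different enzymes in opposite directions appear as one reversible
#' reaction: keeping both copies forces each to carry a negative Gibbs
#' energy, which is only satisfiable at equilibrium. This curation pass
#' finds reaction pairs whose stoichiometries are exact negatives of each
#' other and merges each pair into one reversible reaction (the first id of
#' the pair is kept).
#'
#' @param model Named list of [reaction()] objects.
#' @return A list with `model` (the curated list) and `report` (a data
#'   frame with columns `kept` and `dropped`, one row per merged pair).
#' @examples
#' m <- list(f = reaction("f", c(A = -1, B = 1), "forward_only"),
#'           b = reaction("b", c(B = -1, A = 1), "forward_only"))
#' lump_antiparallel_reactions(m)$report
#' @export
lump_antiparallel_reactions <- function(model) {
  stopifnot(is.list(model))
  key <- function(s, flip = FALSE) {
    s <- s[order(names(s))]
    if (flip) s <- -s
    paste(names(s), format(s, digits = 12), collapse = ";")
  }
  keys <- vapply(model, function(r) key(r$stoichiometry), character(1))
  anti <- vapply(model, function(r) key(r$stoichiometry, flip = TRUE), character(1))
  kept <- character(0); dropped <- character(0)
  drop_idx <- logical(length(model))
  for (i in seq_along(model)) {
    if (drop_idx[i]) next
    j <- which(keys == anti[i] & !drop_idx & seq_along(model) > i)
    if (length(j)) {
      j <- j[1L]
      drop_idx[j] <- TRUE
      model[[i]]$directionality <- "reversible"
      kept <- c(kept, names(model)[i]); dropped <- c(dropped, names(model)[j])
    }
  }
  list(model = model[!drop_idx],
       report = data.frame(kept = kept, dropped = dropped,
                           stringsAsFactors = FALSE))
}

#' Group dissolved carbon dioxide species into a single reactant
#'
#' Aqueous carbon dioxide is distributed over CO2, H2CO3, HCO3- and CO3--;
#' for thermodynamic analysis these tagged species are pooled into one
#' reactant (conventionally `CO2tot`). Replacing a species by the pooled
#' reactant can unbalance oxygen, so water is added to the reaction to
#' compensate; the entry of `species_map` for each tagged species gives the
#' number of waters added on the same side per unit of that species
#' (negative values add to the opposite side). The defaults assume the
#' pooled reactant is referenced to dissolved CO2, so the hydrated species
#' each return one water.
#'
#' The pass touches only reactions containing a tagged species; everything
#' else is passed through unchanged.
#'
#' @param model Named list of [reaction()] objects.
#' @param species_map Named numeric: tagged species name -> waters added on
#'   the same side per unit replaced.
#' @param to Name of the pooled reactant (default `"CO2tot"`).
#' @param water Name of the water reactant in the model (default `"H2O"`).
#' @return A list with `model` (curated) and `report` (data frame with
#'   columns `reaction` and `replaced`).
#' @export
group_co2_reactant <- function(model,
                               species_map = c(CO2 = 0, H2CO3 = 1,
                                               "HCO3-" = 1, "CO3--" = 1),
                               to = "CO2tot", water = "H2O") {
  stopifnot(is.list(model), is.numeric(species_map), !is.null(names(species_map)))
  touched <- character(0); replaced <- character(0)
  out <- lapply(model, function(rx) {
    s <- rx$stoichiometry
    hits <- intersect(names(s), names(species_map))
    if (!length(hits)) return(rx)
    for (sp in hits) {
      coef <- s[[sp]]
      s <- s[names(s) != sp]
      s[to] <- if (to %in% names(s)) s[[to]] + coef else coef
      w <- coef * species_map[[sp]]
      if (w != 0) {
        s[water] <- if (water %in% names(s)) s[[water]] + w else w
      }
    }
    s <- s[s != 0]
    touched <<- c(touched, rx$id)
    replaced <<- c(replaced, paste(hits, collapse = ","))
    reaction(rx$id, s, directionality = rx$directionality,
             is_transport = rx$is_transport)
  })
  names(out) <- names(model)
  list(model = out,
       report = data.frame(reaction = touched, replaced = replaced,
                           stringsAsFactors = FALSE))
}
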