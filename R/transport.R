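#' Specify a transmembrane transport event
#'
#' Describes the transport portion of a reaction that moves species between
#' two compartments: the net charge translocated, the membrane potential
#' difference, and the transported species with their stoichiometric
#' coefficients and compartments.
#'
#' Sign convention (documented because conventions differ between tools):
#' coefficients and the membrane potential are oriented
#' destination-minus-origin. A species leaving the origin compartment enters
#' with coefficient -1 there and +1 in the destination; `delta_psi` is the
#' potential of the destination minus the origin, so a positive charge
#' moving down the potential gradient yields a negative potential term for
#' the forward direction.
#'
#' @param net_charge_translocated Integer net charge `n` moved across the
#'   membrane (destination-positive).
#' @param delta_psi Membrane potential difference in V (destination minus
#'   origin).
#' @param transported A list of entries, each a list with elements
#'   `species` (a [species()]), `s` (signed stoichiometric coefficient) and
#'   `compartment` (the compartment whose conditions apply to the entry).
#'   May be empty when only charge is moved.
#' @return An object of class `transport_spec`.
#' @examples
#' cargo <- list(
#'   list(species = species("X", -100, 0, 1), s = -1, compartment = "out"),
#'   list(species = species("X", -100, 0, 1), s = 1, compartment = "in")
#' )
#' transport_spec(0, 0, cargo)
#' @export
transport_spec <- function(net_charge_translocated, delta_psi, transported = list()) {
  stopifnot(length(net_charge_translocated) == 1L,
            net_charge_translocated == round(net_charge_translocated),
            is.numeric(delta_psi), length(delta_psi) == 1L)
  stopifnot(is.list(transported))
  for (entry in transported) {
    if (!inherits(entry$species, "thermo_species") ||
        !is.numeric(entry$s) || is.null(entry$compartment)) {
      stop("each transported entry needs fields species (thermo_species), ",
           "s (coefficient) and compartment")
    }
  }
  if (length(transported) == 0L && net_charge_translocated == 0) {
    stop("transport spec must move at least one species or a net charge")
  }
  structure(
    list(net_charge_translocated = as.integer(net_charge_translocated),
         delta_psi = delta_psi, transported = transported),
    class = "transport_spec"
  )
}

#' Membrane-potential term of a transport Gibbs energy
#'
#' The electrical work of moving a net charge `n` across a membrane
#' potential difference: `n F delta_psi` with the Faraday constant
#' F = 96.485 kJ mol^-1 V^-1.
#'
#' @param n Net charge translocated (destination-positive).
#' @param delta_psi Membrane potential difference in V (destination minus
#'   origin).
#' @return Energy in kJ/mol.
#' @examples
#' membrane_potential_term(1, 0.15) # 14.47 kJ/mol
#' @export
membrane_potential_term <- function(n, delta_psi) {
  stopifnot(is.numeric(n), is.numeric(delta_psi))
  n * FARADAY * delta_psi
}

#' pH-gradient term of a transport Gibbs energy
#'
#' Implements the proton-gradient correction for transported species,
#' \deqn{\Delta_{\Delta pH} G = \sum_i s_i \Delta_f G_i'^0
#'   - 2.3 RT \sum_i s_i N_H(i) \, pH_i}
#' where each transported species contributes its transformed formation
#' energy evaluated under the conditions of its own compartment, and the
#' second sum corrects for the compartment-specific proton reference. The
#' printed coefficient 2.3 (an approximation of ln 10) is used as stated.
#' The term vanishes when both compartments share identical conditions and
#' the transported species sets cancel.
#'
#' @param spec A [transport_spec()].
#' @param compartment_conditions Named list of [conditions()] keyed by
#'   compartment id; must cover every compartment referenced by the spec,
#'   and all compartments must share one temperature.
#' @return Energy in kJ/mol.
#' @export
delta_ph_term <- function(spec, compartment_conditions) {
  stopifnot(inherits(spec, "transport_spec"), is.list(compartment_conditions))
  if (length(spec$transported) == 0L) return(0)
  comps <- unique(vapply(spec$transported, `[[`, character(1), "compartment"))
  missing <- setdiff(comps, names(compartment_conditions))
  if (length(missing)) {
    stop("no conditions supplied for compartment(s): ",
         paste(missing, collapse = ", "))
  }
  temps <- vapply(compartment_conditions[comps], `[[`, numeric(1), "temperature")
  if (diff(range(temps)) > 1e-9) {
    stop("compartments must share one temperature for the pH-gradient term")
  }
  rt <- R_GAS * temps[[1L]]
  energy_sum <- 0
  ph_sum <- 0
  for (entry in spec$transported) {
    cond <- compartment_conditions[[entry$compartment]]
    energy_sum <- energy_sum +
      entry$s * transform_species(entry$species, cond)$value
    ph_sum <- ph_sum + entry$s * entry$species$n_hydrogen * cond$ph
  }
  energy_sum - 2.3 * rt * ph_sum
}

#' Standard transformed Gibbs energy of a transport reaction
#'
#' Combines the chemical (single-compartment) part of a transport reaction
#' with the transmembrane part:
#' total = chemical + membrane-potential term + pH-gradient term.
#'
#' @param compartment_dg0 Standard transformed Gibbs energy of the chemical
#'   part in kJ/mol (from [reaction_standard_dg()]).
#' @param spec A [transport_spec()].
#' @param compartment_conditions Named list of [conditions()] keyed by
#'   compartment, as for [delta_ph_term()].
#' @return A list with components `total`, `chemical`, `potential` and `ph`
#'   (all kJ/mol); `total` is their exact sum.
#' @export
transport_reaction_dg0 <- function(compartment_dg0, spec, compartment_conditions) {
  stopifnot(is.numeric(compartment_dg0), length(compartment_dg0) == 1L)
  potential <- membrane_potential_term(spec$net_charge_translocated, spec$delta_psi)
  ph <- delta_ph_term(spec, compartment_conditions)
  list(total = compartment_dg0 + potential + ph,
       chemical = compartment_dg0, potential = potential, ph = ph)
}

#' Reverse the orientation of a transport spec
#'
#' Writes the transport event backwards: the net translocated charge and
#' every transported coefficient change sign, while the membrane potential
#' difference is untouched — it is a property of the membrane, not of the
#' direction the reaction is written in. The transport term of the reversed
#' spec is exactly the negative of the original.
#'
#' @param spec A [transport_spec()].
#' @return A [transport_spec()].
#' @export
reverse_transport_spec <- function(spec) {
  stopifnot(inherits(spec, "transport_spec"))
  transported <- lapply(spec$transported, function(entry) {
    entry$s <- -entry$s
    entry
  })
  transport_spec(-spec$net_charge_translocated, spec$delta_psi, transported)
}
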