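#' Generate a seeded toy network with a known feasibility status
#'
#' Builds small random metabolic networks whose thermodynamic feasibility
#' is guaranteed by construction, for testing and benchmarking the NET
#' machinery.
#'
#' Feasible targets are built by first sampling concentration bounds and a
#' concentration point inside them, then choosing standard reaction
#' energies so that every direction-constrained reaction has a comfortably
#' negative (forward) or positive (backward) Gibbs energy at that point:
#' the planted point is then a feasibility witness. Infeasible targets
#' start from a feasible construction and overwrite one direction-
#' constrained reaction's standard energy so that its constraint is violated
#' everywhere in the concentration box (the box optimum of the affine Gibbs
#' energy is pushed past the allowed sign with a positive margin).
#'
#' Generation is deterministic for a given `seed` and leaves the global
#' random number generator untouched.
#'
#' @param n_metabolites Number of metabolites (>= 2).
#' @param n_reactions Number of reactions (>= 1).
#' @param seed Integer seed.
#' @param target_status `"feasible"` or `"infeasible"`.
#' @param dg0_range Range from which unconstrained (reversible) reactions
#'   draw their standard Gibbs energies, kJ/mol.
#' @param bounds_range Concentration window (mol/L) within which the
#'   per-metabolite bounds are sampled.
#' @param margin_range Range of the feasibility (or infeasibility) margin
#'   in kJ/mol; larger margins give better-separated instances.
#' @param conditions A [conditions()] object.
#' @return A list of class `toy_network` with elements `reactions`, `dg0`,
#'   `bounds`, `conditions`, `target_status`, `witness` (the planted
#'   log-concentration point for feasible targets) and `seed`.
#' @examples
#' toy <- generate_toy_network(3, 3, seed = 1)
#' check_feasibility(net_problem(toy$reactions, toy$dg0, toy$conditions,
#'                               bounds = toy$bounds))$status
#' @export
generate_toy_network <- function(n_metabolites, n_reactions, seed,
                                 target_status = c("feasible", "infeasible"),
                                 dg0_range = c(-30, 30),
                                 bounds_range = c(1e-6, 5e-2),
                                 margin_range = c(2, 15),
                                 conditions = thermonet::conditions()) {
  target_status <- match.arg(target_status)
  stopifnot(n_metabolites >= 2, n_reactions >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  rt <- rt_of(conditions)
  mets <- paste0("M", seq_len(n_metabolites))

  # per-metabolite bounds: a log-uniform window inside bounds_range
  lo_all <- log(bounds_range[1L]); hi_all <- log(bounds_range[2L])
  a <- stats::runif(n_metabolites, lo_all, hi_all)
  b <- stats::runif(n_metabolites, lo_all, hi_all)
  lb <- pmin(a, b); ub <- pmax(a, b)
  bounds <- data.frame(reactant = mets, c_min = exp(lb), c_max = exp(ub),
                       stringsAsFactors = FALSE)
  witness <- stats::runif(n_metabolites, lb, ub)
  names(witness) <- mets

  dirs <- sample(c("forward_only", "backward_only", "reversible"),
                 n_reactions, replace = TRUE)
  if (target_status == "infeasible" && !any(dirs != "reversible")) {
    dirs[sample.int(n_reactions, 1L)] <- "forward_only"
  }

  reactions <- vector("list", n_reactions)
  dg0 <- numeric(n_reactions)
  pick_one <- function(x) x[sample.int(length(x), 1L)] # safe for length-1 x
  for (j in seq_len(n_reactions)) {
    k <- pick_one(2:min(3L, n_metabolites))
    picks <- sample(mets, k)
    coefs <- sample(c(-1, 1, 2, -2), k, replace = TRUE,
                    prob = c(0.4, 0.4, 0.1, 0.1))
    # ensure both a substrate and a product
    if (all(coefs > 0)) coefs[1L] <- -coefs[1L]
    if (all(coefs < 0)) coefs[1L] <- -coefs[1L]
    s <- stats::setNames(coefs, picks)
    id <- paste0("R", j)
    reactions[[j]] <- reaction(id, s, directionality = dirs[j])
    drive <- rt * sum(s * witness[picks])
    margin <- stats::runif(1L, margin_range[1L], margin_range[2L])
    dg0[j] <- switch(dirs[j],
      forward_only = -margin - drive,   # dG' at witness = -margin
      backward_only = margin - drive,   # dG' at witness = +margin
      reversible = stats::runif(1L, dg0_range[1L], dg0_range[2L])
    )
  }
  names(reactions) <- names(dg0) <- paste0("R", seq_len(n_reactions))

  if (target_status == "infeasible") {
    j <- pick_one(which(dirs != "reversible"))
    s <- reactions[[j]]$stoichiometry
    margin <- stats::runif(1L, margin_range[1L], margin_range[2L])
    x_lo <- lb[match(names(s), mets)]; x_hi <- ub[match(names(s), mets)]
    if (dirs[j] == "forward_only") {
      # make even the most favourable corner positive
      best <- rt * sum(ifelse(s > 0, s * x_lo, s * x_hi))
      dg0[j] <- -best + margin
    } else {
      best <- rt * sum(ifelse(s > 0, s * x_hi, s * x_lo))
      dg0[j] <- -best - margin
    }
    witness <- NULL
  }

  structure(
    list(reactions = reactions, dg0 = dg0, bounds = bounds,
         conditions = conditions, target_status = target_status,
         witness = witness, seed = seed),
    class = "toy_network"
  )
}

#' @export
print.toy_network <- function(x, ...) {
  cat(sprintf("toy network (seed %d): %d metabolites, %d reactions, target %s\n",
              x$seed, nrow(x$bounds), length(x$reactions), x$target_status))
  invisible(x)
}

#' Build the NET problem of a toy network
#'
#' @param toy A `toy_network` from [generate_toy_network()].
#' @param ... Passed to [net_problem()].
#' @return A [net_problem()].
#' @export
toy_net_problem <- function(toy, ...) {
  stopifnot(inherits(toy, "toy_network"))
  net_problem(toy$reactions, toy$dg0, toy$conditions, bounds = toy$bounds, ...)
}
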