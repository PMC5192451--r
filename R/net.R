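#' Build a network-embedded thermodynamics (NET) problem
#'
#' Assembles the linear program behind NET analysis. The change of variables
#' `x_i = ln(c_i)` makes every reaction Gibbs energy an affine function
#' \deqn{\Delta_r G_j' = \Delta_r G_j'^0 + RT \sum_i S_{ij} x_i}
#' of the log-concentrations, so feasibility and extremal questions over
#' bounded metabolite concentrations become linear programs:
#' concentration bounds become box bounds `ln(c_min) <= x <= ln(c_max)`,
#' fixed reaction directions become half-space constraints
#' (`Delta_r G' <= -epsilon` forward, `>= +epsilon` backward; strict
#' inequalities are not expressible in an LP, so a small margin `epsilon`
#' stands in for strictness), and cofactor-ratio bounds become bounds on
#' `x_a - x_b`.
#'
#' Water and protons never carry concentration variables (water activity is
#' 1; pH is held constant); water's formation energy is already inside the
#' supplied standard reaction energies.
#'
#' @param reactions Named list of [reaction()] objects (or a single one).
#' @param dg0 Named numeric vector of standard transformed reaction Gibbs
#'   energies in kJ/mol covering every reaction id.
#' @param conditions A [conditions()] object (provides RT).
#' @param bounds Optional data frame with columns `reactant`, `c_min`,
#'   `c_max` (mol/L) for measured metabolites (see [read_bounds()]).
#'   Reactants without a row receive `default_bounds` and are tagged
#'   `"default"`.
#' @param default_bounds Length-2 numeric, the physiological concentration
#'   range assumed for unmeasured metabolites; defaults to 1e-6 to 5e-2 M.
#' @param epsilon Strictness margin in kJ/mol for directionality
#'   constraints (default 1e-6).
#' @param ratio_bounds Optional data frame with columns `a`, `b`, `lower`,
#'   `upper` constraining concentration ratios `c_a / c_b` (e.g. redox
#'   cofactor pairs).
#' @param dg0_error Optional named numeric of symmetric per-reaction
#'   uncertainties in kJ/mol; a reaction with error `e` may realise any
#'   standard energy in `dg0 +/- e`. Off (zero) by default.
#' @return An object of class `net_problem`.
#' @examples
#' cond <- glycolysis_conditions()
#' dg0 <- glycolysis_dg0(cond)
#' prob <- net_problem(glycolysis_model(), stats::setNames(dg0$dg0_kj_mol, dg0$id), cond)
#' @export
net_problem <- function(reactions, dg0, conditions, bounds = NULL,
                        default_bounds = c(1e-6, 5e-2), epsilon = 1e-6,
                        ratio_bounds = NULL, dg0_error = NULL) {
  if (inherits(reactions, "thermo_reaction")) {
    reactions <- stats::setNames(list(reactions), reactions$id)
  }
  stopifnot(is.list(reactions), length(reactions) >= 1L)
  ok <- vapply(reactions, inherits, logical(1), "thermo_reaction")
  if (!all(ok)) stop("'reactions' must be thermo_reaction objects")
  ids <- vapply(reactions, `[[`, character(1), "id")
  names(reactions) <- ids
  stopifnot(is.numeric(dg0), !is.null(names(dg0)))
  missing <- setdiff(ids, names(dg0))
  if (length(missing)) {
    stop("no standard Gibbs energy supplied for reaction(s): ",
         paste(missing, collapse = ", "))
  }
  stopifnot(inherits(conditions, "thermo_conditions"))
  stopifnot(is.numeric(default_bounds), length(default_bounds) == 2L,
            default_bounds[1L] > 0, default_bounds[1L] <= default_bounds[2L])
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0)

  all_names <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  variables <- all_names[!is_water(all_names) & !is_proton(all_names)]

  nvar <- length(variables)
  bt <- data.frame(reactant = variables,
                   c_min = rep(default_bounds[1L], nvar),
                   c_max = rep(default_bounds[2L], nvar),
                   provenance = rep("default", nvar), stringsAsFactors = FALSE)
  if (!is.null(bounds)) {
    stopifnot(all(c("reactant", "c_min", "c_max") %in% names(bounds)))
    if (any(bounds$c_min <= 0 | bounds$c_min > bounds$c_max)) {
      stop("measured bounds must satisfy 0 < c_min <= c_max")
    }
    hit <- match(bt$reactant, bounds$reactant)
    take <- !is.na(hit)
    bt$c_min[take] <- bounds$c_min[hit[take]]
    bt$c_max[take] <- bounds$c_max[hit[take]]
    bt$provenance[take] <- "measured"
  }

  err <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(dg0_error)) {
    stopifnot(is.numeric(dg0_error), !is.null(names(dg0_error)), all(dg0_error >= 0))
    err[intersect(names(dg0_error), ids)] <-
      dg0_error[intersect(names(dg0_error), ids)]
  }

  if (!is.null(ratio_bounds)) {
    stopifnot(all(c("a", "b", "lower", "upper") %in% names(ratio_bounds)))
    unknown <- setdiff(c(ratio_bounds$a, ratio_bounds$b), variables)
    if (length(unknown)) {
      stop("ratio bound on unknown reactant(s): ", paste(unknown, collapse = ", "))
    }
  }

  prob <- structure(
    list(reactions = reactions, dg0 = dg0[ids], conditions = conditions,
         variables = variables, bounds = bt, epsilon = epsilon,
         ratio_bounds = ratio_bounds, dg0_error = err),
    class = "net_problem"
  )
  prob$lp <- build_lp(prob)
  prob
}

#' @export
print.net_problem <- function(x, ...) {
  n_fixed <- sum(vapply(x$reactions, `[[`, character(1), "directionality") != "reversible")
  cat(sprintf("NET problem: %d reactions (%d direction-constrained), %d concentration variables\n",
              length(x$reactions), n_fixed, length(x$variables)))
  invisible(x)
}

# ---- internal LP representation -------------------------------------------
# variables: log-concentrations x, then one bounded error variable per
# reaction with nonzero dg0 uncertainty. Constraint rows are stored as
# A v <= b / A v >= b pairs; reaction row j encodes
# dG_j' - dg0_j = RT * S_j . x + e_j.

build_lp <- function(prob) {
  rt <- rt_of(prob$conditions)
  d <- length(prob$variables)
  err_ids <- names(prob$dg0_error)[prob$dg0_error > 0]
  nv <- d + length(err_ids)
  var_names <- c(prob$variables, if (length(err_ids)) paste0(".err.", err_ids))

  lb <- c(log(prob$bounds$c_min), -prob$dg0_error[err_ids])
  ub <- c(log(prob$bounds$c_max), +prob$dg0_error[err_ids])
  names(lb) <- names(ub) <- var_names

  rxn_row <- function(rx) {
    row <- stats::setNames(numeric(nv), var_names)
    s <- rx$stoichiometry
    s <- s[names(s) %in% prob$variables]
    row[names(s)] <- rt * s
    if (rx$id %in% err_ids) row[paste0(".err.", rx$id)] <- 1
    row
  }
  rows <- matrix(unlist(lapply(prob$reactions, rxn_row)),
                 nrow = length(prob$reactions), ncol = nv, byrow = TRUE,
                 dimnames = list(names(prob$reactions), var_names))

  A <- matrix(0, 0, nv); dir <- character(0); rhs <- numeric(0); label <- character(0)
  for (id in names(prob$reactions)) {
    dd <- prob$reactions[[id]]$directionality
    if (dd == "forward_only") {
      A <- rbind(A, rows[id, ]); dir <- c(dir, "<=")
      rhs <- c(rhs, -prob$epsilon - prob$dg0[[id]]); label <- c(label, id)
    } else if (dd == "backward_only") {
      A <- rbind(A, rows[id, ]); dir <- c(dir, ">=")
      rhs <- c(rhs, prob$epsilon - prob$dg0[[id]]); label <- c(label, id)
    }
  }
  if (!is.null(prob$ratio_bounds)) {
    for (k in seq_len(nrow(prob$ratio_bounds))) {
      rb <- prob$ratio_bounds[k, ]
      row <- stats::setNames(numeric(nv), var_names)
      row[rb$a] <- 1; row[rb$b] <- -1
      lab <- paste0("ratio:", rb$a, "/", rb$b)
      if (is.finite(rb$lower) && is.finite(rb$upper) && rb$lower == rb$upper) {
        # a pinned ratio is one equality row (degenerate <=/>= pairs upset
        # simplex implementations)
        A <- rbind(A, row); dir <- c(dir, "=="); rhs <- c(rhs, log(rb$lower))
        label <- c(label, lab)
      } else {
        if (is.finite(rb$lower) && rb$lower > 0) {
          A <- rbind(A, row); dir <- c(dir, ">="); rhs <- c(rhs, log(rb$lower))
          label <- c(label, lab)
        }
        if (is.finite(rb$upper)) {
          A <- rbind(A, row); dir <- c(dir, "<="); rhs <- c(rhs, log(rb$upper))
          label <- c(label, lab)
        }
      }
    }
  }
  list(nv = nv, var_names = var_names, lb = lb, ub = ub,
       A = A, dir = dir, rhs = rhs, label = label,
       rxn_rows = rows, rt = rt)
}

# solve min/max of obj . v over the LP's constraint set; returns
# list(status, value, v). status: "optimal", "infeasible" or "failed".
solve_lp <- function(lp, obj, maximize = FALSE, keep = TRUE,
                     backend = c("boot", "pracma")) {
  backend <- match.arg(backend)
  keep_rows <- if (length(keep) == 1L && isTRUE(keep)) {
    seq_along(lp$dir)
  } else keep
  A <- lp$A[keep_rows, , drop = FALSE]
  dir <- lp$dir[keep_rows]; rhs <- lp$rhs[keep_rows]

  # shift to y = v - lb >= 0; append upper-bound rows y <= ub - lb
  span <- lp$ub - lp$lb
  rhs_sh <- rhs - if (nrow(A)) as.numeric(A %*% lp$lb) else numeric(0)
  A_all <- rbind(A, diag(lp$nv))
  dir_all <- c(dir, rep("<=", lp$nv))
  rhs_all <- c(rhs_sh, span)

  # normalise so all right-hand sides are non-negative
  flip <- rhs_all < 0
  A_all[flip, ] <- -A_all[flip, , drop = FALSE]
  rhs_all[flip] <- -rhs_all[flip]
  dir_all[flip] <- ifelse(dir_all[flip] == "<=", ">=",
                          ifelse(dir_all[flip] == ">=", "<=", "=="))

  le <- dir_all == "<="; ge <- dir_all == ">="; eq <- dir_all == "=="
  if (backend == "boot") {
    res <- tryCatch(
      boot::simplex(a = unname(obj),
                    A1 = if (any(le)) unname(A_all[le, , drop = FALSE]),
                    b1 = if (any(le)) unname(rhs_all[le]),
                    A2 = if (any(ge)) unname(A_all[ge, , drop = FALSE]),
                    b2 = if (any(ge)) unname(rhs_all[ge]),
                    A3 = if (any(eq)) unname(A_all[eq, , drop = FALSE]),
                    b3 = if (any(eq)) unname(rhs_all[eq]),
                    maxi = maximize,
                    n.iter = 50 * (lp$nv + length(rhs_all)),
                    eps = 1e-10),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(list(status = "failed", value = NA_real_, v = NULL,
                  message = conditionMessage(res)))
    }
    if (res$solved == -1) return(list(status = "infeasible", value = NA_real_, v = NULL))
    if (res$solved != 1) return(list(status = "failed", value = NA_real_, v = NULL,
                                     message = "iteration limit reached"))
    v <- res$soln + lp$lb
    list(status = "optimal", value = sum(obj * v), v = v)
  } else {
    if (!requireNamespace("pracma", quietly = TRUE)) {
      stop("backend 'pracma' requires the pracma package")
    }
    # pracma::linprog minimises cc . y over A y <= b, Aeq y = beq, y >= 0
    A2 <- rbind(A_all[le, , drop = FALSE], -A_all[ge, , drop = FALSE])
    b2 <- c(rhs_all[le], -rhs_all[ge])
    res <- tryCatch(
      suppressWarnings(pracma::linprog(
        cc = unname(obj), A = unname(A2), b = unname(b2),
        Aeq = if (any(eq)) unname(A_all[eq, , drop = FALSE]),
        beq = if (any(eq)) unname(rhs_all[eq]),
        maxiter = 10000, maximize = maximize)),
      error = function(e) e
    )
    if (inherits(res, "error") || is.null(res$x) || anyNA(res$x)) {
      msg <- if (inherits(res, "error")) conditionMessage(res) else "no solution"
      if (grepl("[Ee]mpty|[Ii]nfeasible|no feasible", msg)) {
        return(list(status = "infeasible", value = NA_real_, v = NULL))
      }
      return(list(status = "infeasible", value = NA_real_, v = NULL, message = msg))
    }
    v <- res$x + lp$lb
    list(status = "optimal", value = sum(obj * v), v = v)
  }
}

# ---- public NET operations -------------------------------------------------

#' Check thermodynamic feasibility of a NET problem
#'
#' A problem is feasible when some concentration assignment within the
#' bounds satisfies every fixed reaction direction (and every ratio bound).
#' Infeasible problems come with a certificate: an irreducible set of
#' direction/ratio constraints whose joint removal is required for
#' feasibility (computed by a deletion filter). A reaction with no
#' concentration-bearing reactants whose fixed direction contradicts its
#' constant standard energy is reported immediately with itself as the
#' certificate.
#'
#' @param problem A [net_problem()].
#' @param backend LP backend, `"boot"` (default) or `"pracma"`.
#' @return A list with elements `status` (`"feasible"`, `"infeasible"` or
#'   `"failed"`), `certificate` (character vector of constraint labels,
#'   empty when feasible) and `example` (a named feasible concentration
#'   vector in mol/L, when one exists).
#' @examples
#' cond <- glycolysis_conditions()
#' dg0 <- glycolysis_dg0(cond)
#' prob <- net_problem(glycolysis_model(), stats::setNames(dg0$dg0_kj_mol, dg0$id), cond)
#' check_feasibility(prob)$status
#' @export
check_feasibility <- function(problem, backend = "boot") {
  stopifnot(inherits(problem, "net_problem"))
  lp <- problem$lp
  # constant reactions: a sign constraint whose row is all zero either holds
  # for every concentration or for none
  if (nrow(lp$A)) {
    const_rows <- which(apply(lp$A, 1L, function(r) all(r == 0)))
    for (k in const_rows) {
      violated <- switch(lp$dir[k],
                         "<=" = 0 > lp$rhs[k],
                         ">=" = 0 < lp$rhs[k],
                         "==" = lp$rhs[k] != 0)
      if (violated) {
        return(list(status = "infeasible", certificate = lp$label[k],
                    example = NULL))
      }
    }
  }
  res <- solve_lp(lp, numeric(lp$nv), backend = backend)
  if (res$status == "optimal") {
    conc <- exp(res$v[seq_along(problem$variables)])
    names(conc) <- problem$variables
    return(list(status = "feasible", certificate = character(0), example = conc))
  }
  if (res$status == "failed") {
    return(list(status = "failed", certificate = character(0), example = NULL,
                message = res$message))
  }
  # deletion filter over the labelled constraint rows: drop a row for good
  # whenever the remainder is still infeasible; what survives is irreducible
  active <- seq_along(lp$dir)
  for (k in seq_along(lp$dir)) {
    trial <- setdiff(active, k)
    r <- solve_lp(lp, numeric(lp$nv), keep = trial, backend = backend)
    if (r$status == "infeasible") active <- trial
  }
  list(status = "infeasible", certificate = unique(lp$label[active]),
       example = NULL)
}

#' Feasible range of a reaction's Gibbs energy
#'
#' Minimises and maximises the affine reaction Gibbs energy
#' `Delta_r G_k'` over the feasible set of the NET problem (two LP solves).
#' By default the reaction's own direction constraint stays active while it
#' is being ranged, i.e. the range is taken within the feasible set.
#'
#' @param problem A [net_problem()].
#' @param reaction_id Id of the reaction to range.
#' @param keep_own_sign Keep the ranged reaction's own direction constraint
#'   active (default `TRUE`); set `FALSE` to range it against the rest of
#'   the network only.
#' @param backend LP backend, `"boot"` or `"pracma"`.
#' @return An object of class `gibbs_range`: a list with `reaction_id`,
#'   `dg_min`, `dg_max` (kJ/mol) and `status` (`"feasible"`, `"infeasible"`
#'   or `"failed"`).
#' @export
dg_range <- function(problem, reaction_id, keep_own_sign = TRUE, backend = "boot") {
  stopifnot(inherits(problem, "net_problem"))
  if (!reaction_id %in% names(problem$reactions)) {
    stop("unknown reaction id: ", reaction_id)
  }
  lp <- problem$lp
  keep <- if (keep_own_sign) seq_along(lp$dir) else which(lp$label != reaction_id)
  obj <- lp$rxn_rows[reaction_id, ]
  lo <- solve_lp(lp, obj, maximize = FALSE, keep = keep, backend = backend)
  hi <- solve_lp(lp, obj, maximize = TRUE, keep = keep, backend = backend)
  status <- if (lo$status == "optimal" && hi$status == "optimal") "feasible"
  else if (lo$status == "infeasible" || hi$status == "infeasible") "infeasible"
  else "failed"
  structure(
    list(reaction_id = reaction_id,
         dg_min = problem$dg0[[reaction_id]] + lo$value,
         dg_max = problem$dg0[[reaction_id]] + hi$value,
         status = status),
    class = "gibbs_range"
  )
}

#' @export
print.gibbs_range <- function(x, ...) {
  if (x$status == "feasible") {
    cat(sprintf("%s: dG' in [%.4f, %.4f] kJ/mol\n", x$reaction_id, x$dg_min, x$dg_max))
  } else {
    cat(sprintf("%s: %s\n", x$reaction_id, x$status))
  }
  invisible(x)
}

#' Gibbs-energy ranges for every reaction of a NET problem
#'
#' @param problem A [net_problem()].
#' @param backend LP backend.
#' @param keep_own_sign Passed to [dg_range()].
#' @return A data frame with columns `id`, `dg_min`, `dg_max`, `status`.
#' @export
dg_ranges <- function(problem, keep_own_sign = TRUE, backend = "boot") {
  ids <- names(problem$reactions)
  rows <- lapply(ids, dg_range, problem = problem,
                 keep_own_sign = keep_own_sign, backend = backend)
  data.frame(
    id = ids,
    dg_min = vapply(rows, `[[`, numeric(1), "dg_min"),
    dg_max = vapply(rows, `[[`, numeric(1), "dg_max"),
    status = vapply(rows, `[[`, character(1), "status"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Thermodynamically tightened concentration range of one metabolite
#'
#' Minimises and maximises one log-concentration over the feasible set and
#' exponentiates, giving the concentrations the network's directionality
#' constraints still allow. The result always lies within the input bounds
#' (the optimisation can only tighten).
#'
#' @param problem A [net_problem()].
#' @param reactant_id Name of a concentration-bearing reactant.
#' @param backend LP backend.
#' @return A list with `reactant_id`, `c_min`, `c_max` (mol/L) and `status`.
#' @export
concentration_range <- function(problem, reactant_id, backend = "boot") {
  stopifnot(inherits(problem, "net_problem"))
  i <- match(reactant_id, problem$variables)
  if (is.na(i)) stop("unknown (or concentration-free) reactant: ", reactant_id)
  lp <- problem$lp
  obj <- stats::setNames(numeric(lp$nv), lp$var_names)
  obj[reactant_id] <- 1
  lo <- solve_lp(lp, obj, maximize = FALSE, backend = backend)
  hi <- solve_lp(lp, obj, maximize = TRUE, backend = backend)
  if (lo$status != "optimal" || hi$status != "optimal") {
    return(list(reactant_id = reactant_id, c_min = NA_real_, c_max = NA_real_,
                status = if (lo$status == "infeasible") "infeasible" else "failed"))
  }
  input <- problem$bounds[problem$bounds$reactant == reactant_id, ]
  list(reactant_id = reactant_id,
       c_min = min(max(exp(lo$value), input$c_min), input$c_max),
       c_max = max(min(exp(hi$value), input$c_max), input$c_min),
       status = "feasible")
}

#' Tightened concentration ranges for all metabolites
#'
#' @param problem A [net_problem()].
#' @param backend LP backend.
#' @return A data frame with columns `reactant`, `c_min`, `c_max`,
#'   `provenance`, `status`.
#' @export
concentration_ranges <- function(problem, backend = "boot") {
  rows <- lapply(problem$variables, concentration_range,
                 problem = problem, backend = backend)
  data.frame(
    reactant = problem$variables,
    c_min = vapply(rows, `[[`, numeric(1), "c_min"),
    c_max = vapply(rows, `[[`, numeric(1), "c_max"),
    provenance = problem$bounds$provenance[match(problem$variables,
                                                 problem$bounds$reactant)],
    status = vapply(rows, `[[`, character(1), "status"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Assign reaction directionalities from concentration ranges
#'
#' Runs NET analysis "in reverse": starting from the stated directionality
#' flags (a priori typically all reversible), each initially reversible
#' reaction whose feasible Gibbs-energy range lies strictly below
#' `-epsilon` becomes forward-only, and strictly above `+epsilon`
#' backward-only. Because each newly fixed direction constrains the
#' concentrations reachable by the rest of the network, the procedure
#' iterates to a fixed point (constraint propagation); a fixed point must be
#' reached within one sweep per reaction, otherwise an invariant violation
#' is raised.
#'
#' @param problem A [net_problem()].
#' @param backend LP backend.
#' @return A list with `directions` (named character vector), `iterations`,
#'   and `problem` (the problem rebuilt with the assigned directions).
#' @export
assign_directionality <- function(problem, backend = "boot") {
  stopifnot(inherits(problem, "net_problem"))
  eps <- problem$epsilon
  current <- problem
  n <- length(problem$reactions)
  for (iter in seq_len(n + 1L)) {
    changed <- FALSE
    dirs <- vapply(current$reactions, `[[`, character(1), "directionality")
    for (id in names(current$reactions)[dirs == "reversible"]) {
      rng <- dg_range(current, id, backend = backend)
      if (rng$status != "feasible") {
        stop("directionality assignment hit an ", rng$status,
             " subproblem at reaction '", id, "'")
      }
      newdir <- if (rng$dg_max < -eps) "forward_only"
      else if (rng$dg_min > eps) "backward_only"
      else "reversible"
      if (newdir != "reversible") {
        current$reactions[[id]]$directionality <- newdir
        changed <- TRUE
      }
    }
    if (changed) {
      current$lp <- build_lp(current)
    } else {
      return(list(
        directions = vapply(current$reactions, `[[`, character(1), "directionality"),
        iterations = iter, problem = current
      ))
    }
  }
  stop("directionality assignment did not reach a fixed point within ",
       n + 1L, " sweeps (invariant violation)")
}

#' Flag putative regulatory sites
#'
#' Reactions displaced far from thermodynamic equilibrium — whose maximum
#' feasible Gibbs energy stays strictly below a threshold (default
#' -10 kJ/mol) — are flagged as candidate sites of genetic or allosteric
#' regulation.
#'
#' @param problem A [net_problem()].
#' @param threshold Flagging threshold in kJ/mol (strict `<`, default -10).
#' @param backend LP backend.
#' @return Character vector of flagged reaction ids.
#' @export
flag_regulatory_sites <- function(problem, threshold = -10, backend = "boot") {
  ranges <- dg_ranges(problem, backend = backend)
  ranges$id[ranges$status == "feasible" & ranges$dg_max < threshold]
}
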