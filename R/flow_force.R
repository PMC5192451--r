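#' Parameters of the flow-force relation for a unimolecular reaction
#'
#' Kinetic and conservation parameters of a reversible unimolecular
#' enzymatic reaction S = P at steady state with a conserved substrate plus
#' product pool (Cs + Cp = C). Under that conservation the net rate can be
#' written purely as a function of the thermodynamic driving force
#' (affinity) A = -Delta_r G; see [rate_at_affinity()].
#'
#' @param vs_max Maximum forward rate (any consistent rate unit; rates are
#'   reported normalised to `vs_max`).
#' @param vp_max Maximum backward rate, same unit as `vs_max`.
#' @param Ks,Kp Michaelis constants of substrate and product, mol/L.
#' @param C Conserved total substrate + product concentration, mol/L.
#' @param temperature Temperature in K.
#' @return An object of class `flow_force_params`.
#' @examples
#' # a thermodynamically reversible parameterisation: equal Michaelis
#' # constants of 1 mM, C = 10 mM, fast reverse limb
#' flow_force_params(vs_max = 1, vp_max = 100, Ks = 1e-3, Kp = 1e-3, C = 1e-2)
#' @export
flow_force_params <- function(vs_max = 1, vp_max = 100, Ks = 1e-3, Kp = 1e-3,
                              C = 1e-2, temperature = 298.15) {
  vals <- c(vs_max = vs_max, vp_max = vp_max, Ks = Ks, Kp = Kp, C = C,
            temperature = temperature)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all flow-force parameters must be positive and finite")
  }
  structure(as.list(vals), class = "flow_force_params")
}

#' @export
print.flow_force_params <- function(x, ...) {
  cat(sprintf(
    "flow-force params: vs_max %g, vp_max %g, Ks %g M, Kp %g M, C %g M, T %g K\n",
    x$vs_max, x$vp_max, x$Ks, x$Kp, x$C, x$temperature))
  invisible(x)
}

#' Net rate as a function of affinity (flow-force relation)
#'
#' Evaluates the normalised steady-state rate of a reversible unimolecular
#' reaction with a conserved substrate + product pool as a function of the
#' affinity A = -Delta_r G:
#' \deqn{\frac{v}{v_s^{max}} = \frac{e^{A/RT} - 1}
#'   {\left(\frac{K_s}{C}+1\right) e^{A/RT}
#'    + \frac{v_s^{max}}{v_p^{max}} \left(\frac{K_p}{C}+1\right)}}
#' The rate is zero at A = 0 (equilibrium), strictly increasing in A, and
#' saturates at `1 / (Ks/C + 1)` as A grows.
#'
#' @param A Affinity in kJ/mol (vectorised); negative values give reverse
#'   net flux.
#' @param params A [flow_force_params()].
#' @return Normalised rate `v / vs_max`.
#' @examples
#' rate_at_affinity(c(0, 5, 50), flow_force_params())
#' @export
rate_at_affinity <- function(A, params) {
  stopifnot(inherits(params, "flow_force_params"), is.numeric(A))
  rt <- R_GAS * params$temperature
  a <- A / rt
  alpha <- params$Ks / params$C + 1
  beta <- (params$vs_max / params$vp_max) * (params$Kp / params$C + 1)
  out <- numeric(length(a))
  neg <- a <= 0
  # two algebraically identical branches keep exp() bounded for any A
  out[neg] <- (exp(a[neg]) - 1) / (alpha * exp(a[neg]) + beta)
  out[!neg] <- (1 - exp(-a[!neg])) / (alpha + beta * exp(-a[!neg]))
  out
}

#' Affinity sweep with near-equilibrium proportionality coefficient
#'
#' Evaluates the flow-force curve on an affinity grid and fits the
#' near-equilibrium proportional law `v = L A` by least squares through the
#' origin over the points with `|A| < RT`. For a thermodynamically
#' reversible parameterisation the proportional law holds over a wide
#' affinity range (a doubling in affinity doubles the flux); for an
#' irreversible parameterisation the curve is linear with an offset at
#' larger affinities and proportionality holds only very close to
#' equilibrium.
#'
#' @param params A [flow_force_params()].
#' @param A_grid Numeric affinity grid in kJ/mol; must include 0 (so that
#'   the equilibrium anchor of the proportional fit is present).
#' @return A list with `curve` (data frame `A`, `v`), `L` (fitted
#'   phenomenological coefficient, rate per kJ/mol), and `residuals`
#'   (deviations `v - L A` on the grid).
#' @examples
#' sw <- flow_force_sweep(flow_force_params(), seq(-5, 30, by = 0.5))
#' sw$L
#' @export
flow_force_sweep <- function(params, A_grid = seq(-10, 30, length.out = 201)) {
  stopifnot(is.numeric(A_grid), length(A_grid) >= 3L)
  if (min(abs(A_grid)) > 1e-9 &&
      !(min(A_grid) < 0 && max(A_grid) > 0)) {
    stop("A_grid must cover A = 0")
  }
  rt <- R_GAS * params$temperature
  v <- rate_at_affinity(A_grid, params)
  near <- abs(A_grid) < rt & abs(A_grid) > 0
  if (!any(near)) stop("A_grid has no nonzero points with |A| < RT")
  L <- sum(A_grid[near] * v[near]) / sum(A_grid[near]^2)
  list(curve = data.frame(A = A_grid, v = v), L = L,
       residuals = v - L * A_grid)
}

#' Canonical reversible / irreversible flow-force parameter sets
#'
#' Two standard parameterisations contrasting thermodynamically reversible
#' and irreversible enzymes at a conserved pool of C = 10 mM: the
#' reversible enzyme is symmetric (equal maximum rates of 100 in both
#' directions, Ks = Kp = 1 mM), the irreversible one has a 100-fold slower
#' reverse limb (vp_max = 1) and a weaker product site (Kp = 10 mM).
#'
#' @param kind `"reversible"` or `"irreversible"`.
#' @return A [flow_force_params()].
#' @examples
#' flow_force_example_params("reversible")
#' @export
flow_force_example_params <- function(kind = c("reversible", "irreversible")) {
  kind <- match.arg(kind)
  if (kind == "reversible") {
    flow_force_params(vs_max = 100, vp_max = 100, Ks = 1e-3, Kp = 1e-3, C = 1e-2)
  } else {
    flow_force_params(vs_max = 100, vp_max = 1, Ks = 1e-3, Kp = 10e-3, C = 1e-2)
  }
}

#' Capacity-normalised deviation from the proportional flow-force law
#'
#' Measures how far a flow-force curve departs from the proportional
#' near-equilibrium law `v = L A`, per unit of capacity:
#' `(v(A) - L A) / L`, in affinity units (kJ/mol). Normalising by L makes
#' curves of very different enzyme capacity comparable — otherwise a
#' 100-fold larger L trivially produces 100-fold larger raw residuals
#' regardless of linearity. By default L is the tangent slope at
#' equilibrium ([flow_force_slope0()]).
#'
#' @param params A [flow_force_params()].
#' @param A_grid Affinity grid in kJ/mol.
#' @param L Proportionality coefficient; defaults to the tangent slope at
#'   A = 0.
#' @return Numeric vector of signed deviations, kJ/mol.
#' @examples
#' g <- seq(-10, 10, by = 0.5)
#' rev <- proportionality_residuals(flow_force_example_params("reversible"), g)
#' irr <- proportionality_residuals(flow_force_example_params("irreversible"), g)
#' all(abs(rev) <= abs(irr))
#' @export
proportionality_residuals <- function(params, A_grid, L = flow_force_slope0(params)) {
  stopifnot(is.numeric(A_grid), is.numeric(L), L > 0)
  (rate_at_affinity(A_grid, params) - L * A_grid) / L
}

#' Near-equilibrium slope by central finite differences
#'
#' Numerical derivative of [rate_at_affinity()] at A = 0; equals the
#' phenomenological coefficient L of the proportional regime.
#'
#' @param params A [flow_force_params()].
#' @param h Step size in kJ/mol.
#' @return Slope in normalised rate per kJ/mol.
#' @export
flow_force_slope0 <- function(params, h = 1e-5) {
  (rate_at_affinity(h, params) - rate_at_affinity(-h, params)) / (2 * h)
}
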