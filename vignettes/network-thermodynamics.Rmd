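---
title: "Thermodynamic analysis of metabolic networks with thermonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic analysis of metabolic networks with thermonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermonet)
```

## The problem

The net flux of a biochemical reaction runs in the direction in which its
Gibbs energy change is negative. Given quantitative metabolite
concentrations, thermodynamics therefore constrains which directions a
metabolic network can actually use, whether a measured metabolome is
consistent with an assumed flux pattern at all, and which reactions are held
so far from equilibrium that they are plausible sites of regulation.
`thermonet` implements that chain of reasoning: transformed Gibbs energies
of formation at physiological conditions, reaction energies over
pseudoisomer-grouped reactants, transport energetics across membranes,
linear-programming analysis of whole networks in log-concentration space
(NET analysis), and the non-equilibrium flow-force relation for single
enzymatic reactions.

## Transformed formation energies

Tabulated standard Gibbs energies of formation refer to zero ionic strength
and an explicit proton inventory. Intracellular conditions differ, so each
species (one protonation state, with formation energy $\Delta_f G^0$,
charge $z$ and hydrogen count $N_H$) is moved to pH and ionic strength $I$
by the Legendre transform

$$\Delta_f G'^0 = \Delta_f G^0 - N_H RT \ln(10^{-\mathrm{pH}})
  - RT \ln(10) A\,(z^2 - N_H)\frac{\sqrt I}{1 + 1.6\sqrt I},$$

whose last term comes from the extended Debye–Hückel activity model
($A = 0.510651$, $B = 1.6$ in $(\mathrm{L/mol})^{1/2}$). Two numerical
choices matter here:

* **Gas constant.** We use $R = 8.31451\,\mathrm{J\,mol^{-1}K^{-1}}$.
  With it, $RT\ln(10)A$ evaluates to 2.91482 kJ/mol at 298.15 K — the
  coefficient conventionally quoted for the ionic-strength term — and the
  bundled glycolysis reference values reproduce to a few thousandths of a
  kJ/mol. The truncation $R = 8.314$ shifts every hydrogen-bearing species
  by about 0.0025 kJ/mol per hydrogen atom, which is enough to miss
  tabulated values for NADH (27 hydrogens) by ~0.07 kJ/mol.
* **Temperature dependence.** The 2.91482 coefficient is recomputed as
  $RT\ln(10)A$ from the conditions' temperature rather than hard-coded, so
  non-standard temperatures are supported; $A$ and $B$ themselves are kept
  at their standard-temperature values (the package carries no enthalpy
  data, so full temperature corrections of $\Delta_f G^0$ are out of
  scope).

The Debye–Hückel expression is stated for $I$ between 0.005 and 0.25 M.
Outside that window there is no better closed form available to the
package, so `conditions()` records a warning state and computes anyway.

A biochemical reactant such as ATP is a pool of protonation states assumed
to be at internal equilibrium. Species-level values are pooled with the
log-sum-exp rule

$$\Delta_f G_j'^0 = -RT\ln \sum_i \exp\!\left(-\Delta_f G_i'^0/RT\right),$$

implemented with a shift by the minimum input so the exponentials never
overflow. The pooled value is always at or below the most stable state and
converges to it as the other states fall away.

```{r}
cond <- glycolysis_conditions() # pH 7, I 0.15 M, 298.15 K (yeast cytosol)
head(reactant_energies(glycolysis_species(), cond), 4)
```

Reaction energies are stoichiometric sums of reactant-level values,
$\Delta_r G'^0 = \sum_i S_{ij} \Delta_f G_i'^0$. Two conventions follow the
standard biochemical treatment: reactions are stored without protons (pH is
held constant, so hydrogen need not be balanced; the import layer strips
H⁺ tokens with a warning), and water contributes its formation energy to
$\Delta_r G'^0$ but has unit activity in the concentration-dependent term
— dropping water's −155.88 kJ/mol from the enolase reaction, for example,
would miss its tabulated value by exactly that amount.

```{r}
glycolysis_dg0()
```

One caveat on the bundled reference values: for phosphoglycerate kinase the
stoichiometric sum over the bundled formation energies gives
−8.16 kJ/mol, while the value usually quoted alongside this dataset is
+8.16 kJ/mol; the sign there is inconsistent with the formation energies it
derives from, so the package (and its tests) carry the recomputed value.
Reference conventions are a second caveat: NAD is anchored at 0 kJ/mol and
NADH measured against it, so the table's `reference_group` column tags the
pair and mixing anchored with absolute values can be detected.

## Group contributions

Where no measured formation energy exists, it is estimated additively from
counted functional groups, $\Delta_f G^0 = P_o + \sum_j n_j P_j$. The
module is entirely table-driven: ring and similar structural corrections
are ordinary named groups (e.g. `">CH- (ring)"`), not special-cased code,
and fuller published tables load from TSV without code changes. The two
bundled tables carry the glucose worked example (six groups) in both an
older and an updated contribution set; the estimates land 2% and 0.2% from
the experimental −915.9 kJ/mol respectively. Printed per-group totals in
such tables are typically rounded from unrounded intermediates and can
disagree with count × unit in the last digit, so tests compare recomputed
products at ±0.3 kJ/mol. Decomposing a structure into groups is manual by
design; automatic decomposition from SMILES and the component-contribution
method are out of scope.

## Transport reactions

A reaction spanning two compartments gains two terms on top of its
chemical part: the electrical work $nF\Delta\Psi$ of moving net charge $n$
across the membrane potential, and a pH-gradient term

$$\Delta_{\Delta \mathrm{pH}} G = \sum_i s_i \Delta_f G_i'^0
  - 2.3\,RT \sum_i s_i N_H(i)\,\mathrm{pH}_i,$$

in which each transported species contributes its transformed energy
evaluated under its own compartment's conditions. The literal 2.3 (rather
than $\ln 10$) is kept as conventionally printed; the difference is ~0.1%
of the term. Signs follow a destination-minus-origin convention for $s_i$
and $\Delta\Psi$, documented on `transport_spec()`; reversing a transport
reaction negates $n$ and the $s_i$ but not $\Delta\Psi$, which belongs to
the membrane, so the transport term negates exactly. Both compartments
must share one temperature; no Nernst-equilibrium machinery is included.

## NET analysis

With $x_i = \ln c_i$, every reaction energy
$\Delta_r G_j' = \Delta_r G_j'^0 + RT \sum_i S_{ij} x_i$ is affine, so the
following are all linear programs over the box
$\ln c^{min} \le x \le \ln c^{max}$:

* **feasibility** — is any concentration assignment consistent with all
  fixed reaction directions (and optional cofactor-ratio bounds)?
* **Gibbs-energy ranges** — minimise/maximise each $\Delta_r G_k'$ over the
  feasible set (the reaction's own sign constraint stays active by
  default; a flag drops it);
* **concentration tightening** — minimise/maximise each $x_i$;
* **directionality assignment** — fix each initially reversible reaction
  whose range lies strictly on one side of zero, iterating to a fixed
  point so that input-irreversible reactions propagate through shared
  metabolite pools;
* **regulatory-site flagging** — reactions with
  $\Delta_r G'_{max} < -10$ kJ/mol (strictly; the threshold is an
  argument) are far enough from equilibrium to be candidate control
  points.

Numerical choices: strict inequalities are approximated as
$\le -\varepsilon$ / $\ge +\varepsilon$ with $\varepsilon = 10^{-6}$ kJ/mol
(configurable) since LPs cannot express strictness; unmeasured metabolites
default to a physiological range of $10^{-6}$ to $5\times10^{-2}$ M
(configurable — the literature states "physiological range" without
numbers, so this is the package's choice and can be overridden per
metabolite); optional per-reaction symmetric uncertainties on
$\Delta_r G'^0$ relax the energy to an interval via a bounded auxiliary
variable, and are off by default. The default solver is the two-phase
simplex from the recommended `boot` package, with `pracma`'s solver as an
alternative backend; results agree to well under $10^{-4}$ kJ/mol and a
pinned ratio bound is emitted as a single equality row because degenerate
$\le/\ge$ pairs upset simplex implementations. Infeasibility comes with an
irreducible certificate computed by a deletion filter over the direction
and ratio constraints, and a reaction with no concentration-bearing
reactants whose fixed sign contradicts its constant energy is reported
immediately by name.

Two curation passes prepare models that were not written with
thermodynamics in mind: antiparallel reaction pairs (the same conversion
catalysed by different enzymes in opposite directions) are lumped into one
reversible reaction, since keeping both copies forces both energies
negative and hence equilibrium; and tagged dissolved-CO₂ species
(CO₂/H₂CO₃/HCO₃⁻/CO₃²⁻) pool into a single CO2tot reactant with water
added to rebalance oxygen. The water adjustment per pooled species is an
argument because it depends on the reference state chosen for the pool;
the default assumes the pool is referenced to dissolved CO₂.

```{r}
dg0 <- glycolysis_dg0(cond)
prob <- net_problem(glycolysis_model(), setNames(dg0$dg0_kj_mol, dg0$id), cond)
check_feasibility(prob)$status
head(dg_ranges(prob), 3)
```

## The synthetic toy-network generator

`generate_toy_network()` builds the small random instances the test suite
and benchmarks run on. Feasible instances plant a concentration witness
inside sampled bounds and choose standard energies so every
direction-constrained reaction clears its sign at the witness by a 2–15
kJ/mol margin; infeasible instances overwrite one constrained reaction's
energy so its sign fails at the most favourable corner of the
concentration box, again by a positive margin. Default windows —
concentrations sampled inside $10^{-6}$ to $5\times10^{-2}$ M, reversible
energies uniform on ±30 kJ/mol, unit-to-double stoichiometric
coefficients over two to three metabolites per reaction — mirror the
physiological ranges and central-metabolism energies discussed above.
Generation is deterministic per seed and restores the global RNG state.

What these instances emulate is the *geometry* of NET problems: coupled
affine energies over a concentration box. What they do not emulate is the
structure of real networks — conserved moieties, hub cofactors shared by
dozens of reactions, correlated measurement errors, or energies estimated
with correlated group-contribution uncertainty. Tests passing on them
show the optimisation machinery is correct, not that any particular
biological dataset is feasible.

The test suite checks the LP answers against brute-force enumeration on
dense log-concentration grids, with a strict/relaxed two-sided construction
that makes grid conclusions rigorous for the continuous problem: a strictly
grid-feasible point certifies feasibility, while emptiness of the grid
under constraints relaxed by one grid step's worth of energy certifies
infeasibility. Instances the grid resolution cannot certify are excluded
by the oracle itself, never by looking at the package's answer. Problem
sizes — up to four metabolites for enumeration, a thousand seeded
instances per property — keep the whole suite under a minute.

## The flow-force relation

Feasibility says nothing about rates. For a reversible unimolecular
reaction $S \rightleftharpoons P$ at steady state with a conserved pool
$C_s + C_p = C$, eliminating the concentrations from reversible
Michaelis–Menten kinetics leaves the net rate as a function of the
affinity $A = -\Delta_r G$ alone:

$$\frac{v}{v_s^{max}} =
  \frac{e^{A/RT} - 1}
  {\left(\frac{K_s}{C}+1\right) e^{A/RT}
   + \frac{v_s^{max}}{v_p^{max}}\left(\frac{K_p}{C}+1\right)}.$$

The implementation evaluates an algebraically identical rescaled form for
positive affinities so the exponential never overflows; the rate is
exactly zero at equilibrium, strictly increasing, and saturates at
$1/(K_s/C + 1)$. Near equilibrium the proportional law $v = LA$ holds;
`flow_force_sweep()` reports $L$ as a least-squares slope through the
origin over $|A| < RT$, and `flow_force_slope0()` gives the exact tangent.

The canonical contrast between a thermodynamically reversible and an
irreversible enzyme is bundled as `flow_force_example_params()`. The
conventional parameterisation of this contrast quotes only the backward
maximum rates (100 versus 1) with $K_s = K_p = 1$ mM (irreversible:
$K_p = 10$ mM) and $C = 10$ mM; the forward maximum is left implicit. We
set $v_s^{max} = v_p^{max} = 100$ for the reversible enzyme — a symmetric
carrier, which is what thermodynamic reversibility means mechanistically —
and $v_s^{max} = 100$, $v_p^{max} = 1$ for the irreversible one. Under any
asymmetric reading of the reversible set the advertised contrast actually
inverts, which is why the choice is documented here rather than buried.
Because the two parameterisations differ a hundred-fold in capacity $L$,
proportionality is compared per unit capacity
(`proportionality_residuals()`, in affinity units): on that scale the
reversible enzyme is strictly closer to $v = LA$ at every nonzero
affinity, which is the regime ordering the package asserts — curve shapes
are never compared against values read off a published figure.

## Interfaces and limitations

All energies are kJ/mol, concentrations mol/L, temperatures K. Bespoke TSV
(species tables, models with equation strings, bounds) and JSON
(per-compartment conditions) are the interchange formats; a minimal SBML
importer maps species references and reversibility flags onto the same
representation. The `thermonet` script under `exec/` exposes the pipeline
as subcommands (`transform`, `dg0`, `net-check`, `net-range`, `direction`,
`regulatory`, `groupgc`, `flowforce`, `make-toy`) with exit codes 0 /
1 (infeasible) / 2 (input error).

Known limitations, all deliberate: no metal-complex pseudoisomers (no
binding data is bundled), no temperature dependence of $\Delta_f G^0$
itself, no flux-space optimisation coupling directions to mass balance
(the analysis constrains concentrations and signs only), and no automatic
molecular decomposition for group contributions.
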