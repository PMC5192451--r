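# thermonet

Thermodynamics-based analysis of metabolic networks in R: from tabulated
standard Gibbs energies of formation to network-level statements about
which reactions can run in which direction inside a cell.

Quantitative metabolomics gives concentrations; thermodynamics turns them
into constraints. A reaction's net flux runs where its Gibbs energy is
negative, so a metabolic network plus measured (or assumed physiological)
concentration ranges defines a feasibility problem: which directions are
possible at all, how far each reaction sits from equilibrium, and which
metabolite concentrations the network itself pins down. `thermonet`
implements that pipeline for systems biologists working with metabolic
models and metabolome data.

## What it computes

**Transformed formation energies.** Each species (one protonation state:
formation energy Δ<sub>f</sub>G⁰, charge z, hydrogen count N<sub>H</sub>)
is moved to physiological pH and ionic strength I by the Legendre
transform

Δ<sub>f</sub>G′⁰ = Δ<sub>f</sub>G⁰ − N<sub>H</sub>·RT·ln(10<sup>−pH</sup>) −
RT·ln(10)·A·(z² − N<sub>H</sub>)·√I / (1 + 1.6√I)

(extended Debye–Hückel, A = 0.510651). The protonation states of one
reactant (ATP⁴⁻, HATP³⁻, H₂ATP²⁻ …) pool as pseudoisomers:
Δ<sub>f</sub>G′⁰<sub>j</sub> = −RT·ln Σ<sub>i</sub> exp(−Δ<sub>f</sub>G′⁰<sub>i</sub>/RT).
Reaction energies are stoichiometric sums Δ<sub>r</sub>G′⁰ = Σ S<sub>ij</sub>Δ<sub>f</sub>G′⁰<sub>i</sub>.

**Group contributions.** Δ<sub>f</sub>G⁰ estimates from counted functional
groups, Δ<sub>f</sub>G⁰ = P₀ + Σ n<sub>j</sub>P<sub>j</sub>, table-driven.

**Transport reactions.** Membrane potential (nFΔΨ) and pH-gradient terms
on top of the chemical part for reactions spanning compartments.

**NET analysis.** In log-concentration space every Δ<sub>r</sub>G′ is
affine, so feasibility of a measured metabolome, per-reaction
Δ<sub>r</sub>G′ ranges, tightened concentration ranges, directionality
assignment with network propagation, and regulatory-site flagging
(Δ<sub>r</sub>G′<sub>max</sub> < −10 kJ/mol) are all linear programs.

**Flow-force relation.** For a unimolecular reaction with a conserved
substrate+product pool, the net rate as a function of affinity A = −Δ<sub>r</sub>G,
with the near-equilibrium proportional law v = L·A and the
reversible-versus-irreversible regime contrast.

A yeast glycolysis reference dataset (17 reactants, 32 species, 10
reactions, cytosolic pH 7 / I 0.15 M / 298.15 K) is bundled, as is a seeded
generator of feasible- and infeasible-by-construction toy networks.

## Worked example

```r
library(thermonet)

cond <- glycolysis_conditions()   # pH 7, I 0.15 M, 298.15 K
energies <- reactant_energies(glycolysis_species(), cond)
head(energies, 5)
#>                        reactant n_species dfg0_prime_kj_mol
#> 1 3-Phospho-glyceroyl phosphate         2         -2206.351
#> 2           2-Phospho-glycerate         2         -1341.508
#> 3           3-Phospho-glycerate         2         -1347.406
#> 4                           ADP         3         -1425.173
#> 5                           ATP         3         -2292.282
```

ATP's −2292.28 kJ/mol is the pooled value of its three protonation states
after the pH/ionic-strength transform. Reaction energies follow, e.g.
hexokinase at −24.58 kJ/mol, and a NET problem asks whether the whole
pathway can run forward within physiological concentrations (1 µM – 50 mM):

```r
dg0 <- glycolysis_dg0()
fwd <- lapply(glycolysis_model(), function(r) { r$directionality <- "forward_only"; r })
prob <- net_problem(fwd, setNames(dg0$dg0_kj_mol, dg0$id), cond)

check_feasibility(prob)$status
#> [1] "feasible"
head(dg_ranges(prob), 4)
#>     id    dg_min dg_max   status
#> 1 HEX1 -75.02251 -1e-06 feasible
#> 2  PGI -23.62454 -1e-06 feasible
#> 3  PFK -67.66052 -1e-06 feasible
#> 4  FBA -31.25790 -1e-06 feasible
head(concentration_ranges(prob), 3)
#>              reactant       c_min c_max provenance   status
#> 1             Glucose 1.00000e-06  0.05    default feasible
#> 2                 ATP 1.00000e-06  0.05    default feasible
#> 3 Glucose 6-phosphate 3.63207e-06  0.05    default feasible
```

Every reaction can be driven forward (all `dg_min` < 0, and the forward
constraints cap `dg_max` just below zero); the directionality constraints
already tighten glucose 6-phosphate's feasible floor above its default
bound. With wide default bounds no reaction is *forced* below −10 kJ/mol,
so `flag_regulatory_sites(prob)` is empty — flags appear once measured
concentrations narrow the ranges.

A command-line front end (`exec/thermonet`) exposes the same pipeline as
subcommands (`transform`, `dg0`, `net-check`, `net-range`, `direction`,
`regulatory`, `groupgc`, `flowforce`, `make-toy`); exit codes distinguish
success (0), thermodynamic infeasibility (1) and input errors (2).

See `vignettes/network-thermodynamics.Rmd` for the model, conventions
(water, protons, reference-anchored cofactors), numerical choices and
limitations.

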