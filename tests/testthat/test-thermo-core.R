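cond_yeast <- conditions(ph = 7, ionic_strength = 0.15, temperature = 298.15)

test_that("conditions validate inputs and record the Debye-Huckel range state", {
  expect_error(conditions(ionic_strength = -0.1), "ionic_strength")
  expect_error(conditions(temperature = 0), "temperature")
  expect_true(cond_yeast$ionic_strength_in_range)
  expect_warning(c0 <- conditions(ionic_strength = 0.5), "validity range")
  expect_false(c0$ionic_strength_in_range)
})

test_that("extended Debye-Huckel log activity coefficient matches direct arithmetic", {
  expect_identical(log_activity_coefficient(0, cond_yeast), 0)
  # -A sqrt(0.15) / (1 + 1.6 sqrt(0.15)) with A = 0.510651
  expect_equal(log_activity_coefficient(1, cond_yeast), -0.1221072, tolerance = 1e-6)
  # z^2 scaling is exact
  expect_equal(log_activity_coefficient(2, cond_yeast),
               4 * log_activity_coefficient(1, cond_yeast))
  c_i0 <- suppressWarnings(conditions(ionic_strength = 0))
  expect_identical(log_activity_coefficient(3, c_i0), 0)
})

test_that("species-level transform reproduces tabulated formation energies", {
  glc <- transform_species(species("Glucose", -915.9, 0, 12), cond_yeast)
  expect_equal(glc$value, -428.06, tolerance = 0.02)
  expect_identical(glc$level, "species")
  nadh <- transform_species(species("NADH", 22.65, -2, 27), cond_yeast)
  expect_equal(nadh$value, 1117.50, tolerance = 0.02)
  # a species with no hydrogens and no charge is untouched by the transform
  inert <- transform_species(species("X", -123.4, 0, 0), cond_yeast)
  expect_equal(inert$value, -123.4)
})

test_that("at zero ionic strength the transform reduces to the pH term alone", {
  cond0 <- suppressWarnings(conditions(ph = 7, ionic_strength = 0))
  rt <- 8.31451e-3 * 298.15
  set.seed(42)
  for (i in 1:25) {
    sp <- species("rand", stats::runif(1, -3000, 100),
                  sample(-4:2, 1), sample(0:30, 1))
    expect_equal(transform_species(sp, cond0)$value,
                 sp$dfg0 + sp$n_hydrogen * rt * log(10^7), tolerance = 1e-9)
  }
})

test_that("pseudoisomer merging is stable, condition-checked and bounded by its inputs", {
  rt <- 8.31451e-3 * 298.15
  one <- transform_species(species("A", -100, 0, 0), cond_yeast)
  expect_equal(merge_pseudoisomers(list(one))$value, one$value)
  # two equal-energy states: G - RT ln 2
  two <- merge_pseudoisomers(list(one, one))
  expect_equal(two$value, one$value - rt * log(2), tolerance = 1e-10)
  expect_identical(two$level, "reactant")
  # merged value never exceeds the most stable state, and approaches it as
  # the other states fall away (dominance limit)
  set.seed(7)
  for (gap in c(1, 5, 20, 80, 300)) {
    e2 <- transform_species(species("B", -100 + gap, 0, 0), cond_yeast)
    m <- merge_pseudoisomers(list(one, e2))$value
    expect_lte(m, min(one$value, e2$value) + 1e-12)
    if (gap >= 80) expect_equal(m, one$value, tolerance = 1e-10)
  }
  other <- transform_species(species("A", -100, 0, 0),
                             conditions(ph = 6, ionic_strength = 0.15))
  expect_error(merge_pseudoisomers(list(one, other)), "different conditions")
})

test_that("reactant-level energies reproduce the multi-species table rows", {
  atp <- reactant("ATP", list(
    species("ATP4-", -2768.1, -4, 12),
    species("HATP3-", -2811.48, -3, 13),
    species("H2ATP2-", -2838.18, -2, 14)
  ))
  expect_equal(reactant_energy(atp, cond_yeast)$value, -2292.28, tolerance = 0.02)
  pi_r <- reactant("Pi", list(
    species("HPO4-2", -1096.1, -2, 1),
    species("H2PO4-", -1137.3, -1, 2)
  ))
  expect_equal(reactant_energy(pi_r, cond_yeast)$value, -1059.30, tolerance = 0.02)
  adp <- reactant("ADP", list(
    species("ADP3-", -1906.13, -3, 12),
    species("HADP2-", -1947.1, -2, 13),
    species("H2ADP1-", -1971.98, -1, 14)
  ))
  expect_equal(reactant_energy(adp, cond_yeast)$value, -1425.17, tolerance = 0.02)
  # single-species reactant collapses to the species transform
  glc <- reactant("Glucose", species("Glucose", -915.9, 0, 12))
  expect_equal(reactant_energy(glc, cond_yeast)$value,
               transform_species(glc$species[[1]], cond_yeast)$value)
})

test_that("reaction standard energies are stoichiometric sums with clear errors", {
  energies <- reactant_energies(glycolysis_species(), cond_yeast)
  model <- glycolysis_model()
  expect_equal(reaction_standard_dg(model[["HEX1"]], energies), -24.58,
               tolerance = 0.05)
  expect_equal(reaction_standard_dg(model[["PYK"]], energies), -29.08,
               tolerance = 0.05)
  # antisymmetry under reversal
  fwd <- parse_reaction_equation("Glucose + ATP = Glucose 6-phosphate + ADP")
  rev <- parse_reaction_equation("Glucose 6-phosphate + ADP = Glucose + ATP")
  expect_equal(reaction_standard_dg(fwd, energies),
               -reaction_standard_dg(rev, energies))
  expect_error(
    reaction_standard_dg(parse_reaction_equation("Glucose = Unobtainium"), energies),
    "Unobtainium"
  )
})

test_that("concentration-dependent reaction energy applies the log term correctly", {
  rt <- 8.31451e-3 * 298.15
  hex1 <- parse_reaction_equation("Glucose + ATP = Glucose 6-phosphate + ADP")
  conc1 <- c(Glucose = 1, ATP = 1, `Glucose 6-phosphate` = 1, ADP = 1)
  expect_equal(reaction_dg(hex1, -24.58, conc1, cond_yeast), -24.58)
  # 10 mM glucose, 1 mM G6P, ATP = ADP shifts by RT ln(0.1)
  conc2 <- c(Glucose = 1e-2, ATP = 1e-3, `Glucose 6-phosphate` = 1e-3, ADP = 1e-3)
  expect_equal(reaction_dg(hex1, -24.58, conc2, cond_yeast), -30.29,
               tolerance = 0.05)
  # equilibrium: mass-action ratio equal to exp(-dG0/RT) gives exactly zero
  ab <- parse_reaction_equation("A = B")
  dg0 <- -7.3
  conc_eq <- c(A = 1e-3, B = 1e-3 * exp(dg0 / -rt))
  expect_equal(reaction_dg(ab, dg0, conc_eq, cond_yeast), 0, tolerance = 1e-10)
  expect_error(reaction_dg(ab, dg0, c(A = 0, B = 1), cond_yeast), "nonpositive")
  # water activity is fixed at 1: its concentration is never consulted
  eno <- parse_reaction_equation("2-Phospho-glycerate = Phosphoenolpyruvate + H2O")
  expect_equal(
    reaction_dg(eno, -3.41, c(`2-Phospho-glycerate` = 1e-3,
                              Phosphoenolpyruvate = 1e-3), cond_yeast),
    -3.41
  )
})

test_that("uniform concentration scaling cancels for mass-balanced reactions", {
  rxn <- parse_reaction_equation("A + B = C + D")
  conc <- c(A = 2e-3, B = 5e-4, C = 1e-2, D = 3e-5)
  base <- reaction_dg(rxn, 5, conc, cond_yeast)
  for (f in c(0.1, 3, 50)) {
    expect_equal(reaction_dg(rxn, 5, conc * f, cond_yeast), base, tolerance = 1e-9)
  }
})

test_that("pathway energies are additive: lumped glycolysis equals the weighted sum", {
  energies <- reactant_energies(glycolysis_species(), cond_yeast)
  dg0 <- glycolysis_dg0(cond_yeast)
  v <- stats::setNames(dg0$dg0_kj_mol, dg0$id)
  # one glucose passes the top of the pathway once and the triose leg twice
  mult <- c(HEX1 = 1, PGI = 1, PFK = 1, FBA = 1, TPI = 1,
            GAPD = 2, PGK = 2, PGM = 2, ENO = 2, PYK = 2)
  lumped <- parse_reaction_equation(paste(
    "Glucose + 2 NAD + 2 ADP + 2 Pi =",
    "2 Pyruvate + 2 NADH + 2 ATP + 2 H2O"))
  expect_equal(sum(v[names(mult)] * mult),
               reaction_standard_dg(lumped, energies), tolerance = 1e-9)
})
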