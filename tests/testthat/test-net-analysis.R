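cond <- conditions(ph = 7, ionic_strength = 0.15)
RT <- 8.31451e-3 * 298.15

single_problem <- function(dg0, dir = "reversible", bounds = NULL, ...) {
  rxn <- reaction("R1", c(S = -1, P = 1), directionality = dir)
  net_problem(list(R1 = rxn), c(R1 = dg0), cond, bounds = bounds, ...)
}

test_that("problem construction enumerates concentration variables correctly", {
  dg0 <- glycolysis_dg0(cond)
  prob <- net_problem(glycolysis_model(), stats::setNames(dg0$dg0_kj_mol, dg0$id), cond)
  # 17 reactants in the model minus water, which carries no variable
  expect_length(prob$variables, 16)
  expect_false("H2O" %in% prob$variables)
  expect_identical(unique(prob$bounds$provenance), "default")
  p1 <- single_problem(5)
  expect_identical(check_feasibility(p1)$status, "feasible")
})

test_that("an over-constrained forward reaction is certified infeasible", {
  # S -> P with dG'0 = +50 and bounds [1e-6, 1e-1]: even the best
  # concentration ratio leaves dG' ~ +21.5, so the direction is impossible
  prob <- single_problem(50, dir = "forward_only",
                         bounds = data.frame(reactant = c("S", "P"),
                                             c_min = 1e-6, c_max = 1e-1))
  res <- check_feasibility(prob)
  expect_identical(res$status, "infeasible")
  expect_identical(res$certificate, "R1")
  rng <- dg_range(prob, "R1")
  expect_identical(rng$status, "infeasible")
})

test_that("a constant-energy reaction with an impossible sign fails immediately", {
  rxn <- reaction("waterworks", c(H2O = 1), directionality = "forward_only")
  prob <- net_problem(list(waterworks = rxn), c(waterworks = 12), cond)
  res <- check_feasibility(prob)
  expect_identical(res$status, "infeasible")
  expect_identical(res$certificate, "waterworks")
})

test_that("forward chains with negative standard energies are feasible", {
  m <- list(
    R1 = reaction("R1", c(A = -1, B = 1), "forward_only"),
    R2 = reaction("R2", c(B = -1, C = 1), "forward_only")
  )
  prob <- net_problem(m, c(R1 = -10, R2 = -10), cond)
  res <- check_feasibility(prob)
  expect_identical(res$status, "feasible")
  expect_length(res$certificate, 0)
  # the returned example point satisfies both directions
  for (id in names(m)) {
    dg <- reaction_dg(m[[id]], prob$dg0[[id]], res$example, cond)
    expect_lt(dg, 0)
  }
})

test_that("fixed concentrations collapse the Gibbs range to a point", {
  b <- data.frame(reactant = c("S", "P"), c_min = c(2e-3, 5e-4),
                  c_max = c(2e-3, 5e-4))
  prob <- single_problem(-3, bounds = b)
  rng <- dg_range(prob, "R1")
  expected <- -3 + RT * log(5e-4 / 2e-3)
  expect_equal(rng$dg_min, expected, tolerance = 1e-8)
  expect_equal(rng$dg_max, expected, tolerance = 1e-8)
})

test_that("the standard-state point lies inside an unconstrained range", {
  b <- data.frame(reactant = c("S", "P"), c_min = 0.5, c_max = 2)
  prob <- single_problem(4.2, bounds = b)
  rng <- dg_range(prob, "R1")
  expect_lte(rng$dg_min, 4.2)
  expect_gte(rng$dg_max, 4.2)
})

test_that("concentration ranges only tighten, and do tighten under constraints", {
  # no sign constraints: bounds come back unchanged
  prob <- single_problem(0)
  cr <- concentration_range(prob, "P")
  expect_equal(cr$c_min, 1e-6); expect_equal(cr$c_max, 5e-2)
  # S -> P forward with dG'0 = 0 and S pinned at 1 mM forces c_P < 1 mM
  b <- data.frame(reactant = "S", c_min = 1e-3, c_max = 1e-3)
  prob2 <- single_problem(0, dir = "forward_only", bounds = b)
  cr2 <- concentration_range(prob2, "P")
  expect_lt(cr2$c_max, 1e-3 + 1e-9)
  expect_gte(cr2$c_min, 1e-6 - 1e-12)
  all_ranges <- concentration_ranges(prob2)
  expect_identical(all_ranges$status, rep("feasible", 2))
})

test_that("adding a direction constraint never widens any range", {
  for (seed in 1:20) {
    toy <- generate_toy_network(4, 3, seed = 200 + seed, target_status = "feasible")
    base <- toy_net_problem(toy)
    dirs <- vapply(base$reactions, `[[`, character(1), "directionality")
    free <- names(dirs)[dirs == "reversible"]
    if (!length(free)) next
    tighter_rxns <- base$reactions
    rng0 <- dg_range(base, free[1])
    tighter_rxns[[free[1]]]$directionality <-
      if (rng0$dg_min < -1) "forward_only" else "backward_only"
    tight <- net_problem(tighter_rxns, base$dg0, base$conditions, bounds = toy$bounds)
    if (check_feasibility(tight)$status != "feasible") next
    r0 <- dg_ranges(base); r1 <- dg_ranges(tight)
    expect_true(all(r1$dg_min >= r0$dg_min - 1e-6))
    expect_true(all(r1$dg_max <= r0$dg_max + 1e-6))
    c0 <- concentration_ranges(base); c1 <- concentration_ranges(tight)
    expect_true(all(c1$c_min >= c0$c_min * (1 - 1e-9)))
    expect_true(all(c1$c_max <= c0$c_max * (1 + 1e-9)))
  }
})

test_that("directionality assignment fixes one-sided ranges and keeps feasibility", {
  # a reaction whose feasible range sits strictly below zero becomes forward
  b <- data.frame(reactant = c("S", "P"), c_min = c(1e-3, 4e-4), c_max = c(2e-3, 8e-4))
  prob <- single_problem(-1.6, bounds = b)
  rng <- dg_range(prob, "R1")
  expect_lt(rng$dg_max, 0) # range like the published [-2.2, -1.0] case
  out <- assign_directionality(prob)
  expect_identical(unname(out$directions["R1"]), "forward_only")
  expect_identical(check_feasibility(out$problem)$status, "feasible")
  # a range straddling zero stays reversible
  wide <- single_problem(0.5)
  expect_identical(unname(assign_directionality(wide)$directions["R1"]), "reversible")
})

test_that("input-irreversible reactions propagate onto reversible neighbours", {
  # R1 runs backward (B -> A net), which keeps the shared pool B above the
  # pinned A concentration; that floor on B pushes R2's whole range below
  # zero, so R2 is assigned forward even though its unconstrained range
  # straddles zero
  m <- list(
    R1 = reaction("R1", c(A = -1, B = 1), "backward_only"),
    R2 = reaction("R2", c(B = -1, C = 1), "reversible")
  )
  b <- data.frame(reactant = c("A", "C"), c_min = 1e-3, c_max = 1e-3)
  unconstrained <- net_problem(m["R2"], c(R2 = -1), cond, bounds = b)
  rng0 <- dg_range(unconstrained, "R2")
  expect_lt(rng0$dg_min, 0); expect_gt(rng0$dg_max, 0) # straddles alone
  prob <- net_problem(m, c(R1 = 0, R2 = -1), cond, bounds = b)
  out <- assign_directionality(prob)
  expect_identical(unname(out$directions["R2"]), "forward_only")
  expect_identical(unname(out$directions["R1"]), "backward_only")
  expect_identical(check_feasibility(out$problem)$status, "feasible")
})

test_that("regulatory-site flagging applies the strict -10 kJ/mol threshold", {
  point_problem <- function(dg0) {
    b <- data.frame(reactant = c("S", "P"), c_min = 1e-3, c_max = 1e-3)
    single_problem(dg0, bounds = b)
  }
  expect_identical(flag_regulatory_sites(point_problem(-12)), "R1")
  expect_identical(flag_regulatory_sites(point_problem(-5)), character(0))
  # exactly at the threshold: not flagged (strict inequality)
  expect_identical(flag_regulatory_sites(point_problem(-10)), character(0))
  expect_identical(flag_regulatory_sites(point_problem(-10.5), threshold = -11),
                   character(0))
})

test_that("cofactor-ratio bounds constrain the solution space", {
  m <- list(R1 = reaction("R1", c(NADH = -1, NAD = 1), "reversible"))
  ratio <- data.frame(a = "NADH", b = "NAD", lower = 0.1, upper = 0.1)
  prob <- net_problem(m, c(R1 = 0), cond, ratio_bounds = ratio)
  rng <- dg_range(prob, "R1")
  expected <- 0 + RT * log(1 / 0.1)
  expect_equal(rng$dg_min, expected, tolerance = 1e-6)
  expect_equal(rng$dg_max, expected, tolerance = 1e-6)
})

test_that("standard-energy uncertainty widens ranges by exactly the stated error", {
  b <- data.frame(reactant = c("S", "P"), c_min = 1e-3, c_max = 1e-3)
  exact <- single_problem(-4, bounds = b)
  fuzzy <- single_problem(-4, bounds = b, dg0_error = c(R1 = 2.5))
  r0 <- dg_range(exact, "R1"); r1 <- dg_range(fuzzy, "R1")
  expect_equal(r1$dg_min, r0$dg_min - 2.5, tolerance = 1e-8)
  expect_equal(r1$dg_max, r0$dg_max + 2.5, tolerance = 1e-8)
})

test_that("the glycolysis network is feasible under wide physiological bounds", {
  dg0 <- glycolysis_dg0(cond)
  prob <- net_problem(glycolysis_model(), stats::setNames(dg0$dg0_kj_mol, dg0$id), cond)
  expect_identical(check_feasibility(prob)$status, "feasible")
  # and it supports fully forward operation of the pathway
  fwd <- lapply(glycolysis_model(), function(r) {
    r$directionality <- "forward_only"; r
  })
  prob_fwd <- net_problem(fwd, stats::setNames(dg0$dg0_kj_mol, dg0$id), cond)
  expect_identical(check_feasibility(prob_fwd)$status, "feasible")
})

test_that("LP backends agree to within 1e-4 kJ/mol", {
  skip_if_not_installed("pracma")
  for (seed in c(3, 17, 31)) {
    toy <- generate_toy_network(4, 3, seed = seed, target_status = "feasible")
    prob <- toy_net_problem(toy)
    for (id in names(prob$reactions)) {
      a <- dg_range(prob, id, backend = "boot")
      b <- dg_range(prob, id, backend = "pracma")
      expect_equal(a$dg_min, b$dg_min, tolerance = 1e-4)
      expect_equal(a$dg_max, b$dg_max, tolerance = 1e-4)
    }
  }
})

test_that("identical inputs give identical results (determinism)", {
  toy <- generate_toy_network(4, 4, seed = 7, target_status = "feasible")
  p1 <- toy_net_problem(toy); p2 <- toy_net_problem(toy)
  expect_identical(dg_ranges(p1), dg_ranges(p2))
  expect_identical(check_feasibility(p1)$status, check_feasibility(p2)$status)
})

test_that("antiparallel reaction pairs are lumped into one reversible reaction", {
  m <- list(
    fwd = reaction("fwd", c(A = -1, B = 1), "forward_only"),
    rev = reaction("rev", c(B = -1, A = 1), "forward_only"),
    other = reaction("other", c(B = -1, C = 1), "reversible")
  )
  out <- lump_antiparallel_reactions(m)
  expect_named(out$model, c("fwd", "other"))
  expect_identical(out$model$fwd$directionality, "reversible")
  expect_identical(out$report$dropped, "rev")
  # nothing to lump: model passes through untouched
  none <- lump_antiparallel_reactions(m["other"])
  expect_identical(names(none$model), "other")
  expect_equal(nrow(none$report), 0)
})

test_that("tagged carbon dioxide species pool into CO2tot with water rebalancing", {
  m <- list(R1 = reaction("R1", c(Pyruvate = -1, `HCO3-` = -1, X = 1), "reversible"),
            R2 = reaction("R2", c(A = -1, B = 1), "reversible"))
  out <- group_co2_reactant(m)
  expect_equal(out$model$R1$stoichiometry,
               c(Pyruvate = -1, X = 1, CO2tot = -1, H2O = -1))
  expect_identical(out$model$R2$stoichiometry, m$R2$stoichiometry)
  expect_identical(out$report$reaction, "R1")
})
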