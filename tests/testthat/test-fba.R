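test_that("FBA optimum equals brute-force vertex enumeration on small polytopes", {
  cases <- list(
    list(model = toy_two_route_model(), objective = "DRAIN",
         direction = "max"),
    list(model = toy_diamond_model(), objective = "R2", direction = "max"),
    list(model = toy_diamond_model(), objective = "EX_p",
         direction = "max"),
    list(model = toy_reversible_model(), objective = "EX_b",
         direction = "max"),
    list(model = toy_reversible_model(), objective = "EX_b",
         direction = "min"),
    list(model = toy_onedof_model(), objective = "CONV",
         direction = "max"))
  for (cs in cases) {
    oracle <- enumerate_lp_optimum(cs$model, cs$objective, cs$direction)
    fd <- solve_fba(cs$model, objective = cs$objective,
                    direction = cs$direction)
    expect_equal(fd$status, "optimal", info = cs$model$metadata$name)
    expect_equal(fd$objective_value, oracle, tolerance = 1e-9,
                 info = paste(cs$model$metadata$name, cs$objective,
                              cs$direction))
  }
})

test_that("hand-computable two-route optimum is recovered", {
  # 1 unit substrate, best route yields 2 ATP: DRAIN optimum = 2
  fd <- solve_fba(toy_two_route_model(), objective = "DRAIN")
  expect_equal(fd$objective_value, 2, tolerance = 1e-9)
  expect_equal(unname(fd$fluxes[["R_hi"]]), 1, tolerance = 1e-9)
})

test_that("FBA reports infeasibility and unboundedness honestly", {
  # forced uptake with no consumer
  mets <- list(metabolite("a_e", compartment = "extracellular",
                          carbon_atoms = 1))
  m <- metabolic_model(mets, list(reaction("EX_a", c(a_e = -1), -1, -1,
                                           is_exchange = TRUE)),
                       metadata = list(name = "stuck", version = "1"))
  fd <- solve_fba(m, objective = "EX_a")
  expect_equal(fd$status, "infeasible")
  expect_null(fd$fluxes)
  # free internal loop with an infinite bound
  mets2 <- list(metabolite("a", carbon_atoms = 1),
                metabolite("b", carbon_atoms = 1))
  m2 <- metabolic_model(mets2,
                        list(reaction("F", c(a = -1, b = 1), 0, Inf),
                             reaction("B", c(b = -1, a = 1), 0, Inf)),
                        metadata = list(name = "loop", version = "1"))
  expect_equal(solve_fba(m2, objective = "F")$status, "unbounded")
})

test_that("no carbon means no growth", {
  m <- build_core_model()   # carbon exchanges are closed by default
  fd <- solve_fba(m, objective = "BIOMASS")
  expect_equal(fd$status, "optimal")
  expect_equal(fd$objective_value, 0, tolerance = 1e-9)
})

test_that("optimal flux distributions satisfy mass and carbon conservation", {
  m <- build_core_model()
  m <- set_bounds(m, "EX_fru", -1, -1)
  m <- set_po_mode(m, "high")
  fd <- solve_fba(m, objective = "BIOMASS")
  S <- build_stoichiometric_matrix(m)
  expect_lt(max(abs(S %*% fd$fluxes)), 1e-6)
  expect_lt(abs(flux_carbon_balance(m, fd)), 1e-6)
})

test_that("P/O mode switching closes the right oxidase class", {
  hi <- set_po_mode(build_core_model(), "high")
  expect_equal(hi$reactions[["CYTBD"]]$upper_bound, 0)
  expect_equal(hi$reactions[["CYTBO"]]$upper_bound, 0)
  expect_gt(hi$reactions[["CYTCO"]]$upper_bound, 0)
  lo <- set_po_mode(build_core_model(), "low")
  expect_equal(lo$reactions[["CYTCO"]]$upper_bound, 0)
  expect_gt(lo$reactions[["CYTBD"]]$upper_bound, 0)
  # the original model is untouched
  expect_gt(build_core_model()$reactions[["CYTBD"]]$upper_bound, 0)
  expect_error(set_po_mode(toy_chain_model(), "high"), "oxidase")
})

test_that("measured P/O ratio is 2.5 (cytochrome-c) and 1.5 (ubiquinol)", {
  expect_equal(measure_po_ratio(po_mode = "high")$po, 2.5,
               tolerance = 1e-9)
  expect_equal(measure_po_ratio(po_mode = "low")$po, 1.5,
               tolerance = 1e-9)
})

test_that("alginate yields: ceilings, P/O ordering and glycerol P/O-independence", {
  m <- build_core_model()
  y_f_hi <- theoretical_alginate_yield(m, "fructose", "high")
  y_f_lo <- theoretical_alginate_yield(m, "fructose", "low")
  y_g_hi <- theoretical_alginate_yield(m, "glycerol", "high")
  y_g_lo <- theoretical_alginate_yield(m, "glycerol", "low")
  # carbon stoichiometric ceilings: 6C monomer from 6C / 3C substrate
  expect_lte(y_f_hi, 1 + 1e-9)
  expect_lte(y_g_hi, 0.5 + 1e-9)
  # glycerol yield does not depend on the oxidase branch
  expect_equal(y_g_hi, y_g_lo, tolerance = 1e-6)
  # fructose yield is strictly better with the efficient oxidase
  expect_gt(y_f_hi, y_f_lo)
})

test_that("alginate yield does not increase when the pathway ATP cost grows", {
  m <- build_core_model()
  base <- theoretical_alginate_yield(m, "fructose", "low")
  costly <- m
  st <- costly$reactions[["ALGE"]]$stoichiometry
  st[c("atp", "h2o")] <- -1
  st[c("adp", "pi")] <- 1
  costly$reactions[["ALGE"]]$stoichiometry <- st
  expect_lte(theoretical_alginate_yield(costly, "fructose", "low"), base)
  expect_lt(theoretical_alginate_yield(costly, "fructose", "low"), base)
})

test_that("biomass yields respect the P/O ordering and decrease with NGAM", {
  m <- build_core_model()
  y_hi <- theoretical_biomass_yield(m, "fructose", "high")
  y_lo <- theoretical_biomass_yield(m, "fructose", "low")
  expect_gte(y_hi, y_lo)
  grid <- yield_vs_po_curve(m, sources = "fructose", po_modes = "high",
                            ngam_grid = c(0, 1.5, 3, 5))
  expect_true(all(diff(grid$biomass_yield) <= 1e-9))
  # single-point grid agrees with the direct call
  expect_equal(grid$biomass_yield[1], y_hi)
  expect_equal(grid$alginate_yield[1],
               theoretical_alginate_yield(m, "fructose", "high"))
  # NGAM at the full ATP capacity of the substrate leaves nothing to grow on
  probe <- set_po_mode(m, "high")
  probe <- set_bounds(probe, "EX_fru", -1, -1)
  cap <- solve_fba(probe, objective = "ATPM")$objective_value
  y0 <- theoretical_biomass_yield(m, "fructose", "high",
                                  energy_params(ngam = cap))
  expect_equal(unname(y0), 0, tolerance = 1e-6)
})

test_that("the NGAM drop at fixed growth rate is positive and finite", {
  m <- build_core_model()
  y0 <- theoretical_biomass_yield(m, "fructose", "high",
                                  energy_params(ngam = 0))
  y1 <- theoretical_biomass_yield(m, "fructose", "high",
                                  energy_params(ngam = 1.5))
  expect_gt(y0, y1)
  expect_lt(y0 - y1, 0.2)
})
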