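test_that("constructors enforce the type invariants", {
  expect_error(metabolite("x", carbon_atoms = -1), "non-negative")
  expect_error(metabolite("glc", carbon_atoms = 5, formula = "C6H12O6"),
               "implies 6 carbon")
  expect_error(reaction("r", c(a = -1, b = 1), 1, 0), "exceeds")
  expect_error(reaction("ex", c(a = -1, b = 1), is_exchange = TRUE),
               "exactly one metabolite")
  mets <- list(metabolite("a", carbon_atoms = 1),
               metabolite("a", carbon_atoms = 1))
  expect_error(metabolic_model(mets, list(reaction("r", c(a = -1), 0, 1))),
               "duplicate metabolite ids")
  expect_error(
    metabolic_model(list(metabolite("a", carbon_atoms = 1)),
                    list(reaction("r", c(a = -1, ghost = 1), 0, 1))),
    "undefined metabolites")
})

test_that("stoichiometric matrix matches the reaction definitions", {
  m <- toy_chain_model(with_c_exchange = TRUE)
  S <- build_stoichiometric_matrix(m)
  expect_equal(dim(S), c(3L, 4L))
  expect_equal(unname(S[, "R1"]), c(-1, 1, 0))
  expect_equal(unname(S[, "R2"]), c(0, -1, 1))
  # empty model
  empty <- metabolic_model(list(), list(),
                           metadata = list(name = "empty", version = "0"))
  expect_equal(dim(build_stoichiometric_matrix(empty)), c(0L, 0L))
  # core model: carbon-weighted column sums vanish for non-exchange columns
  core <- build_core_model()
  Sc <- build_stoichiometric_matrix(core)
  carbon <- vapply(core$metabolites, `[[`, 0, "carbon_atoms")
  wsum <- as.vector(carbon[rownames(Sc)] %*% Sc)
  names(wsum) <- colnames(Sc)
  non_ex <- !vapply(core$reactions, `[[`, FALSE, "is_exchange")
  expect_lt(max(abs(wsum[non_ex])), 1e-9)
})

test_that("carbon balance checker reports imbalance, exemptions and unknowns", {
  mets <- list(metabolite("a", carbon_atoms = 3),
               metabolite("b", carbon_atoms = 2),
               metabolite("x_e", compartment = "extracellular",
                          carbon_atoms = 6))
  rxns <- list(reaction("BAD", c(a = -1, b = 1), 0, 1),
               reaction("EX_x", c(x_e = -1), -1, 1, is_exchange = TRUE))
  m <- metabolic_model(mets, rxns, validate = FALSE)
  cb <- check_elemental_balance(m)
  expect_equal(cb$imbalanced$reaction_id, "BAD")
  expect_equal(cb$imbalanced$imbalance, -1)
  expect_equal(cb$exempt, "EX_x")
  # missing composition is explicit, not a silent pass
  m$metabolites[["a"]]$carbon_atoms <- NA_real_
  cb2 <- check_elemental_balance(m)
  expect_true("BAD" %in% cb2$unknown$reaction_id)
  # the packaged core model is clean
  expect_equal(nrow(check_elemental_balance(build_core_model())$imbalanced),
               0L)
})

test_that("dead-end detection is reversibility- and exchange-aware", {
  expect_equal(find_dead_end_metabolites(toy_chain_model()), "c")
  expect_equal(find_dead_end_metabolites(toy_chain_model(TRUE)),
               character(0))
  expect_equal(find_dead_end_metabolites(build_core_model()), character(0))
})

test_that("equation parser and formatter agree", {
  p <- parse_equation("2 a + b -> c")
  expect_equal(p$stoichiometry, c(a = -2, b = -1, c = 1))
  expect_false(p$reversible)
  expect_true(parse_equation("a <=> b")$reversible)
  expect_equal(format_equation(c(a = -2, b = -1, c = 1)), "2 a + b -> c")
  expect_error(parse_equation("a b c"), "arrow")
})

test_that("tsv save/load round trip is bit-exact", {
  m <- toy_two_route_model()
  # throw awkward coefficients at the writer
  m$reactions[["R_hi"]]$stoichiometry[["atp"]] <- 1 / 3
  m$reactions[["R_hi"]]$stoichiometry[["adp"]] <- -1 / 3
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_tsv(m, path)
  m2 <- read_model_tsv(path, validate = FALSE)
  expect_identical(build_stoichiometric_matrix(m),
                   build_stoichiometric_matrix(m2))
  expect_identical(vapply(m$reactions, `[[`, 0, "lower_bound"),
                   vapply(m2$reactions, `[[`, 0, "lower_bound"))
  expect_identical(vapply(m$reactions, `[[`, 0, "upper_bound"),
                   vapply(m2$reactions, `[[`, 0, "upper_bound"))
  expect_length(validate_model(m2, stop_on_error = FALSE), 0L)
  # empty reaction list loads as an empty model
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# mucaflux model tsv v1", "# metabolites", "# reactions"),
             p2)
  e <- read_model_tsv(p2)
  expect_equal(length(e$reactions), 0L)
  expect_equal(length(e$metabolites), 0L)
})

test_that("malformed tsv input fails with the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# mucaflux model tsv v1", "# reactions",
               "r1\ta -> b\tzero\t10\t\t"), path)
  expect_error(read_model_tsv(path), "line 3.*non-numeric bounds")
  expect_error(read_model_tsv(withr::local_tempfile(fileext = ".tsv")),
               "not found")
})

test_that("SBML write/read preserves the model", {
  m <- build_core_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(m, path)
  m2 <- read_model_sbml(path)
  expect_identical(build_stoichiometric_matrix(m),
                   build_stoichiometric_matrix(m2))
  expect_identical(vapply(m$reactions, `[[`, "", "gpr"),
                   vapply(m2$reactions, `[[`, "", "gpr"))
  expect_identical(vapply(m$reactions, `[[`, FALSE, "is_exchange"),
                   vapply(m2$reactions, `[[`, FALSE, "is_exchange"))
  expect_identical(vapply(m$metabolites, `[[`, 0, "carbon_atoms"),
                   vapply(m2$metabolites, `[[`, 0, "carbon_atoms"))
  expect_error(read_model_sbml(withr::local_tempfile(fileext = ".xml")),
               "not found")
})

test_that("packaged core model file matches its manifest and the builder", {
  path <- system.file("extdata", "core_model.tsv", package = "mucaflux")
  manifest <- jsonlite::read_json(
    system.file("extdata", "core_model_manifest.json",
                package = "mucaflux"))
  m <- load_model(path, "tsv")
  expect_equal(length(m$reactions), manifest$n_reactions)
  expect_equal(length(m$metabolites), manifest$n_metabolites)
  expect_length(validate_model(m, stop_on_error = FALSE), 0L)
  expect_identical(build_stoichiometric_matrix(m),
                   build_stoichiometric_matrix(build_core_model()))
})

test_that("core model has no 6-phosphofructokinase", {
  m <- build_core_model()
  pfk_like <- Filter(function(r) {
    st <- r$stoichiometry
    all(c("f6p", "atp", "fbp") %in% names(st)) &&
      st[["f6p"]] < 0 && st[["atp"]] < 0 && st[["fbp"]] > 0
  }, m$reactions)
  expect_length(pfk_like, 0L)
})

test_that("the four NADPH-cycle reactions sum to NADPH + H+ + 1/2 O2 -> H2O + NADP+", {
  m <- build_core_model()
  S <- build_stoichiometric_matrix(m)
  net <- rowSums(S[, c("AATB", "KATB", "GDHA", "NADB")])
  expected <- c(nadph = -1, h = -1, o2 = -0.5, nadp = 1, h2o = 1)
  expect_equal(net[names(expected)], expected)
  expect_equal(sum(abs(net)), sum(abs(expected)))  # and nothing else
})

test_that("alginate pathway cost is 3 high-energy bonds and 2 NAD+ per monomer", {
  cost <- alginate_pathway_cost(source = "fructose")
  expect_equal(cost$phosphate_bonds, 3)
  expect_equal(cost$nad_reduced, 2)
  cost_g <- alginate_pathway_cost(source = "glycerol")
  expect_equal(cost_g$phosphate_bonds, 3)
  expect_equal(cost_g$nad_reduced, 2)
})

test_that("GPR parsing handles precedence, parentheses and errors", {
  expect_null(parse_gpr(""))
  expect_equal(parse_gpr("geneA"), "geneA")
  tree <- parse_gpr("a and b or c")
  expect_equal(tree$op, "or")
  expect_equal(tree$args[[1]]$op, "and")
  expect_equal(sort(gpr_genes("(a and b) or (c and d)")),
               c("a", "b", "c", "d"))
  expect_error(parse_gpr("a and (b or c"), "unbalanced")
  expect_error(parse_gpr("a and or b"), "unexpected token")
})
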