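test_that("one-dof flux is uniform on the uptake window", {
  m <- toy_onedof_model(0.9, 1.1)
  s <- sample_flux_space(m, n_samples = 400, seed = 5)
  conv <- s$samples[, "CONV"]
  expect_true(all(conv >= 0.9 - 1e-9 & conv <= 1.1 + 1e-9))
  ks <- suppressWarnings(stats::ks.test(conv, "punif", 0.9, 1.1))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampling is deterministic given the seed and seed is mandatory", {
  m <- toy_onedof_model()
  a <- sample_flux_space(m, n_samples = 50, seed = 3)
  b <- sample_flux_space(m, n_samples = 50, seed = 3)
  expect_identical(a$samples, b$samples)
  c_ <- sample_flux_space(m, n_samples = 50, seed = 4)
  expect_false(identical(a$samples, c_$samples))
  expect_error(sample_flux_space(m, n_samples = 10), "seed")
})

test_that("every sample satisfies the steady-state constraint and bounds", {
  m <- build_core_model()
  cts <- list(exchange_constraint("EX_fru", -9.4, 0.05, unit = "mmolC"),
              exchange_constraint("EX_co2", 7.5, 0.05, unit = "mmolC"),
              exchange_constraint("BIOMASS", 0.04, 0.05))
  s <- sample_flux_space(m, cts, n_samples = 100, seed = 2)
  S <- build_stoichiometric_matrix(m)
  resid <- abs(S %*% t(s$samples))
  expect_lt(max(resid), 1e-6)
  lb <- vapply(m$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(m$reactions, `[[`, 0, "upper_bound")
  lb["EX_fru"] <- -9.4 / 6 * 1.05; ub["EX_fru"] <- -9.4 / 6 * 0.95
  for (j in seq_along(lb)) {
    expect_true(all(s$samples[, j] >= lb[j] - 1e-7 &
                    s$samples[, j] <= ub[j] + 1e-7))
  }
})

test_that("infeasible constraint windows fail loudly", {
  m <- toy_onedof_model()
  cts <- list(exchange_constraint("EX_s", -5, 0.01),
              exchange_constraint("EX_p", 1, 0.01))
  expect_error(sample_flux_space(m, cts, n_samples = 10, seed = 1),
               "empty")
})

test_that("flux-change probabilities: ties, separation and null behaviour", {
  m <- toy_onedof_model()
  a <- sample_flux_space(m, n_samples = 300, seed = 9)
  # identical sets: all ties -> 1/2
  expect_equal(unname(flux_change_probability(a, a)),
               rep(0.5, length(a$reaction_ids)))
  # doubled uptake window: disjoint flux intervals -> P+ = 1 on the chain
  m_hi <- toy_onedof_model(1.8, 2.2)
  b <- sample_flux_space(m_hi, n_samples = 300, seed = 10)
  p <- flux_change_probability(a, b)
  expect_equal(unname(p[c("CONV", "EX_p")]), c(1, 1))
  expect_equal(unname(p[["EX_s"]]), 0)  # more uptake = more negative
  # independent identical conditions: P+ near 1/2 within 3 binomial sigmas
  a2 <- sample_flux_space(m, n_samples = 300, seed = 11)
  p0 <- flux_change_probability(a, a2)
  expect_lt(max(abs(p0 - 0.5)), 3 * sqrt(0.25 / 300))
  # mismatched sample sets are rejected
  short <- sample_flux_space(m, n_samples = 10, seed = 1)
  expect_error(flux_change_probability(a, short), "same number")
})

test_that("doubling the sample count moves P+ by less than 3 binomial sigmas", {
  m <- toy_onedof_model()
  m2 <- toy_onedof_model(0.95, 1.3)
  p_small <- flux_change_probability(
    sample_flux_space(m, n_samples = 500, seed = 21),
    sample_flux_space(m2, n_samples = 500, seed = 22))
  p_big <- flux_change_probability(
    sample_flux_space(m, n_samples = 1000, seed = 23),
    sample_flux_space(m2, n_samples = 1000, seed = 24))
  expect_lt(max(abs(p_big - p_small)), 3 * sqrt(0.25 / 500))
})

test_that("evidence scores quantify concordance", {
  expect_equal(evidence_score(1, 1.5, TRUE), 1)
  expect_equal(evidence_score(1, -1.5, TRUE), 0)
  expect_equal(evidence_score(0.5, 2, TRUE), 0.5)
  expect_equal(evidence_score(0.5, -2, TRUE), 0.5)
  expect_equal(evidence_score(0.99, 3, FALSE), 0)
  expect_warning(s <- evidence_score(0.8, 0, TRUE), "zero expression")
  expect_equal(s, 0)
  expect_error(evidence_score(1.2, 1, TRUE), "\\[0, 1\\]")
})

test_that("regulation calls are mutually exclusive and threshold-driven", {
  tab <- data.frame(
    reaction_id = c("t", "m", "p", "n"),
    p_plus = c(0.97, 0.95, 0.03, 0.6),
    d_expression = c(1.2, 0.05, 1.5, 0.3),
    significant = c(TRUE, FALSE, TRUE, TRUE))
  tab$score <- evidence_score(tab$p_plus, tab$d_expression, tab$significant)
  calls <- classify_regulation(tab)
  expect_equal(calls, c("transcriptional", "metabolic",
                        "post-transcriptional", "none"))
  expect_error(classify_regulation(tab, score_hi = 0.4), "\\(0.5, 1\\]")
})

test_that("ranking is deterministic with documented tie-breaks", {
  tab <- data.frame(
    reaction_id = c("b", "a", "c", "d"),
    p_plus = c(0.5, 0.5, 1, 0.5),
    d_expression = c(0.2, 0.2, 2, 0.9),
    significant = c(TRUE, TRUE, TRUE, TRUE))
  tab$score <- evidence_score(tab$p_plus, tab$d_expression, tab$significant)
  ranked <- rank_reactions(tab)
  expect_equal(ranked$reaction_id, c("c", "d", "a", "b"))
  expect_equal(ranked$rank, 1:4)
  # all-zero scores fall back to id order
  tab0 <- data.frame(reaction_id = c("z", "y", "x"), p_plus = 0.5,
                     d_expression = 0, significant = FALSE, score = 0)
  expect_equal(rank_reactions(tab0)$reaction_id, c("x", "y", "z"))
})

test_that("rank-based AUROC agrees with an independent ROC implementation", {
  set.seed(6)
  truth <- rep(c(TRUE, FALSE), c(8, 40))
  score <- c(runif(8, 0.4, 1), runif(40, 0, 0.8))
  ours <- score_auroc(score, truth)
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth,
                                        predictor = score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("alginate-pathway reactions dominate the WT-vs-mucA ranking", {
  study <- generate_two_condition_study()
  tab <- score_two_condition_study(study, n_samples = 400, seed = 8)
  alg <- names(which(study$truth))
  top <- tab$reaction_id[seq_along(alg)]
  expect_setequal(top, alg)
  expect_true(all(tab$score[tab$reaction_id %in% alg] > 0.9))
})

test_that("NADPH-cycle down-regulation scores concordantly in WT-vs-double-mutant", {
  m <- build_core_model()
  study <- generate_two_condition_study(
    m,
    cond_a = c(uptake_c = 9.4, co2_c = 7.5, alginate_c = 0, mu = 0.04),
    cond_b = c(uptake_c = 5.8, co2_c = 4.3, alginate_c = 0, mu = 0.04),
    regulated = c(AATB = -1.2, KATB = -1.1, GDHA = -1.3, NADB = -1.2),
    seed = 4)
  tab <- score_two_condition_study(study, n_samples = 600, seed = 12)
  cyc <- tab[tab$reaction_id %in% c("AATB", "KATB", "GDHA", "NADB"), ]
  # the cycle can only shrink in the low-uptake condition: flux-change
  # probabilities lean down, so the down-regulation scores are concordant
  expect_true(all(cyc$p_plus < 0.5))
  expect_true(all(cyc$score > 0.5))
})
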