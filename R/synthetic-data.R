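# Synthetic-data generators with known ground truth. They emulate the study
# layout the analysis modules expect — triplicate chemostats of five strains
# on two carbon sources, a ~6,500-gene array with an up-regulated alginate
# operon and a down-regulated NADPH cycle — so every pipeline stage can be
# exercised end-to-end without external downloads. All generators are pure
# functions of (parameters, seed).

#' Study design for the synthetic generators
#'
#' Defaults mirror the chemostat study layout: five strains (wild-type,
#' an algC deletion, the alginate-overproducing mucA strain and its two
#' non-producing mucA-background controls), two carbon sources, triplicate
#' cultivations and a 6,519-gene array.
#'
#' @param strains Condition labels.
#' @param carbon_sources Carbon sources.
#' @param replicates Replicate chemostats per condition (>= 2).
#' @param n_genes Number of genes on the array.
#' @param seed Integer seed.
#' @return List of class `"study_design"`.
#' @export
study_design <- function(strains = c("wild-type", "dalgC", "mucA",
                                     "mucA_dalgC", "mucA_TTalgD"),
                         carbon_sources = c("fructose", "glycerol"),
                         replicates = 3, n_genes = 6519, seed = 1) {
  if (replicates < 2) stop("replicates must be >= 2")
  structure(list(strains = strains, carbon_sources = carbon_sources,
                 replicates = replicates, n_genes = n_genes, seed = seed),
            class = "study_design")
}

# gene inventory: named model genes first, anonymous filler genes after
.design_genes <- function(design) {
  named <- unique(unlist(lapply(build_core_model()$reactions,
                                function(r) gpr_genes(r$gpr))))
  if (design$n_genes < length(named)) {
    stop("n_genes must be >= ", length(named), " (the modeled genes)")
  }
  c(named, sprintf("gene%04d", seq_len(design$n_genes - length(named))))
}

ALG_OPERON_GENES <- c("algD", "alg8", "alg44", "algE", "algG", "algX",
                      "algL", "algI", "algJ", "algF", "algA", "algC")
NADPH_CYCLE_GENES <- c("aatB", "katB", "gdhA", "nadB")

#' Default regulated gene sets
#'
#' The alginate operon (plus algC) is up 1 log2 unit in every
#' mucA-background strain; the NADPH-cycle genes are down 1 log2 unit in
#' mucA backgrounds grown on fructose.
#'
#' @param design A [study_design()].
#' @return Data frame with `gene`, `strain`, `carbon_source`, `effect`
#'   (log2 units), one row per regulated gene x condition.
#' @export
default_regulated_sets <- function(design = study_design()) {
  muca <- grep("^mucA", design$strains, value = TRUE)
  up <- expand.grid(gene = ALG_OPERON_GENES, strain = muca,
                    carbon_source = design$carbon_sources,
                    stringsAsFactors = FALSE)
  up$effect <- 1
  down <- expand.grid(gene = NADPH_CYCLE_GENES, strain = muca,
                      carbon_source = "fructose",
                      stringsAsFactors = FALSE)
  down$effect <- -1
  rbind(up, down)
}

#' Generate a synthetic expression matrix with known effects
#'
#' Intensities follow a log-normal model: log2 x = baseline(gene) +
#' effect(gene, condition) + N(0, noise_sd), with gene baselines drawn once
#' per seed from N(8, 2) in log2 units.
#'
#' @param design A [study_design()].
#' @param regulated_sets Data frame (`gene`, `strain`, `carbon_source`,
#'   `effect`) of true log2 effects; defaults to [default_regulated_sets()].
#' @param noise_sd Replicate noise in log2 units (> 0; default 0.5).
#' @param seed Integer seed; defaults to the design's.
#' @return List with `expression` (an [expression_matrix()]) and `truth`
#'   (the effect table actually applied).
#' @export
generate_expression <- function(design = study_design(),
                                regulated_sets = default_regulated_sets(design),
                                noise_sd = 0.5, seed = design$seed) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  genes <- .design_genes(design)
  unknown <- setdiff(regulated_sets$gene, genes)
  if (length(unknown)) {
    stop("regulated_sets contains genes outside the design: ",
         paste(unknown, collapse = ", "))
  }
  conditions <- expand.grid(strain = design$strains,
                            carbon_source = design$carbon_sources,
                            stringsAsFactors = FALSE)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  baseline <- stats::setNames(stats::rnorm(length(genes), 8, 2), genes)
  n_cond <- nrow(conditions)
  cols <- n_cond * design$replicates
  lmat <- matrix(NA_real_, length(genes), cols)
  sample_ids <- character(cols)
  groups <- character(cols)
  k <- 0L
  for (i in seq_len(n_cond)) {
    eff <- stats::setNames(rep(0, length(genes)), genes)
    hit <- regulated_sets$strain == conditions$strain[i] &
      regulated_sets$carbon_source == conditions$carbon_source[i]
    if (any(hit)) {
      eff[regulated_sets$gene[hit]] <- regulated_sets$effect[hit]
    }
    for (rep_ in seq_len(design$replicates)) {
      k <- k + 1L
      lmat[, k] <- baseline + eff +
        stats::rnorm(length(genes), 0, noise_sd)
      sample_ids[k] <- paste(conditions$strain[i],
                             conditions$carbon_source[i], rep_, sep = ".")
      groups[k] <- paste(conditions$strain[i], conditions$carbon_source[i],
                         sep = ".")
    }
  }
  dimnames(lmat) <- list(genes, sample_ids)
  list(expression = expression_matrix(2^lmat, groups),
       truth = regulated_sets)
}

#' Noiseless "true" chemostat fluxes for the synthetic study
#'
#' Channel values mirror the magnitudes of the real steady states, but the
#' uptake is set to the exact sum of the product channels so the noiseless
#' carbon balance is 100 percent, and the acetyl channel follows the
#' measured acetylation degrees (0.19 on fructose, 0.32 on glycerol; acetyl
#' carries 2 C against the 6 C monomer).
#'
#' @return Data frame in the chemostat-table layout.
#' @export
default_true_fluxes <- function() {
  base <- data.frame(
    strain = c("wild-type", "mucA", "dalgC", "mucA_dalgC", "mucA_TTalgD",
               "wild-type", "mucA", "mucA_TTalgD"),
    carbon_source = c(rep("fructose", 5), rep("glycerol", 3)),
    dilution_rate = 0.04,
    od660 = c(7.8, 7.0, 8.1, 8.4, 9.2, 9.2, 7.4, 9.9),
    q_alginate = c(0, 12.3, 0, 0, 0, 0, 10.6, 0),
    q_co2 = c(7.5, 4.6, 7.4, 4.3, 3.9, 6.4, 3.6, 5.0),
    q_biomass_c = 1.51,
    stringsAsFactors = FALSE)
  degree <- ifelse(base$carbon_source == "fructose", 0.19, 0.32)
  base$q_acetyl <- base$q_alginate * degree * 2 / 6
  base$q_uptake <- base$q_alginate + base$q_acetyl + base$q_co2 +
    base$q_biomass_c
  base[, c("strain", "carbon_source", "dilution_rate", "od660", "q_uptake",
           "q_alginate", "q_acetyl", "q_co2", "q_biomass_c")]
}

#' Generate noisy chemostat measurements
#'
#' Applies unbiased multiplicative noise, factor `1 + rel_noise * N(0, 1)`,
#' independently to every measured channel of a noiseless flux table.
#'
#' @param true_fluxes Noiseless table (default [default_true_fluxes()]);
#'   its carbon balances must be 100 percent.
#' @param rel_noise Relative noise level (>= 0).
#' @param seed Integer seed.
#' @return A `chemostat_table` data frame.
#' @export
generate_chemostat_measurements <- function(true_fluxes =
                                              default_true_fluxes(),
                                            rel_noise = 0.03, seed = 1) {
  if (rel_noise < 0) stop("rel_noise must be >= 0")
  out <- true_fluxes
  channels <- c("od660", "q_uptake", "q_alginate", "q_acetyl", "q_co2",
                "q_biomass_c")
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  for (ch in channels) {
    noise <- 1 + rel_noise * stats::rnorm(nrow(out))
    out[[ch]] <- pmax(out[[ch]] * noise, 0)
  }
  class(out) <- c("chemostat_table", "data.frame")
  out
}

#' Generate a two-condition flux + expression study with ground truth
#'
#' Builds exchange-constraint sets for a reference condition A and a test
#' condition B on the core model (defaults mirror the wild-type and the
#' alginate-overproducing strain on fructose: uptake, CO2, alginate and
#' growth windows at +/- 5 percent), a reaction-level expression table in
#' which the truly regulated reactions carry significant changes concordant
#' with the constructed flux change while all decoys are null, and the
#' ground-truth labels.
#'
#' @param model A `metabolic_model` (default [build_core_model()]).
#' @param cond_a,cond_b Named numeric vectors of measured exchange fluxes in
#'   mmolC/gDW/h: `uptake_c`, `co2_c`, `alginate_c`, plus `mu` (1/h).
#' @param regulated Named numeric vector: truly regulated reaction ids ->
#'   log2 expression effect (sign concordant with the A -> B flux change).
#' @param rel_tol Constraint window half-width (default 0.05).
#' @param seed Integer seed (used for the decoy expression noise).
#' @param null_study Make condition B identical to A and zero out all
#'   expression effects (null control).
#' @return List with `constraints_a`, `constraints_b`, `expression`
#'   (reaction-level table: `reaction_id`, `d_expression`, `significant`),
#'   `truth` (logical vector per reaction) and `model`.
#' @export
generate_two_condition_study <- function(model = build_core_model(),
                                         cond_a = c(uptake_c = 9.4,
                                                    co2_c = 7.5,
                                                    alginate_c = 0,
                                                    mu = 0.04),
                                         cond_b = c(uptake_c = 18.3,
                                                    co2_c = 4.6,
                                                    alginate_c = 12.3,
                                                    mu = 0.04),
                                         regulated = c(PMI = 1.2, PMM = 1.2,
                                                       GMPP = 1.2, GMD = 1.4,
                                                       ALGE = 1.3),
                                         rel_tol = 0.05, seed = 1,
                                         null_study = FALSE) {
  if (null_study) {
    cond_b <- cond_a
    regulated <- regulated[0]
  }
  build_constraints <- function(cond) {
    cts <- list(
      exchange_constraint("EX_fru", -cond[["uptake_c"]], rel_tol,
                          unit = "mmolC"),
      exchange_constraint("EX_co2", cond[["co2_c"]], rel_tol,
                          unit = "mmolC"),
      exchange_constraint("BIOMASS", cond[["mu"]], rel_tol),
      exchange_constraint("EX_algMac", 0, 0))
    if (cond[["alginate_c"]] > 0) {
      cts <- c(cts, list(exchange_constraint("EX_algM",
                                             cond[["alginate_c"]], rel_tol,
                                             unit = "mmolC")))
    } else {
      cts <- c(cts, list(exchange_constraint("EX_algM", 0, 0)))
    }
    cts
  }
  constraints_a <- build_constraints(cond_a)
  constraints_b <- build_constraints(cond_b)
  unknown <- setdiff(names(regulated), names(model$reactions))
  if (length(unknown)) {
    stop("regulated reactions not in the model: ",
         paste(unknown, collapse = ", "))
  }
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed + 1L)
  ids <- names(model$reactions)
  d_expression <- stats::setNames(stats::rnorm(length(ids), 0, 0.15), ids)
  significant <- stats::setNames(rep(FALSE, length(ids)), ids)
  d_expression[names(regulated)] <- regulated
  significant[names(regulated)] <- TRUE
  expression <- data.frame(reaction_id = ids,
                           d_expression = unname(d_expression),
                           significant = unname(significant),
                           stringsAsFactors = FALSE)
  truth <- stats::setNames(ids %in% names(regulated), ids)
  list(constraints_a = constraints_a, constraints_b = constraints_b,
       expression = expression, truth = truth, model = model, seed = seed)
}

#' Run the regulation-scoring pipeline on a generated study
#'
#' Convenience wrapper: samples both conditions and scores every reaction.
#'
#' @param study Output of [generate_two_condition_study()].
#' @param n_samples Samples per condition (default 1000).
#' @param seed Sampler seed; condition B uses `seed + 1`.
#' @return An `evidence_score_table` with the ground-truth labels merged in
#'   as a `truth` column.
#' @export
score_two_condition_study <- function(study, n_samples = 1000,
                                      seed = study$seed) {
  sa <- sample_flux_space(study$model, study$constraints_a, n_samples,
                          seed = seed)
  sb <- sample_flux_space(study$model, study$constraints_b, n_samples,
                          seed = seed + 1L)
  tab <- score_regulation(sa, sb, study$expression)
  tab$truth <- unname(study$truth[tab$reaction_id])
  tab
}

#' Area under the ROC curve for evidence-score recovery
#'
#' Rank-based (Mann-Whitney) AUROC of the scores against the ground-truth
#' labels, with ties handled by midranks.
#'
#' @param score Numeric evidence scores.
#' @param truth Logical ground-truth labels.
#' @return AUROC in `[0, 1]`.
#' @export
score_auroc <- function(score, truth) {
  stopifnot(length(score) == length(truth))
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative labels")
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
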