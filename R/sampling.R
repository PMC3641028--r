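# Random sampling of constrained flux spaces and transcriptional-regulation
# evidence scoring.
#
# The flux space {v : S v = 0, lb <= v <= ub, exchange constraints} is a
# bounded convex polytope. It is parameterized on the null space of S
# (v = v0 + N t) and explored with a coordinate hit-and-run walk: pick a
# null-space direction, intersect the line with the bound constraints, and
# jump to a uniform point of the feasible segment. After warm-up, thinned
# iterates are asymptotically uniform on the polytope.

#' Exchange-flux constraint from a measurement
#'
#' Ties a reaction's flux to a measured value within a relative tolerance.
#' Measurements in mmolC/gDW/h are converted to mmol/gDW/h by dividing by
#' the carbon count of the exchanged metabolite.
#'
#' @param reaction_id Constrained reaction id.
#' @param flux Measured flux (mmol/gDW/h unless `unit = "mmolC"`).
#' @param rel_tol Relative tolerance (default 0.05, i.e. +/- 5 percent).
#' @param unit `"mmol"` or `"mmolC"`.
#' @return List of class `"exchange_constraint"`.
#' @export
exchange_constraint <- function(reaction_id, flux, rel_tol = 0.05,
                                unit = c("mmol", "mmolC")) {
  unit <- match.arg(unit)
  if (rel_tol < 0) stop("rel_tol must be >= 0")
  structure(list(reaction_id = reaction_id, flux = flux, rel_tol = rel_tol,
                 unit = unit),
            class = "exchange_constraint")
}

# apply exchange constraints to model bounds
.constrain_model <- function(model, constraints) {
  carbon <- vapply(model$metabolites, `[[`, 0, "carbon_atoms")
  for (ct in constraints) {
    if (!ct$reaction_id %in% names(model$reactions)) {
      stop("constraint on unknown reaction '", ct$reaction_id, "'")
    }
    flux <- ct$flux
    if (ct$unit == "mmolC") {
      met <- names(model$reactions[[ct$reaction_id]]$stoichiometry)
      if (length(met) != 1L) {
        stop("mmolC constraint needs a single-metabolite reaction ('",
             ct$reaction_id, "')")
      }
      nc <- carbon[[met]]
      if (nc <= 0) stop("metabolite '", met, "' carries no carbon")
      flux <- flux / nc
    }
    halfwidth <- abs(flux) * ct$rel_tol
    model <- set_bounds(model, ct$reaction_id,
                        flux - halfwidth, flux + halfwidth)
  }
  model
}

#' Sample the constrained flux space of a model
#'
#' Feasibility is first checked with an LP probe; the polytope is then
#' parameterized on the null space of the stoichiometric matrix and sampled
#' by coordinate hit-and-run with `10 * dim` warm-up steps and a thinning of
#' 10 (so `10 * n_samples` post-warm-up steps are taken). The chain starts
#' from an interior point obtained by averaging LP vertices that
#' maximize/minimize each null-space coordinate. Deterministic given `seed`.
#'
#' @param model A `metabolic_model`.
#' @param constraints List of [exchange_constraint()]s (may be empty).
#' @param n_samples Number of flux vectors to return.
#' @param seed Mandatory integer seed; the sampler keeps no global state.
#' @param thin Thinning interval (default 10).
#' @param warmup Warm-up steps (default `10 * dim`).
#' @return List of class `"flux_sample_set"`: `samples` (n_samples x
#'   reactions matrix), `reaction_ids`, `seed`, `n_samples`.
#' @export
sample_flux_space <- function(model, constraints = list(), n_samples = 1000,
                              seed, thin = 10, warmup = NULL) {
  if (missing(seed)) stop("seed is a mandatory argument")
  model <- .constrain_model(model, constraints)
  S <- build_stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  if (any(is.infinite(lb)) || any(is.infinite(ub))) {
    stop("sampling needs finite bounds on every reaction; ",
         "unbounded directions must be capped first")
  }

  # feasibility probe; also the fallback start point
  probe <- solve_lp(numeric(ncol(S)), S, numeric(nrow(S)), lb, ub)
  if (probe$status != "optimal") {
    viol <- .nearest_violated_constraint(model, constraints)
    stop("constrained flux space is empty",
         if (nzchar(viol)) paste0(" (check constraint on ", viol, ")"))
  }

  # null-space parameterization v = v0 + N t
  N <- .nullspace(S)
  d <- ncol(N)
  if (d == 0L) {
    samples <- matrix(rep(probe$x, n_samples), nrow = n_samples,
                      byrow = TRUE, dimnames = list(NULL, colnames(S)))
    return(structure(list(samples = samples, reaction_ids = colnames(S),
                          seed = seed, n_samples = n_samples),
                     class = "flux_sample_set"))
  }
  if (is.null(warmup)) warmup <- 10L * d

  # interior-ish start: average the vertices optimizing each coordinate
  verts <- probe$x
  for (j in seq_len(min(d, 25L))) {
    for (dir in c(1, -1)) {
      vr <- solve_lp(dir * N[, j], S, numeric(nrow(S)), lb, ub)
      if (vr$status == "optimal") verts <- rbind(verts, vr$x)
    }
  }
  v <- if (is.matrix(verts)) colMeans(verts) else verts

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  n_steps <- warmup + thin * n_samples
  dirs <- sample.int(d, n_steps, replace = TRUE)
  jumps <- stats::runif(n_steps)
  out <- matrix(NA_real_, n_samples, ncol(S),
                dimnames = list(NULL, colnames(S)))
  k <- 0L
  for (step in seq_len(n_steps)) {
    w <- N[, dirs[step]]
    nz <- abs(w) > 1e-12
    lo <- (lb[nz] - v[nz]) / w[nz]
    hi <- (ub[nz] - v[nz]) / w[nz]
    t_min <- max(pmin(lo, hi))
    t_max <- min(pmax(lo, hi))
    if (t_max > t_min) {
      v <- v + (t_min + jumps[step] * (t_max - t_min)) * w
    }
    if (step > warmup && (step - warmup) %% thin == 0L) {
      k <- k + 1L
      out[k, ] <- v
    }
  }
  structure(list(samples = out, reaction_ids = colnames(S), seed = seed,
                 n_samples = n_samples),
            class = "flux_sample_set")
}

# orthonormal null-space basis of S via SVD
.nullspace <- function(S, tol = 1e-10) {
  if (nrow(S) == 0L) return(diag(ncol(S)))
  sv <- svd(S, nu = 0, nv = ncol(S))
  positive <- sv$d > tol * max(sv$d, 1)
  rank <- sum(positive)
  if (rank >= ncol(S)) {
    return(matrix(0, ncol(S), 0))
  }
  sv$v[, (rank + 1L):ncol(S), drop = FALSE]
}

# identify a constraint whose window is infeasible on its own, for error text
.nearest_violated_constraint <- function(model, constraints) {
  for (ct in constraints) {
    r <- model$reactions[[ct$reaction_id]]
    if (!is.null(r) && r$lower_bound > r$upper_bound) return(ct$reaction_id)
  }
  if (length(constraints)) constraints[[1]]$reaction_id else ""
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat("Flux sample set: ", x$n_samples, " samples over ",
      length(x$reaction_ids), " reactions (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Per-reaction probability of a flux increase between two conditions
#'
#' Pairs the two sample sets by index (independent chains) and reports
#' P+ = P(v_B > v_A) per reaction; ties count one half.
#'
#' @param samples_a,samples_b `flux_sample_set`s over the same reactions with
#'   equal sample counts (condition A = reference, condition B = test).
#' @return Named vector of probabilities in `[0, 1]`.
#' @export
flux_change_probability <- function(samples_a, samples_b) {
  if (!identical(samples_a$reaction_ids, samples_b$reaction_ids)) {
    stop("sample sets cover different reaction sets")
  }
  if (samples_a$n_samples != samples_b$n_samples) {
    stop("sample sets must have the same number of samples")
  }
  gt <- colMeans(samples_b$samples > samples_a$samples)
  eq <- colMeans(samples_b$samples == samples_a$samples)
  stats::setNames(gt + 0.5 * eq, samples_a$reaction_ids)
}

#' Transcriptional-regulation evidence score
#'
#' Probability that the sampled flux change agrees in direction with a
#' significant expression change: `P+` when expression is up, `1 - P+` when
#' down, and 0 when the expression change is not significant (no
#' transcriptional evidence). A significant flag with a zero expression
#' change is demoted to not-significant with a warning.
#'
#' @param p_plus Flux-increase probability (or vector), in `[0, 1]`.
#' @param d_expression Reaction-level log2 expression change(s).
#' @param significant Logical flag(s).
#' @return Score(s) in `[0, 1]`.
#' @export
evidence_score <- function(p_plus, d_expression, significant) {
  n <- max(length(p_plus), length(d_expression), length(significant))
  p_plus <- rep_len(p_plus, n)
  d_expression <- rep_len(d_expression, n)
  significant <- rep_len(significant, n)
  if (any(p_plus < 0 | p_plus > 1, na.rm = TRUE)) {
    stop("p_plus must lie in [0, 1]")
  }
  zero_sig <- significant & !is.na(d_expression) & d_expression == 0
  if (any(zero_sig)) {
    warning(sum(zero_sig),
            " significant flag(s) with zero expression change treated as ",
            "not significant")
    significant[zero_sig] <- FALSE
  }
  score <- numeric(n)
  up <- significant & !is.na(d_expression) & d_expression > 0
  dn <- significant & !is.na(d_expression) & d_expression < 0
  score[up] <- p_plus[up]
  score[dn] <- 1 - p_plus[dn]
  score
}

#' Score and classify reactions for transcriptional regulation
#'
#' Builds the per-reaction evidence table from two condition sample sets and
#' a reaction-level expression table, then classifies each reaction:
#' transcriptional (score >= `score_hi`), metabolic (strong flux change,
#' `max(P+, 1-P+) >= flux_hi`, without significant expression),
#' post-transcriptional (significant expression contradicted by the flux,
#' score <= 1 - `score_hi`) or none.
#'
#' @param samples_a,samples_b `flux_sample_set`s for the two conditions.
#' @param expression_table Data frame from [reaction_expression_change()]
#'   (columns `reaction_id`, `d_expression`, `significant`).
#' @param score_hi,flux_hi Classification thresholds in (0.5, 1].
#' @return Data frame of class `"evidence_score_table"`: `reaction_id`,
#'   `p_plus`, `d_expression`, `significant`, `score`, `call`, `rank`,
#'   ordered by decreasing score (ties by |d_expression|, then id).
#' @export
score_regulation <- function(samples_a, samples_b, expression_table,
                             score_hi = 0.9, flux_hi = 0.9) {
  p_plus <- flux_change_probability(samples_a, samples_b)
  idx <- match(names(p_plus), expression_table$reaction_id)
  de <- expression_table$d_expression[idx]
  sig <- expression_table$significant[idx]
  sig[is.na(sig)] <- FALSE
  tab <- data.frame(reaction_id = names(p_plus),
                    p_plus = unname(p_plus),
                    d_expression = de,
                    significant = sig,
                    stringsAsFactors = FALSE)
  tab$score <- suppressWarnings(
    evidence_score(tab$p_plus, tab$d_expression, tab$significant))
  tab$call <- classify_regulation(tab, score_hi = score_hi,
                                  flux_hi = flux_hi)
  rank_reactions(tab)
}

#' Classify reactions from an evidence table
#'
#' @param table Data frame with `score`, `p_plus`, `significant` columns.
#' @param score_hi Transcriptional / post-transcriptional threshold in
#'   (0.5, 1].
#' @param flux_hi Metabolic (flux-only) threshold in (0.5, 1].
#' @return Character vector of calls: `"transcriptional"`, `"metabolic"`,
#'   `"post-transcriptional"` or `"none"`.
#' @export
classify_regulation <- function(table, score_hi = 0.9, flux_hi = 0.9) {
  for (th in c(score_hi, flux_hi)) {
    if (th <= 0.5 || th > 1) stop("thresholds must lie in (0.5, 1]")
  }
  strong_flux <- pmax(table$p_plus, 1 - table$p_plus) >= flux_hi
  ifelse(table$significant & table$score >= score_hi, "transcriptional",
    ifelse(!table$significant & strong_flux, "metabolic",
      ifelse(table$significant & table$score <= 1 - score_hi,
             "post-transcriptional", "none")))
}

#' Rank reactions by evidence score
#'
#' Descending score; ties broken by |d_expression| (descending) then by
#' reaction id, so the order is deterministic.
#'
#' @param table Evidence data frame with `score`, `d_expression`,
#'   `reaction_id`.
#' @return The table sorted, with a `rank` column (1 = strongest evidence).
#' @export
rank_reactions <- function(table) {
  de <- ifelse(is.na(table$d_expression), 0, abs(table$d_expression))
  o <- order(-table$score, -de, table$reaction_id)
  out <- table[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("evidence_score_table", "data.frame")
  out
}

#' @export
print.evidence_score_table <- function(x, n = 10, ...) {
  cat("Evidence score table (", nrow(x), " reactions)\n", sep = "")
  print.data.frame(utils::head(x, n), digits = 3)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}
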