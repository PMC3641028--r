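# Toy fixtures and an independent brute-force LP oracle.

# linear chain a_e -> b -> c (exchange only for a_e unless with_c_exchange)
toy_chain_model <- function(with_c_exchange = FALSE) {
  mets <- list(metabolite("a_e", compartment = "extracellular",
                          carbon_atoms = 1),
               metabolite("b", carbon_atoms = 1),
               metabolite("c", carbon_atoms = 1))
  rxns <- list(reaction("EX_a", c(a_e = -1), -10, 10, is_exchange = TRUE),
               reaction("R1", c(a_e = -1, b = 1), 0, 10),
               reaction("R2", c(b = -1, c = 1), 0, 10))
  if (with_c_exchange) {
    rxns <- c(rxns, list(reaction("EX_c", c(c = -1), 0, 10,
                                  is_exchange = TRUE)))
  }
  metabolic_model(mets, rxns, metadata = list(name = "chain", version = "1"))
}

# two routes of different ATP yield between m and p; <= 2 degrees of freedom
toy_two_route_model <- function() {
  mets <- list(metabolite("m_e", compartment = "extracellular",
                          carbon_atoms = 1),
               metabolite("m", carbon_atoms = 1),
               metabolite("p", carbon_atoms = 1),
               metabolite("p_e", compartment = "extracellular",
                          carbon_atoms = 1),
               metabolite("atp", carbon_atoms = 0),
               metabolite("adp", carbon_atoms = 0))
  rxns <- list(
    reaction("EX_m", c(m_e = -1), -1, -1, is_exchange = TRUE),
    reaction("Tm", c(m_e = -1, m = 1), 0, 10),
    reaction("R_hi", c(m = -1, adp = -2, p = 1, atp = 2), 0, 10),
    reaction("R_lo", c(m = -1, adp = -1, p = 1, atp = 1), 0, 10),
    reaction("Tp", c(p = -1, p_e = 1), 0, 10),
    reaction("EX_p", c(p_e = -1), 0, 10, is_exchange = TRUE),
    reaction("DRAIN", c(atp = -1, adp = 1), 0, 10))
  metabolic_model(mets, rxns, maintenance_reaction_id = "DRAIN",
                  metadata = list(name = "tworoute", version = "1"))
}

# diamond: two equivalent carbon routes, no cofactors
toy_diamond_model <- function() {
  mets <- list(metabolite("m_e", compartment = "extracellular",
                          carbon_atoms = 1),
               metabolite("m", carbon_atoms = 1),
               metabolite("p", carbon_atoms = 1))
  rxns <- list(
    reaction("EX_m", c(m_e = -1), -1, -1, is_exchange = TRUE),
    reaction("Tm", c(m_e = -1, m = 1), 0, 10),
    reaction("R1", c(m = -1, p = 1), 0, 0.7),
    reaction("R2", c(m = -1, p = 1), 0, 10),
    reaction("EX_p", c(p = -1), 0, 10, is_exchange = TRUE))
  metabolic_model(mets, rxns, metadata = list(name = "diamond",
                                              version = "1"))
}

# reversible shuttle with asymmetric bounds
toy_reversible_model <- function() {
  mets <- list(metabolite("a_e", compartment = "extracellular",
                          carbon_atoms = 1),
               metabolite("a", carbon_atoms = 1),
               metabolite("b", carbon_atoms = 1))
  rxns <- list(
    reaction("EX_a", c(a_e = -1), -2, 2, is_exchange = TRUE),
    reaction("Ta", c(a_e = -1, a = 1), -2, 2),
    reaction("R1", c(a = -1, b = 1), -1.5, 1.5),
    reaction("EX_b", c(b = -1), -0.4, 5, is_exchange = TRUE))
  metabolic_model(mets, rxns, metadata = list(name = "shuttle",
                                              version = "1"))
}

# single-pathway network whose one free flux is uniform on the uptake window
toy_onedof_model <- function(lo = 0.9, hi = 1.1) {
  mets <- list(metabolite("s_e", compartment = "extracellular",
                          carbon_atoms = 1),
               metabolite("p_e", compartment = "extracellular",
                          carbon_atoms = 1))
  rxns <- list(
    reaction("EX_s", c(s_e = -1), -hi, -lo, is_exchange = TRUE),
    reaction("CONV", c(s_e = -1, p_e = 1), 0, 10),
    reaction("EX_p", c(p_e = -1), 0, 10, is_exchange = TRUE))
  metabolic_model(mets, rxns, metadata = list(name = "onedof",
                                              version = "1"))
}

# Brute-force LP oracle for networks whose flux polytope has <= 2 degrees of
# freedom: parameterize on the null space of S and enumerate the candidate
# vertices of the (interval / polygon) feasible set directly.
enumerate_lp_optimum <- function(model, objective,
                                 direction = c("max", "min")) {
  direction <- match.arg(direction)
  S <- build_stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  sv <- svd(S, nu = 0, nv = ncol(S))
  rank <- sum(sv$d > 1e-10 * max(sv$d, 1))
  d <- ncol(S) - rank
  stopifnot(d >= 1, d <= 2)
  N <- sv$v[, (rank + 1):ncol(S), drop = FALSE]
  cvec <- as.numeric(colnames(S) == objective)
  # feasible set in t-space: lb <= N t <= ub  (v0 = 0 satisfies S v = 0)
  if (d == 1) {
    w <- N[, 1]
    lo <- -Inf; hi <- Inf
    for (i in seq_along(w)) {
      if (abs(w[i]) < 1e-12) {
        if (lb[i] > 1e-12 || ub[i] < -1e-12) return(NA_real_)
        next
      }
      r <- sort(c(lb[i] / w[i], ub[i] / w[i]))
      lo <- max(lo, r[1]); hi <- min(hi, r[2])
    }
    if (lo > hi) return(NA_real_)
    vals <- c(sum((cvec %*% N) * lo), sum((cvec %*% N) * hi))
    return(if (direction == "max") max(vals) else min(vals))
  }
  # d == 2: candidate vertices are intersections of constraint-line pairs
  A <- rbind(N, -N)             # rows: N t <= ub ; -N t <= -lb
  bnd <- c(ub, -lb)
  keep <- rowSums(abs(A)) > 1e-12
  if (any(bnd[!keep] < -1e-12)) return(NA_real_)  # 0 outside a fixed bound
  A <- A[keep, , drop = FALSE]; bnd <- bnd[keep]
  pts <- list()
  nr <- nrow(A)
  for (i in seq_len(nr - 1)) {
    for (j in (i + 1):nr) {
      M <- rbind(A[i, ], A[j, ])
      if (abs(det(M)) < 1e-12) next
      t0 <- solve(M, c(bnd[i], bnd[j]))
      if (all(A %*% t0 <= bnd + 1e-8)) pts[[length(pts) + 1]] <- t0
    }
  }
  if (!length(pts)) return(NA_real_)
  vals <- vapply(pts, function(t0) sum(cvec * (N %*% t0)), 0)
  if (direction == "max") max(vals) else min(vals)
}
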