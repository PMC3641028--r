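# Flux balance analysis: max c'v subject to S v = 0 and lb <= v <= ub.

#' Energetic parameters
#'
#' Growth-associated maintenance (GAM) is the ATP hydrolyzed per gram of
#' biomass formed, charged inside the biomass equation; non-growth-associated
#' maintenance (NGAM) is a constant ATP drain imposed as the lower bound of
#' the maintenance reaction. Defaults: GAM 43 mmol ATP/gDW, NGAM 0 (the
#' typical bacterial scenario value is 1.5 mmol ATP/gDW/h).
#'
#' @param gam Growth-associated maintenance, mmol ATP per gDW.
#' @param ngam Non-growth-associated maintenance, mmol ATP per gDW per hour.
#' @return List of class `"energy_params"`.
#' @export
energy_params <- function(gam = 43, ngam = 0) {
  if (gam < 0 || ngam < 0) stop("gam and ngam must be non-negative")
  structure(list(gam = gam, ngam = ngam), class = "energy_params")
}

# rewrite the GAM term (atp + h2o -> adp + pi) of the biomass equation
.apply_gam <- function(model, gam) {
  bid <- model$biomass_reaction_id
  if (is.null(bid)) stop("model has no biomass reaction")
  r <- model$reactions[[bid]]
  st <- r$stoichiometry
  st[c("atp", "h2o")] <- -gam
  st[c("adp", "pi")] <- gam
  r$stoichiometry <- st
  model$reactions[[bid]] <- r
  model
}

#' Switch the active terminal-oxidase branch (P/O mode)
#'
#' In `"high"` mode only the cytochrome-c oxidase branch is open
#' (6 translocated protons per electron pair; theoretical P/O 2.5 with NADH
#' dehydrogenase I); in `"low"` mode only the ubiquinol (bd/bo) oxidases are
#' open (2 protons; P/O 1.5). The inactive class is bounded to zero in a copy
#' of the model; the input is untouched. Oxidase classes are recognized by
#' the subsystem tags `"respiration:cytochrome-c"` and
#' `"respiration:ubiquinol"`.
#'
#' @param model A `metabolic_model` with tagged oxidase reactions.
#' @param mode `"high"` or `"low"`.
#' @return The modified model copy.
#' @export
set_po_mode <- function(model, mode = c("high", "low")) {
  mode <- match.arg(mode)
  subs <- vapply(model$reactions, `[[`, "", "subsystem")
  cytc <- names(model$reactions)[subs == "respiration:cytochrome-c"]
  ubi <- names(model$reactions)[subs == "respiration:ubiquinol"]
  if (!length(cytc) || !length(ubi)) {
    stop("model '", model$metadata$name,
         "' lacks tagged oxidase reactions (subsystems ",
         "'respiration:cytochrome-c' / 'respiration:ubiquinol')")
  }
  closed <- if (mode == "high") ubi else cytc
  for (id in closed) model <- set_bounds(model, id, 0, 0)
  model
}

#' Solve a flux balance analysis problem
#'
#' @param model A `metabolic_model`.
#' @param objective Reaction id to optimize; defaults to the model's stored
#'   objective.
#' @param direction `"max"` or `"min"`.
#' @param bounds Optional named list of bound overrides,
#'   `list(reaction_id = c(lb, ub), ...)`, applied to a copy of the model.
#' @return A `flux_distribution`: list with `fluxes` (named vector,
#'   mmol/gDW/h), `objective_value` and `status` (`"optimal"`, `"infeasible"`
#'   or `"unbounded"`).
#' @export
solve_fba <- function(model, objective = model$objective,
                      direction = c("max", "min"), bounds = NULL) {
  direction <- match.arg(direction)
  if (is.null(objective) || !objective %in% names(model$reactions)) {
    stop("objective reaction '", objective, "' not in model")
  }
  for (id in names(bounds)) {
    model <- set_bounds(model, id, bounds[[id]][1], bounds[[id]][2])
  }
  S <- build_stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  obj <- stats::setNames(numeric(ncol(S)), colnames(S))
  obj[objective] <- 1
  maximize <- direction == "max"

  res <- solve_lp(obj, S, numeric(nrow(S)), lb, ub, maximize = maximize)
  status <- res$status
  structure(list(fluxes = if (status == "optimal") {
                   stats::setNames(res$x, colnames(S))
                 } else NULL,
                 objective_value = if (status == "optimal") {
                   res$objective_value
                 } else NA_real_,
                 objective = objective,
                 status = status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("Flux distribution (", x$status, ")\n", sep = "")
  if (x$status == "optimal") {
    cat("  objective ", x$objective, " = ",
        format(x$objective_value, digits = 6), "\n", sep = "")
    nz <- x$fluxes[abs(x$fluxes) > 1e-9]
    cat("  ", length(nz), " of ", length(x$fluxes),
        " reactions carry flux\n", sep = "")
  }
  invisible(x)
}

#' Carbon flow across the exchange reactions of a solved model
#'
#' Sums flux times carbon content over all exchange reactions; for a
#' carbon-balanced network at steady state the total is zero (uptake carbon =
#' secreted carbon, in mmolC/gDW/h).
#'
#' @param model The `metabolic_model` that was solved.
#' @param fd A `flux_distribution` from [solve_fba()].
#' @return Net exchange carbon flux (mmolC/gDW/h; 0 = balanced).
#' @export
flux_carbon_balance <- function(model, fd) {
  stopifnot(inherits(fd, "flux_distribution"), fd$status == "optimal")
  carbon <- vapply(model$metabolites, `[[`, 0, "carbon_atoms")
  tot <- 0
  for (r in model$reactions) {
    if (!r$is_exchange) next
    met <- names(r$stoichiometry)
    # exchange convention: coefficient -1, uptake-negative flux
    tot <- tot + r$stoichiometry[[met]] * fd$fluxes[[r$id]] * carbon[[met]]
  }
  unname(tot)
}

.source_exchange <- c(fructose = "EX_fru", glycerol = "EX_glyc")

#' Molar masses and carbon counts of the carbon sources
#'
#' @param name `"fructose"` or `"glycerol"`.
#' @return List with `name`, `molar_mass` (g/mol) and `carbon_atoms`.
#' @export
carbon_source <- function(name = c("fructose", "glycerol")) {
  name <- match.arg(name)
  switch(name,
         fructose = list(name = "fructose", molar_mass = 180.16,
                         carbon_atoms = 6L),
         glycerol = list(name = "glycerol", molar_mass = 92.09,
                         carbon_atoms = 3L))
}

# prepare a model for a yield computation: pick oxidase branch, fix substrate
# uptake at 1 mmol/gDW/h (LP homogeneity makes the scale irrelevant), close
# the other carbon source
.yield_setup <- function(model, source, po_mode) {
  model <- set_po_mode(model, po_mode)
  uptake <- .source_exchange[[source]]
  other <- setdiff(unname(.source_exchange), uptake)
  if (!uptake %in% names(model$reactions)) {
    stop("model has no ", source, " exchange (", uptake, ")")
  }
  model <- set_bounds(model, uptake, -1, -1)
  for (id in intersect(other, names(model$reactions))) {
    model <- set_bounds(model, id, 0, 0)
  }
  model
}

#' Theoretical (FBA-optimal) biomass yield
#'
#' Maximizes the biomass flux at a fixed substrate uptake of 1 mmol/gDW/h
#' under the chosen terminal-oxidase mode and maintenance parameters, and
#' converts to mass yield using the substrate molar mass (fructose 180.16,
#' glycerol 92.09 g/mol).
#'
#' @param model A `metabolic_model`; defaults to [build_core_model()].
#' @param source `"fructose"` or `"glycerol"`.
#' @param po_mode `"high"` (P/O 2.5) or `"low"` (P/O 1.5).
#' @param energy An [energy_params()] object.
#' @return Optimal yield in g-DW per g-substrate (rounded to 4 decimals), or
#'   `NA` with a warning when the constraint set is infeasible.
#' @export
theoretical_biomass_yield <- function(model = build_core_model(),
                                      source = c("fructose", "glycerol"),
                                      po_mode = c("high", "low"),
                                      energy = energy_params()) {
  source <- match.arg(source)
  po_mode <- match.arg(po_mode)
  model <- .apply_gam(model, energy$gam)
  model <- .yield_setup(model, source, po_mode)
  if (!is.null(model$maintenance_reaction_id)) {
    model <- set_bounds(model, model$maintenance_reaction_id,
                        lower_bound = energy$ngam)
  }
  fd <- solve_fba(model, objective = model$biomass_reaction_id)
  if (fd$status != "optimal") {
    warning("biomass FBA ", fd$status, " (source = ", source,
            ", ngam = ", energy$ngam, ")")
    return(structure(NA_real_, status = fd$status))
  }
  src <- carbon_source(source)
  # biomass flux is in gDW/gDW/h; uptake of 1 mmol/h weighs molar_mass mg
  round(fd$objective_value / (src$molar_mass / 1000), 4)
}

#' Theoretical (FBA-optimal) alginate yield
#'
#' Maximizes secretion of the deacetylated alginate monomer at a fixed
#' substrate uptake of 1 mmol/gDW/h with growth disabled (biomass flux fixed
#' to zero: the non-growing cell-factory scenario).
#'
#' @inheritParams theoretical_biomass_yield
#' @return Optimal yield in mmol monomer per mmol substrate (rounded to 4
#'   decimals).
#' @export
theoretical_alginate_yield <- function(model = build_core_model(),
                                       source = c("fructose", "glycerol"),
                                       po_mode = c("high", "low")) {
  source <- match.arg(source)
  po_mode <- match.arg(po_mode)
  model <- .yield_setup(model, source, po_mode)
  if (!is.null(model$biomass_reaction_id)) {
    model <- set_bounds(model, model$biomass_reaction_id, 0, 0)
  }
  fd <- solve_fba(model, objective = "EX_algM")
  if (fd$status != "optimal") {
    warning("alginate FBA ", fd$status, " (source = ", source, ")")
    return(structure(NA_real_, status = fd$status))
  }
  round(fd$objective_value, 4)
}

#' Yield table across P/O modes and maintenance values
#'
#' @param model A `metabolic_model`.
#' @param sources Carbon sources to scan.
#' @param po_modes Oxidase modes to scan.
#' @param ngam_grid NGAM values (mmol ATP/gDW/h) for the biomass calculator.
#' @param gam Growth-associated maintenance passed to every biomass solve.
#' @return Data frame with columns `source`, `po_mode`, `ngam`,
#'   `biomass_yield` (g/g) and `alginate_yield` (mmol/mmol; NGAM-independent
#'   by construction, repeated across the grid).
#' @export
yield_vs_po_curve <- function(model = build_core_model(),
                              sources = c("fructose", "glycerol"),
                              po_modes = c("high", "low"),
                              ngam_grid = 0, gam = 43) {
  grid <- expand.grid(source = sources, po_mode = po_modes,
                      ngam = ngam_grid, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  alg <- new.env()
  grid$biomass_yield <- NA_real_
  grid$alginate_yield <- NA_real_
  for (i in seq_len(nrow(grid))) {
    grid$biomass_yield[i] <- theoretical_biomass_yield(
      model, grid$source[i], grid$po_mode[i],
      energy_params(gam = gam, ngam = grid$ngam[i]))
    key <- paste(grid$source[i], grid$po_mode[i])
    if (!exists(key, envir = alg, inherits = FALSE)) {
      alg[[key]] <- theoretical_alginate_yield(model, grid$source[i],
                                               grid$po_mode[i])
    }
    grid$alginate_yield[i] <- alg[[key]]
  }
  grid
}

#' Measure the operational P/O ratio of the respiratory chain
#'
#' Adds a unit NADH source to a copy of the model, closes all carbon
#' exchanges, maximizes the maintenance ATP drain and reports ATP formed per
#' oxygen atom reduced. With 4 protons pumped by NADH dehydrogenase I, a
#' 4 H+/ATP synthase and either 6 (cytochrome-c) or 2 (ubiquinol oxidase)
#' protons translocated downstream, the ratio is 2.5 in `"high"` mode and
#' 1.5 in `"low"` mode.
#'
#' @param model A `metabolic_model`; defaults to [build_core_model()].
#' @param po_mode `"high"` or `"low"`.
#' @return List with `po` (ATP per O), `atp` and `o_atoms` fluxes.
#' @export
measure_po_ratio <- function(model = build_core_model(),
                             po_mode = c("high", "low")) {
  po_mode <- match.arg(po_mode)
  model <- set_po_mode(model, po_mode)
  for (id in intersect(unname(.source_exchange), names(model$reactions))) {
    model <- set_bounds(model, id, 0, 0)
  }
  model$reactions[["NADH_SRC"]] <-
    reaction("NADH_SRC", c(nad = -1, nadh = 1), 1, 1,
             subsystem = "diagnostic")
  fd <- solve_fba(model, objective = model$maintenance_reaction_id)
  if (fd$status != "optimal") stop("P/O probe FBA ", fd$status)
  o_atoms <- -2 * fd$fluxes[["EX_o2"]]
  list(po = unname(fd$objective_value / o_atoms),
       atp = unname(fd$objective_value), o_atoms = unname(o_atoms))
}
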