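#' Create a metabolite
#'
#' Metabolites are the nodes of a metabolic network. Each carries a compartment
#' tag and its number of carbon atoms, which drives the elemental balance
#' diagnostics and all carbon-based yield arithmetic.
#'
#' @param id Short unique identifier (character scalar).
#' @param name Free-text name; defaults to `id`.
#' @param compartment One of `"extracellular"`, `"periplasm"`, `"cytosol"`.
#' @param carbon_atoms Non-negative integer count of carbon atoms.
#' @param formula Optional elemental formula string (e.g. `"C6H12O6"`). When
#'   given, its carbon count must agree with `carbon_atoms`.
#' @return A list of class `"metabolite"`.
#' @export
metabolite <- function(id, name = id,
                       compartment = c("cytosol", "periplasm", "extracellular"),
                       carbon_atoms = 0L, formula = NULL) {
  compartment <- match.arg(compartment)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(carbon_atoms) || length(carbon_atoms) != 1L ||
      is.na(carbon_atoms) || carbon_atoms < 0) {
    stop("carbon_atoms must be a single non-negative number for metabolite '",
         id, "'")
  }
  if (!is.null(formula)) {
    fc <- .formula_carbon(formula)
    if (!is.na(fc) && fc != carbon_atoms) {
      stop("formula '", formula, "' of metabolite '", id,
           "' implies ", fc, " carbon atoms but carbon_atoms = ", carbon_atoms)
    }
  }
  structure(list(id = id, name = name, compartment = compartment,
                 carbon_atoms = as.numeric(carbon_atoms), formula = formula),
            class = "metabolite")
}

# carbon count from an elemental formula ("C6H12O6" -> 6; "H2O" -> 0)
.formula_carbon <- function(formula) {
  m <- regmatches(formula, regexpr("C[0-9]*(?![a-z])", formula, perl = TRUE))
  if (length(m) == 0L) return(0)
  n <- sub("^C", "", m)
  if (!nzchar(n)) 1 else as.numeric(n)
}

#' Create a reaction
#'
#' @param id Short unique identifier.
#' @param stoichiometry Named numeric vector of coefficients
#'   (metabolite id -> signed coefficient; negative = consumed).
#' @param lower_bound,upper_bound Flux bounds in mmol/gDW/h. Reactions are
#'   irreversible in the canonical direction (`lower_bound = 0`) unless stated.
#' @param gpr Gene-protein-reaction boolean rule over gene ids, e.g.
#'   `"(geneA and geneB) or geneC"`. Empty string means no gene association.
#' @param subsystem Free-text pathway tag.
#' @param is_exchange Flag marking boundary (exchange) reactions; these touch
#'   exactly one metabolite and use the uptake-negative sign convention.
#' @return A list of class `"reaction"`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     gpr = "", subsystem = "", is_exchange = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry))) ||
      anyDuplicated(names(stoichiometry))) {
    stop("stoichiometry of reaction '", id,
         "' must be a numeric vector uniquely named by metabolite ids")
  }
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound (", lower_bound,
         ") exceeds upper_bound (", upper_bound, ")")
  }
  if (is_exchange && length(stoichiometry) != 1L) {
    stop("exchange reaction '", id, "' must touch exactly one metabolite")
  }
  structure(list(id = id, stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gpr = gpr, subsystem = subsystem,
                 is_exchange = isTRUE(is_exchange)),
            class = "reaction")
}

#' Assemble a metabolic model
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param biomass_reaction_id,maintenance_reaction_id Ids of the biomass drain
#'   and the maintenance ATP-hydrolysis reaction (may be `NULL` for toy
#'   models).
#' @param objective Default objective reaction id; defaults to the biomass
#'   reaction.
#' @param metadata List with `name` and `version` entries.
#' @param validate Run [validate_model()] on the assembled model (default
#'   `TRUE`).
#' @return A list of class `"metabolic_model"`.
#' @export
metabolic_model <- function(metabolites, reactions,
                            biomass_reaction_id = NULL,
                            maintenance_reaction_id = NULL,
                            objective = biomass_reaction_id,
                            metadata = list(name = "model", version = "0"),
                            validate = TRUE) {
  names(metabolites) <- vapply(metabolites, `[[`, "", "id")
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(metabolites = metabolites, reactions = reactions,
                      biomass_reaction_id = biomass_reaction_id,
                      maintenance_reaction_id = maintenance_reaction_id,
                      objective = objective, metadata = metadata),
                 class = "metabolic_model")
  if (validate) validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique metabolite and reaction ids,
#' ordered bounds, every referenced metabolite defined, exchange reactions
#' touching exactly one metabolite, carbon balance of non-exchange reactions
#' (the biomass drain is exempt), and existence of the designated biomass /
#' maintenance reactions.
#'
#' @param model A `metabolic_model`.
#' @param stop_on_error Raise an error on the first collected violation
#'   (default `TRUE`); otherwise return the violations.
#' @return Invisibly, a character vector of violations (empty when valid).
#' @export
validate_model <- function(model, stop_on_error = TRUE) {
  stopifnot(inherits(model, "metabolic_model"))
  bad <- character(0)
  met_ids <- vapply(model$metabolites, `[[`, "", "id")
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(met_ids)) {
    bad <- c(bad, paste0("duplicate metabolite ids: ",
                         paste(unique(met_ids[duplicated(met_ids)]),
                               collapse = ", ")))
  }
  if (anyDuplicated(rxn_ids)) {
    bad <- c(bad, paste0("duplicate reaction ids: ",
                         paste(unique(rxn_ids[duplicated(rxn_ids)]),
                               collapse = ", ")))
  }
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing)) {
      bad <- c(bad, paste0("reaction '", r$id,
                           "' references undefined metabolites: ",
                           paste(missing, collapse = ", ")))
    }
    if (r$lower_bound > r$upper_bound) {
      bad <- c(bad, paste0("reaction '", r$id, "': lower_bound > upper_bound"))
    }
    if (r$is_exchange && length(r$stoichiometry) != 1L) {
      bad <- c(bad, paste0("exchange reaction '", r$id,
                           "' touches ", length(r$stoichiometry),
                           " metabolites"))
    }
  }
  for (field in c("biomass_reaction_id", "maintenance_reaction_id")) {
    id <- model[[field]]
    if (!is.null(id)) {
      if (!id %in% rxn_ids) {
        bad <- c(bad, paste0(field, " '", id, "' not in the model"))
      } else if (model$reactions[[id]]$is_exchange) {
        bad <- c(bad, paste0(field, " '", id, "' must be non-exchange"))
      }
    }
  }
  cb <- check_elemental_balance(model)
  if (nrow(cb$imbalanced)) {
    bad <- c(bad, paste0("carbon-imbalanced reactions: ",
                         paste(sprintf("%s (%+g)", cb$imbalanced$reaction_id,
                                       cb$imbalanced$imbalance),
                               collapse = ", ")))
  }
  if (stop_on_error && length(bad)) {
    stop("invalid model '", model$metadata$name, "':\n  ",
         paste(bad, collapse = "\n  "))
  }
  invisible(bad)
}

#' Build the stoichiometric matrix
#'
#' @param model A `metabolic_model`.
#' @return A dense numeric matrix with one row per metabolite and one column
#'   per reaction (entry (i, j) = coefficient of metabolite i in reaction j),
#'   with row and column names giving the index maps.
#' @export
build_stoichiometric_matrix <- function(model) {
  met_ids <- vapply(model$metabolites, `[[`, "", "id")
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (r in model$reactions) {
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  }
  S
}

#' Check elemental (carbon) balance of every reaction
#'
#' Exchange reactions and the designated biomass reaction are exempt from the
#' balance requirement and are reported separately; metabolites with missing
#' carbon counts yield explicit "unknown composition" entries rather than a
#' silent pass.
#'
#' @param model A `metabolic_model`.
#' @param element Element to balance; only `"carbon"` is supported.
#' @param tol Absolute imbalance below which a reaction counts as balanced.
#' @return A list with components `imbalanced` (data frame of reaction_id,
#'   imbalance), `exempt` (character vector of exchange/biomass reaction ids)
#'   and `unknown` (data frame of reaction_id, metabolite_id for metabolites
#'   of unknown composition).
#' @export
check_elemental_balance <- function(model, element = "carbon", tol = 1e-9) {
  element <- match.arg(element, "carbon")
  carbon <- vapply(model$metabolites, `[[`, 0, "carbon_atoms")
  names(carbon) <- vapply(model$metabolites, `[[`, "", "id")
  imb_id <- character(0); imb <- numeric(0)
  exempt <- character(0)
  unk_r <- character(0); unk_m <- character(0)
  for (r in model$reactions) {
    if (r$is_exchange ||
        (!is.null(model$biomass_reaction_id) &&
         r$id == model$biomass_reaction_id)) {
      exempt <- c(exempt, r$id)
      next
    }
    mets <- names(r$stoichiometry)
    known <- mets %in% names(carbon) & !is.na(carbon[mets])
    if (any(!known)) {
      unk_r <- c(unk_r, rep(r$id, sum(!known)))
      unk_m <- c(unk_m, mets[!known])
      next
    }
    d <- sum(r$stoichiometry * carbon[mets])
    if (abs(d) > tol) {
      imb_id <- c(imb_id, r$id)
      imb <- c(imb, d)
    }
  }
  list(imbalanced = data.frame(reaction_id = imb_id, imbalance = imb,
                               stringsAsFactors = FALSE),
       exempt = exempt,
       unknown = data.frame(reaction_id = unk_r, metabolite_id = unk_m,
                            stringsAsFactors = FALSE))
}

#' Find dead-end metabolites
#'
#' A metabolite is a dead end when, taking reaction reversibilities into
#' account, it can only ever be produced or only ever be consumed, and no
#' exchange reaction touches it. Dead ends indicate gaps ("holes") in the
#' network.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of dead-end metabolite ids.
#' @export
find_dead_end_metabolites <- function(model) {
  met_ids <- vapply(model$metabolites, `[[`, "", "id")
  producible <- consumable <- exchanged <-
    stats::setNames(rep(FALSE, length(met_ids)), met_ids)
  for (r in model$reactions) {
    if (r$is_exchange) {
      exchanged[names(r$stoichiometry)] <- TRUE
      next
    }
    fwd <- r$upper_bound > 0
    rev <- r$lower_bound < 0
    for (m in names(r$stoichiometry)) {
      s <- r$stoichiometry[[m]]
      if ((s > 0 && fwd) || (s < 0 && rev)) producible[m] <- TRUE
      if ((s < 0 && fwd) || (s > 0 && rev)) consumable[m] <- TRUE
    }
  }
  touched <- producible | consumable
  dead <- touched & !exchanged & (producible != consumable)
  names(dead)[dead]
}

#' Change flux bounds on a reaction
#'
#' @param model A `metabolic_model`.
#' @param id Reaction id.
#' @param lower_bound,upper_bound New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model (copy; the input is untouched).
#' @export
set_bounds <- function(model, id, lower_bound = NULL, upper_bound = NULL) {
  if (!id %in% names(model$reactions)) {
    stop("no reaction '", id, "' in model '", model$metadata$name, "'")
  }
  r <- model$reactions[[id]]
  if (!is.null(lower_bound)) r$lower_bound <- as.numeric(lower_bound)
  if (!is.null(upper_bound)) r$upper_bound <- as.numeric(upper_bound)
  if (r$lower_bound > r$upper_bound) {
    stop("reaction '", id, "': lower_bound > upper_bound after update")
  }
  model$reactions[[id]] <- r
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  n_ex <- sum(vapply(x$reactions, `[[`, FALSE, "is_exchange"))
  cat("Metabolic model '", x$metadata$name, "' (version ",
      x$metadata$version, ")\n", sep = "")
  cat("  ", length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions (", n_ex, " exchanges)\n", sep = "")
  if (!is.null(x$biomass_reaction_id)) {
    cat("  biomass: ", x$biomass_reaction_id,
        ", maintenance: ", x$maintenance_reaction_id, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  sub <- table(vapply(object$reactions, `[[`, "", "subsystem"))
  print(object)
  cat("  subsystems:\n")
  for (s in names(sub)) cat(sprintf("    %-28s %d\n", s, sub[[s]]))
  invisible(object)
}

## ---- reaction-list (tsv) dialect ------------------------------------------

# numeric -> shortest exact plain-decimal representation (round-trips
# bit-exactly; no scientific notation)
.num_to_chr <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    for (d in 1:17) {
      s <- format(v, digits = d, scientific = FALSE, trim = TRUE)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, "")
}

#' Format a stoichiometry as a reaction equation
#'
#' Uses the package's tabular dialect: `2 A + B -> C`, with `<=>` marking
#' reversible reactions and one empty side for exchange reactions.
#'
#' @param stoichiometry Named numeric vector (negative = consumed).
#' @param reversible Use the `<=>` arrow.
#' @return A single equation string.
#' @export
format_equation <- function(stoichiometry, reversible = FALSE) {
  side <- function(coefs) {
    if (!length(coefs)) return("")
    paste(vapply(names(coefs), function(m) {
      cf <- abs(coefs[[m]])
      if (cf == 1) m else paste(.num_to_chr(cf), m)
    }, ""), collapse = " + ")
  }
  lhs <- side(stoichiometry[stoichiometry < 0])
  rhs <- side(stoichiometry[stoichiometry > 0])
  arrow <- if (reversible) "<=>" else "->"
  trimws(paste(lhs, arrow, rhs))
}

#' Parse a reaction equation
#'
#' @param equation Equation string in the dialect of [format_equation()].
#' @return List with `stoichiometry` (named numeric) and `reversible` flag.
#' @export
parse_equation <- function(equation) {
  arrow <- if (grepl("<=>", equation, fixed = TRUE)) "<=>" else "->"
  if (!grepl(arrow, equation, fixed = TRUE)) {
    stop("equation '", equation, "' has no -> or <=> arrow")
  }
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric(0))
    out <- numeric(0)
    for (term in trimws(strsplit(txt, "+", fixed = TRUE)[[1]])) {
      toks <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(toks) == 1L) {
        cf <- 1; met <- toks
      } else if (length(toks) == 2L) {
        cf <- suppressWarnings(as.numeric(toks[1]))
        met <- toks[2]
        if (is.na(cf)) stop("bad coefficient in term '", term,
                            "' of equation '", equation, "'")
      } else {
        stop("cannot parse term '", term, "' of equation '", equation, "'")
      }
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * cf
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (m in names(rhs)) st[m] <- (if (m %in% names(st)) st[[m]] else 0) + rhs[[m]]
  st <- st[st != 0]
  list(stoichiometry = st, reversible = arrow == "<=>")
}

#' Write a model in the tabular (tsv) dialect
#'
#' One text file with a metabolite table (`id name compartment carbon_atoms`)
#' and a reaction table (`id equation lb ub gpr subsystem`), separated by
#' `# metabolites` / `# reactions` section markers; model metadata in
#' `# metadata` header lines. Numeric values are written with full precision
#' so that a save/load round trip preserves stoichiometry bit-exactly.
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path) {
  lines <- c("# mucaflux model tsv v1",
             paste0("# metadata\tname\t", model$metadata$name),
             paste0("# metadata\tversion\t", model$metadata$version))
  for (f in c("biomass_reaction_id", "maintenance_reaction_id", "objective")) {
    if (!is.null(model[[f]])) {
      lines <- c(lines, paste0("# metadata\t", f, "\t", model[[f]]))
    }
  }
  lines <- c(lines, "# metabolites", "id\tname\tcompartment\tcarbon_atoms")
  for (m in model$metabolites) {
    lines <- c(lines, paste(m$id, m$name, m$compartment,
                            .num_to_chr(m$carbon_atoms), sep = "\t"))
  }
  lines <- c(lines, "# reactions", "id\tequation\tlb\tub\tgpr\tsubsystem")
  for (r in model$reactions) {
    eq <- if (r$is_exchange) {
      paste(names(r$stoichiometry),
            if (r$lower_bound < 0) "<=>" else "->")
    } else {
      format_equation(r$stoichiometry, reversible = r$lower_bound < 0)
    }
    lines <- c(lines, paste(r$id, eq, .num_to_chr(r$lower_bound),
                            .num_to_chr(r$upper_bound), r$gpr, r$subsystem,
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a model from the tabular (tsv) dialect
#'
#' @param path File written by [write_model_tsv()] (or hand-authored in the
#'   same dialect).
#' @param validate Validate the assembled model (default `TRUE`).
#' @return A `metabolic_model`.
#' @export
read_model_tsv <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  meta <- list(name = "model", version = "0")
  extra <- list()
  mets <- list(); rxns <- list()
  section <- ""
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#", "", ln))
      if (startsWith(body, "metadata\t")) {
        kv <- strsplit(body, "\t", fixed = TRUE)[[1]]
        if (kv[2] %in% c("name", "version")) meta[[kv[2]]] <- kv[3]
        else extra[[kv[2]]] <- kv[3]
      } else if (body %in% c("metabolites", "reactions")) {
        section <- body
      }
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (section == "metabolites") {
      if (identical(fields[1], "id")) next  # header row
      if (length(fields) < 4L) {
        stop("line ", i, " of ", path, ": expected 4 metabolite fields, got ",
             length(fields))
      }
      carbon <- suppressWarnings(as.numeric(fields[4]))
      if (is.na(carbon)) stop("line ", i, " of ", path,
                              ": carbon_atoms '", fields[4], "' is not numeric")
      mets[[length(mets) + 1L]] <-
        metabolite(fields[1], fields[2], fields[3], carbon)
    } else if (section == "reactions") {
      if (identical(fields[1], "id")) next
      if (length(fields) < 4L) {
        stop("line ", i, " of ", path, ": expected >= 4 reaction fields, got ",
             length(fields))
      }
      eq <- parse_equation(fields[2])
      lb <- suppressWarnings(as.numeric(fields[3]))
      ub <- suppressWarnings(as.numeric(fields[4]))
      if (is.na(lb) || is.na(ub)) {
        stop("line ", i, " of ", path, ": non-numeric bounds")
      }
      one_sided <- grepl("(^|\\s)(->|<=>)\\s*$", fields[2]) ||
        grepl("^\\s*(->|<=>)", fields[2])
      rxns[[length(rxns) + 1L]] <-
        reaction(fields[1], eq$stoichiometry, lb, ub,
                 gpr = if (length(fields) >= 5L) fields[5] else "",
                 subsystem = if (length(fields) >= 6L) fields[6] else "",
                 is_exchange = one_sided && length(eq$stoichiometry) == 1L)
    } else {
      stop("line ", i, " of ", path, ": data outside a section")
    }
  }
  metabolic_model(mets, rxns,
                  biomass_reaction_id = extra$biomass_reaction_id,
                  maintenance_reaction_id = extra$maintenance_reaction_id,
                  objective = extra$objective, metadata = meta,
                  validate = validate)
}

## ---- SBML -----------------------------------------------------------------

#' Write a model as SBML Level 3 Version 1
#'
#' Flux bounds are encoded as model parameters referenced by each reaction
#' (FBC-style); GPR rules travel in legacy `GENE_ASSOCIATION` notes; carbon
#' content is written as a `C<n>` chemical formula annotation.
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  comp_used <- unique(vapply(model$metabolites, `[[`, "", "compartment"))
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
                  ' level="3" version="1">'),
           sprintf('  <model id="%s" name="%s">',
                   esc(model$metadata$name), esc(model$metadata$name)),
           '    <listOfCompartments>')
  for (cp in comp_used) {
    out <- c(out, sprintf('      <compartment id="%s" constant="true"/>', cp))
  }
  out <- c(out, '    </listOfCompartments>', '    <listOfSpecies>')
  for (m in model$metabolites) {
    out <- c(out, sprintf(paste0('      <species id="%s" name="%s" ',
                                 'compartment="%s" constant="false" ',
                                 'boundaryCondition="false" ',
                                 'hasOnlySubstanceUnits="false" ',
                                 'chemicalFormula="C%s"/>'),
                          esc(m$id), esc(m$name), m$compartment,
                          .num_to_chr(m$carbon_atoms)))
  }
  out <- c(out, '    </listOfSpecies>', '    <listOfParameters>')
  for (r in model$reactions) {
    out <- c(out,
             sprintf('      <parameter id="%s_lb" value="%s" constant="true"/>',
                     esc(r$id), .num_to_chr(r$lower_bound)),
             sprintf('      <parameter id="%s_ub" value="%s" constant="true"/>',
                     esc(r$id), .num_to_chr(r$upper_bound)))
  }
  out <- c(out, '    </listOfParameters>', '    <listOfReactions>')
  for (r in model$reactions) {
    out <- c(out, sprintf(paste0('      <reaction id="%s" reversible="%s" ',
                                 'fast="false" sboTerm="%s">'),
                          esc(r$id),
                          if (r$lower_bound < 0) "true" else "false",
                          if (r$is_exchange) "SBO:0000627" else "SBO:0000176"))
    if (nzchar(r$gpr) || nzchar(r$subsystem)) {
      out <- c(out, '        <notes>',
               '          <body xmlns="http://www.w3.org/1999/xhtml">')
      if (nzchar(r$gpr)) {
        out <- c(out, sprintf('            <p>GENE_ASSOCIATION: %s</p>',
                              esc(r$gpr)))
      }
      if (nzchar(r$subsystem)) {
        out <- c(out, sprintf('            <p>SUBSYSTEM: %s</p>',
                              esc(r$subsystem)))
      }
      out <- c(out, '          </body>', '        </notes>')
    }
    reac <- r$stoichiometry[r$stoichiometry < 0]
    prod <- r$stoichiometry[r$stoichiometry > 0]
    if (length(reac)) {
      out <- c(out, '        <listOfReactants>',
               sprintf(paste0('          <speciesReference species="%s" ',
                              'stoichiometry="%s" constant="true"/>'),
                       esc(names(reac)), .num_to_chr(abs(unname(reac)))),
               '        </listOfReactants>')
    }
    if (length(prod)) {
      out <- c(out, '        <listOfProducts>',
               sprintf(paste0('          <speciesReference species="%s" ',
                              'stoichiometry="%s" constant="true"/>'),
                       esc(names(prod)), .num_to_chr(unname(prod))),
               '        </listOfProducts>')
    }
    out <- c(out, '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(out, path)
  invisible(path)
}

#' Read a model from SBML Level 3 Version 1
#'
#' Understands the subset written by [write_model_sbml()]: core SBML species
#' and reactions, flux bounds as `<id>_lb` / `<id>_ub` parameters (missing
#' bounds default to irreversible 0..1000 / reversible -1000..1000 from the
#' `reversible` attribute), `chemicalFormula` carbon counts, and
#' `GENE_ASSOCIATION` / `SUBSYSTEM` notes.
#'
#' @param path SBML file path.
#' @param validate Validate the assembled model (default `TRUE`).
#' @return A `metabolic_model`.
#' @export
read_model_sbml <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file ", path,
                                           ": ", conditionMessage(e)))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_name(mdl))) stop("no <model> element in ", path)
  meta <- list(name = xml2::xml_attr(mdl, "id"), version = "0")
  if (is.na(meta$name)) meta$name <- "model"

  mets <- lapply(xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns),
    function(sp) {
      formula <- xml2::xml_attr(sp, "chemicalFormula")
      carbon <- if (is.na(formula)) 0 else .formula_carbon(formula)
      nm <- xml2::xml_attr(sp, "name")
      metabolite(xml2::xml_attr(sp, "id"),
                 if (is.na(nm)) xml2::xml_attr(sp, "id") else nm,
                 xml2::xml_attr(sp, "compartment"), carbon)
    })

  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rxns <- lapply(xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns),
    function(rx) {
      id <- xml2::xml_attr(rx, "id")
      rev <- identical(xml2::xml_attr(rx, "reversible"), "true")
      refs <- function(xp, sign) {
        nodes <- xml2::xml_find_all(rx, xp, ns)
        if (!length(nodes)) return(numeric(0))
        stats::setNames(sign * as.numeric(xml2::xml_attr(nodes,
                                                         "stoichiometry")),
                        xml2::xml_attr(nodes, "species"))
      }
      st <- c(refs("./s:listOfReactants/s:speciesReference", -1),
              refs("./s:listOfProducts/s:speciesReference", +1))
      lb <- if (paste0(id, "_lb") %in% names(pval)) pval[[paste0(id, "_lb")]]
            else if (rev) -1000 else 0
      ub <- if (paste0(id, "_ub") %in% names(pval)) pval[[paste0(id, "_ub")]]
            else 1000
      notes <- xml2::xml_text(
        xml2::xml_find_all(rx, ".//*[local-name()='p']"))
      gpr <- sub("^GENE_ASSOCIATION:\\s*", "",
                 grep("^GENE_ASSOCIATION:", notes, value = TRUE))
      sub_ <- sub("^SUBSYSTEM:\\s*", "",
                  grep("^SUBSYSTEM:", notes, value = TRUE))
      sbo <- xml2::xml_attr(rx, "sboTerm")
      reaction(id, st, lb, ub,
               gpr = if (length(gpr)) gpr[1] else "",
               subsystem = if (length(sub_)) sub_[1] else "",
               is_exchange = (length(st) == 1L &&
                              identical(sbo, "SBO:0000627")))
    })
  metabolic_model(mets, rxns, metadata = meta, validate = validate)
}

#' Load a metabolic model
#'
#' @param path File path.
#' @param format `"tsv"` (the package's tabular dialect) or `"sbml"`.
#' @param validate Validate on load (default `TRUE`).
#' @return A `metabolic_model`.
#' @export
load_model <- function(path, format = c("tsv", "sbml"), validate = TRUE) {
  format <- match.arg(format)
  switch(format,
         tsv = read_model_tsv(path, validate = validate),
         sbml = read_model_sbml(path, validate = validate))
}

#' Save a metabolic model
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @param format `"tsv"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  switch(format,
         tsv = write_model_tsv(model, path),
         sbml = write_model_sbml(model, path))
}
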