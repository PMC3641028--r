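# Reaction-level comparison of metabolic models. Reactions from different
# reconstructions are matched by a canonical signature that is invariant to
# metabolite order, written direction and (via an explicit synonym table)
# naming conventions — but deliberately NOT invariant to cofactor swaps:
# NAD- and NADP-linked variants of a reaction count as distinct.

#' Canonical signature of a reaction
#'
#' Metabolite ids are mapped through the synonym table (compartment suffixes
#' may be normalized there too); unmapped ids keep their original id behind
#' an `unmapped:` prefix and set the `flagged` attribute. Coefficients are
#' sorted by metabolite id and the direction is canonicalized by choosing
#' the lexicographically smaller side as the consumed side, so `A + B -> C`
#' and `C -> A + B` share a key.
#'
#' @param rxn A [reaction()].
#' @param id_map Named character vector mapping model-local metabolite ids to
#'   shared ids (identity entries may be omitted only for ids already
#'   shared).
#' @param shared_ids Character vector of ids considered already canonical
#'   (defaults to the map's targets).
#' @return Character scalar key with attribute `flagged` (logical: any
#'   unmapped metabolite).
#' @export
canonical_key <- function(rxn, id_map = character(0),
                          shared_ids = unique(unname(id_map))) {
  mets <- names(rxn$stoichiometry)
  mapped <- ifelse(mets %in% names(id_map), unname(id_map[mets]),
                   ifelse(mets %in% shared_ids, mets,
                          paste0("unmapped:", mets)))
  flagged <- any(startsWith(mapped, "unmapped:"))
  st <- stats::setNames(as.numeric(rxn$stoichiometry), mapped)
  st <- tapply(st, names(st), sum)           # merge synonyms that collide
  st <- st[st != 0]
  if (!length(st)) {
    return(structure("empty", flagged = flagged))
  }
  side_txt <- function(s) {
    s <- s[order(names(s))]
    paste(sprintf("%s:%s", names(s), format(abs(s), digits = 12,
                                            trim = TRUE)),
          collapse = "+")
  }
  lhs <- side_txt(st[st < 0])
  rhs <- side_txt(st[st > 0])
  key <- if (lhs <= rhs) paste(lhs, "=", rhs) else paste(rhs, "=", lhs)
  structure(key, flagged = flagged)
}

#' Reaction-inventory overlap between models
#'
#' Applies the exclusion filters (exchange reactions always; any reaction
#' whose subsystem matches `exclude_subsystems`, e.g. periplasm-diffusion
#' classes), computes canonical keys and counts every Venn region of the
#' shared/unique reaction inventories.
#'
#' @param models Named list of >= 2 `metabolic_model`s.
#' @param id_map Synonym table passed to [canonical_key()].
#' @param exclude_subsystems Character vector of subsystem tags to drop
#'   before comparison.
#' @return List with `regions` (named counts, names like `"A"`, `"A&B"`),
#'   `union_size`, and `flagged` (per model, reactions with unmapped
#'   metabolites).
#' @export
overlap_counts <- function(models, id_map = character(0),
                           exclude_subsystems = character(0)) {
  if (length(models) < 2L) stop("need at least two models to compare")
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- paste0("M", seq_along(models))
  }
  keysets <- lapply(models, function(m) {
    keep <- Filter(function(r) {
      !r$is_exchange && !(r$subsystem %in% exclude_subsystems)
    }, m$reactions)
    keys <- vapply(keep, function(r) as.character(canonical_key(r, id_map)),
                   "")
    flagged <- vapply(keep, function(r) {
      isTRUE(attr(canonical_key(r, id_map), "flagged"))
    }, FALSE)
    list(keys = unique(keys),
         flagged = names(keep)[flagged])
  })
  all_keys <- unique(unlist(lapply(keysets, `[[`, "keys")))
  membership <- vapply(keysets, function(k) all_keys %in% k$keys,
                       logical(length(all_keys)))
  if (!is.matrix(membership)) membership <- matrix(membership, nrow = 1L)
  region_of <- apply(membership, 1L, function(row) {
    paste(names(models)[row], collapse = "&")
  })
  regions <- table(region_of)
  list(regions = stats::setNames(as.integer(regions), names(regions)),
       union_size = length(all_keys),
       flagged = lapply(keysets, `[[`, "flagged"))
}
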