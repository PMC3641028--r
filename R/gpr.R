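# Gene-protein-reaction (GPR) boolean rules: "and" joins subunits of one
# complex, "or" joins isozymes. Rules are parsed into nested lists once and
# evaluated against per-gene expression changes.

#' Parse a GPR rule
#'
#' Grammar: `expr := term ("or" term)*`, `term := factor ("and" factor)*`,
#' `factor := gene | "(" expr ")"`. Operator keywords are case-insensitive.
#'
#' @param rule GPR rule string; empty means no gene association.
#' @return `NULL` for an empty rule, a character scalar for a single gene, or
#'   a nested list `list(op = "and"/"or", args = list(...))`.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || !nzchar(trimws(rule))) return(NULL)
  tokens <- regmatches(rule,
                       gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() {
    t <- tokens[pos]; pos <<- pos + 1L; t
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR rule '", rule, "' ends unexpectedly")
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) {
        stop("unbalanced parentheses in GPR rule '", rule, "'")
      }
      advance()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop("unexpected token '", t, "' in GPR rule '", rule, "'")
    }
    advance()
  }
  out <- parse_expr()
  if (!is.na(peek())) {
    stop("trailing tokens in GPR rule '", rule, "' from '", peek(), "'")
  }
  out
}

#' Genes referenced by a GPR rule
#'
#' @param gpr Parsed rule from [parse_gpr()] (or a rule string).
#' @return Character vector of gene ids (empty for no association).
#' @export
gpr_genes <- function(gpr) {
  if (is.character(gpr) && length(gpr) == 1L) gpr <- parse_gpr(gpr)
  collect <- function(node) {
    if (is.null(node)) return(character(0))
    if (is.character(node)) return(node)
    unique(unlist(lapply(node$args, collect)))
  }
  collect(gpr)
}
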