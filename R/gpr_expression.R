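#' Strip transcript suffixes from gene identifiers
#'
#' Model gene ids may carry a trailing transcript marker of the form
#' `".<digit>"` (e.g. `"SYNPCC7002_A0001.1"`) that is absent from expression
#' datasets. Exactly one terminal `.<single digit>` is removed; multi-digit
#' suffixes are outside the stated pattern and left intact.
#'
#' @param ids character vector of gene identifiers.
#' @return character vector with suffixes stripped.
#' @export
truncate_gene_ids <- function(ids) {
  sub("[.][0-9]$", "", ids)
}

# --- GPR rule parser -------------------------------------------------------
# Grammar (AND binds tighter than OR, matching "the MINs must be calculated
# before the MAXs"):
#   rule   := term ('or' term)*
#   term   := factor ('and' factor)*
#   factor := gene | '(' rule ')'
# Expression trees are nested lists: list(op = "min"/"max", args = list(...))
# with character leaves; the constant numeric 1 stands for an empty rule.

gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_parse <- function(rule, rxn = "?") {
  toks <- gpr_tokenize(rule)
  if (!length(toks)) return(1)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  is_op <- function(t) !is.na(t) && tolower(t) %in% c("and", "or", "(", ")")
  parse_rule <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1) args[[1]] else list(op = "max", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1) args[[1]] else list(op = "min", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t))
      stop("GPR compile error in reaction ", rxn, ": unexpected end of rule")
    if (t == "(") {
      advance()
      inner <- parse_rule()
      if (is.na(peek()) || peek() != ")")
        stop("GPR compile error in reaction ", rxn, ": unbalanced parentheses")
      advance()
      return(inner)
    }
    if (is_op(t))
      stop("GPR compile error in reaction ", rxn, ": unexpected token '", t, "'")
    advance()
  }
  expr <- parse_rule()
  if (pos <= length(toks))
    stop("GPR compile error in reaction ", rxn, ": trailing token '", toks[pos], "'")
  expr
}

#' Compile GPR rules into MIN/MAX expression trees
#'
#' Each reaction's boolean gene rule is parsed into an expression tree whose
#' leaves are gene identifiers; AND nodes evaluate as MIN and OR nodes as MAX
#' over gene expression values. AND binds tighter than OR and source
#' parentheses are honored. Reactions with empty rules carry the constant
#' expression 1 (their bounds are never rescaled).
#'
#' @param model a [metabolic_model()] with `grRules`.
#' @return A `reaction_expression_map`: list with `expressions` (per-reaction
#'   trees), `gene_positions` (per-reaction integer indices into
#'   `model$genes`), and `genes_by_length` (gene ids sorted by decreasing
#'   length, kept as a compatibility field for string-substitution pipelines).
#' @export
compile_reaction_expressions <- function(model) {
  exprs <- vector("list", length(model$grRules))
  gene_positions <- vector("list", length(model$grRules))
  for (j in seq_along(model$grRules)) {
    exprs[[j]] <- gpr_parse(model$grRules[j], rxn = model$rxns[j])
    leaves <- gpr_leaves(exprs[[j]])
    unknown <- setdiff(leaves, model$genes)
    if (length(unknown))
      stop("GPR compile error in reaction ", model$rxns[j],
           ": unknown gene(s) ", paste(unknown, collapse = ", "))
    gene_positions[[j]] <- match(leaves, model$genes)
  }
  out <- list(expressions = exprs, gene_positions = gene_positions,
              genes_by_length = model$genes[order(-nchar(model$genes))])
  class(out) <- "reaction_expression_map"
  out
}

gpr_leaves <- function(expr) {
  if (is.character(expr)) return(expr)
  if (is.numeric(expr)) return(character())
  unique(unlist(lapply(expr$args, gpr_leaves)))
}

#' Map an expression profile onto model genes
#'
#' Builds the gene value vector `x` (length = number of model genes): all
#' ones, then each model gene whose suffix-truncated id matches a profile id
#' takes the profile's fold-change value. Unmatched model genes keep the
#' neutral value 1; profile genes absent from the model are ignored.
#'
#' @param model a [metabolic_model()].
#' @param profile named numeric vector, names = dataset gene ids.
#' @return numeric vector `x`, named by model gene id.
#' @export
map_profile_to_model <- function(model, profile) {
  if (anyDuplicated(names(profile)))
    stop("duplicate profile gene ids: ",
         paste(unique(names(profile)[duplicated(names(profile))]), collapse = ", "))
  x <- stats::setNames(rep(1, length(model$genes)), model$genes)
  pos <- match(truncate_gene_ids(model$genes), names(profile))
  hit <- !is.na(pos)
  x[hit] <- as.numeric(profile[pos[hit]])
  x
}

#' Evaluate a compiled reaction expression
#'
#' Recursive evaluation of the MIN/MAX tree against a gene value vector:
#' AND nodes take the minimum of their arguments, OR nodes the maximum.
#' The constant expression (empty rule) returns 1.
#'
#' @param expr an expression tree from [compile_reaction_expressions()].
#' @param x named numeric gene value vector (names = model gene ids).
#' @return the reaction expression level theta (scalar).
#' @export
evaluate_reaction_expression <- function(expr, x) {
  if (is.numeric(expr)) return(expr)
  if (is.character(expr)) {
    if (!expr %in% names(x))
      stop("evaluation error: gene '", expr, "' not in value vector")
    return(unname(x[[expr]]))
  }
  vals <- vapply(expr$args, evaluate_reaction_expression, 0, x = x)
  if (expr$op == "min") min(vals) else max(vals)
}

#' Evaluate all reaction expression levels
#'
#' @param rmap a `reaction_expression_map`.
#' @param x named numeric gene value vector.
#' @return numeric vector of theta values, one per reaction.
#' @export
evaluate_all_expressions <- function(rmap, x) {
  vapply(rmap$expressions, evaluate_reaction_expression, 0, x = x)
}
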