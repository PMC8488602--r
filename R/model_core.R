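#' Metabolic model container
#'
#' A `metabolic_model` is a plain list mirroring the fields of a COBRA-style
#' genome-scale model: stoichiometric matrix `S` (metabolites x reactions),
#' per-reaction flux bounds `lb`/`ub` (mmol/gDW/h), identifiers (`rxns`,
#' `rxnNames`, `mets`, `genes`), boolean gene-protein-reaction rule strings
#' (`grRules`), per-reaction subsystem annotations (`subSystems`, a list of
#' character vectors since a reaction may belong to several pathways), and two
#' binary indicator vectors `f` and `g` selecting the primary and secondary
#' flux objectives of the bi-level optimization.
#'
#' @param S numeric matrix, metabolites x reactions.
#' @param lb,ub numeric vectors of flux bounds, one entry per reaction.
#' @param rxns,rxnNames character vectors of reaction ids and display names.
#' @param mets character vector of metabolite ids.
#' @param genes character vector of gene ids (model form, possibly carrying a
#'   trailing ".<digit>" transcript suffix).
#' @param grRules character vector of GPR rule strings ("" when none).
#' @param subSystems list of character vectors of subsystem names.
#' @param f,g binary indicator vectors for the primary/secondary objectives.
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(S, lb, ub, rxns, rxnNames = rxns, mets = rownames(S),
                            genes = character(), grRules = NULL,
                            subSystems = NULL, f = NULL, g = NULL) {
  S <- as.matrix(S)
  n <- ncol(S)
  if (is.null(grRules)) grRules <- rep("", n)
  if (is.null(subSystems)) subSystems <- rep(list("Unassigned"), n)
  if (is.null(f)) f <- numeric(n)
  if (is.null(g)) g <- numeric(n)
  if (!is.list(subSystems)) subSystems <- as.list(subSystems)
  model <- list(S = S, lb = as.numeric(lb), ub = as.numeric(ub),
                rxns = as.character(rxns), rxnNames = as.character(rxnNames),
                mets = as.character(mets), genes = as.character(genes),
                grRules = as.character(grRules), subSystems = subSystems,
                f = as.numeric(f), g = as.numeric(g))
  class(model) <- "metabolic_model"
  validate_model(model)
  model
}

validate_model <- function(model) {
  n <- ncol(model$S)
  m <- nrow(model$S)
  stopifnot(length(model$mets) == m)
  for (fld in c("lb", "ub", "rxns", "rxnNames", "grRules", "f", "g")) {
    if (length(model[[fld]]) != n)
      stop(sprintf("field '%s' has length %d, expected %d (reaction count)",
                   fld, length(model[[fld]]), n))
  }
  if (length(model$subSystems) != n)
    stop("subSystems must have one entry per reaction")
  if (any(model$lb > model$ub))
    stop("lb > ub for reaction(s): ",
         paste(model$rxns[model$lb > model$ub], collapse = ", "))
  if (sum(model$f == 1) > 1 || sum(model$g == 1) > 1)
    stop("f and g must each contain at most one 1")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites x %d reactions, %d genes\n",
              nrow(x$S), ncol(x$S), length(x$genes)))
  if (any(x$f == 1))
    cat("  primary objective  (f):", x$rxns[x$f == 1], "\n")
  if (any(x$g == 1))
    cat("  secondary objective(g):", x$rxns[x$g == 1], "\n")
  invisible(x)
}

#' Read a metabolic model
#'
#' Reads either the package's delimited toy-table format (a directory holding
#' `reactions.tsv` and `genes.tsv`) or an SBML Level 3 file. Missing GPR rules
#' become empty strings and freshly created objective indicator vectors `f`/`g`
#' are all zero.
#'
#' The toy-table `reactions.tsv` has columns `id`, `name`, `equation` (e.g.
#' `"2 atp + co2 -> c3"`; `<->` marks reversibility but bounds govern), `lb`,
#' `ub`, `grRule`, and `subsystems` (`;`-joined). `genes.tsv` has column `id`.
#'
#' @param path file (SBML) or directory (toy-table) path.
#' @param format `"toy-table"` or `"sbml"`.
#' @return A [metabolic_model()].
#' @export
read_model <- function(path, format = c("toy-table", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  switch(format,
         "toy-table" = read_toy_table(path),
         "sbml" = read_sbml(path))
}

read_toy_table <- function(dir) {
  rfile <- file.path(dir, "reactions.tsv")
  gfile <- file.path(dir, "genes.tsv")
  if (!file.exists(rfile)) stop("toy-table parse error: missing ", rfile)
  rx <- utils::read.delim(rfile, stringsAsFactors = FALSE, quote = "")
  need <- c("id", "name", "equation", "lb", "ub", "grRule", "subsystems")
  missing_cols <- setdiff(need, names(rx))
  if (length(missing_cols))
    stop("toy-table parse error: reactions.tsv lacks column(s) ",
         paste(missing_cols, collapse = ", "))
  genes <- character()
  if (file.exists(gfile))
    genes <- utils::read.delim(gfile, stringsAsFactors = FALSE, quote = "")$id
  eqs <- lapply(rx$equation, parse_reaction_equation)
  mets <- unique(unlist(lapply(eqs, names)))
  S <- matrix(0, length(mets), nrow(rx), dimnames = list(mets, rx$id))
  for (j in seq_along(eqs)) S[names(eqs[[j]]), j] <- eqs[[j]]
  gr <- rx$grRule
  gr[is.na(gr)] <- ""
  subs <- strsplit(ifelse(is.na(rx$subsystems) | rx$subsystems == "",
                          "Unassigned", rx$subsystems), ";", fixed = TRUE)
  subs <- lapply(subs, trimws)
  metabolic_model(S, rx$lb, rx$ub, rx$id, rx$name, mets, genes, gr, subs)
}

# "2 atp + co2 -> c3 + 0.5 o2"  ->  named coefficient vector
parse_reaction_equation <- function(eq) {
  if (is.na(eq) || !nzchar(trimws(eq)))
    stop("toy-table parse error: empty reaction equation")
  sides <- strsplit(eq, "<->|<=>|->|=>", perl = TRUE)[[1]]
  if (length(sides) > 2)
    stop("toy-table parse error: malformed equation '", eq, "'")
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric())
    out <- numeric()
    for (term in trimws(strsplit(s, "+", fixed = TRUE)[[1]])) {
      if (!nzchar(term)) next
      toks <- strsplit(term, "\\s+")[[1]]
      if (length(toks) == 1) {
        coef <- 1; met <- toks[1]
      } else if (length(toks) == 2 && !is.na(suppressWarnings(as.numeric(toks[1])))) {
        coef <- as.numeric(toks[1]); met <- toks[2]
      } else stop("toy-table parse error: malformed term '", term, "'")
      out[met] <- (if (met %in% names(out)) out[met] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- if (length(sides) == 2) parse_side(sides[2], +1) else numeric()
  for (met in names(rhs)) lhs[met] <- (if (met %in% names(lhs)) lhs[met] else 0) + rhs[met]
  lhs
}

#' Write a model in the toy-table format
#'
#' Inverse of [read_model()] for the toy-table format; writing then reading
#' reproduces all fields exactly.
#'
#' @param model a [metabolic_model()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_table <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_eq <- function(j) {
    s <- model$S[, j]
    fmt <- function(idx) paste(
      vapply(idx, function(i) {
        co <- abs(s[i])
        if (co == 1) model$mets[i]
        else paste(format(co, scientific = FALSE, trim = TRUE), model$mets[i])
      }, ""), collapse = " + ")
    lhs <- which(s < 0); rhs <- which(s > 0)
    paste(fmt(lhs), "->", fmt(rhs))
  }
  rx <- data.frame(
    id = model$rxns, name = model$rxnNames,
    equation = vapply(seq_len(ncol(model$S)), fmt_eq, ""),
    lb = model$lb, ub = model$ub, grRule = model$grRules,
    subsystems = vapply(model$subSystems, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(id = model$genes), file.path(dir, "genes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

# Minimal SBML L3 (+fbc) reader: species, reactions with stoichiometry,
# fbc bounds as plain parameters, geneProductAssociation left as grRules text
# when encoded in notes or fbc:geneProductRef trees.
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error: ", conditionMessage(e)))
  ns <- xml2::xml_ns(doc)
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  mets <- xml2::xml_attr(sp, "id")
  if (!length(mets)) stop("SBML parse error: no species elements found")
  params <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rxn_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (!length(rxn_nodes)) stop("SBML parse error: no reaction elements found")
  n <- length(rxn_nodes)
  S <- matrix(0, length(mets), n, dimnames = list(mets, NULL))
  lb <- numeric(n); ub <- numeric(n)
  rxns <- character(n); rxnNames <- character(n); gr <- character(n)
  for (j in seq_len(n)) {
    node <- rxn_nodes[[j]]
    rxns[j] <- xml2::xml_attr(node, "id")
    nm <- xml2::xml_attr(node, "name")
    rxnNames[j] <- if (is.na(nm)) rxns[j] else nm
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        node, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      sgn <- if (side == "listOfReactants") -1 else 1
      for (ref in refs) {
        met <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (!met %in% mets) stop("SBML parse error: unknown species '", met, "'")
        S[met, j] <- S[met, j] + sgn * st
      }
    }
    lbref <- xml2::xml_attr(node, "lowerFluxBound")
    ubref <- xml2::xml_attr(node, "upperFluxBound")
    lb[j] <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]]
             else if (rev) -1000 else 0
    ub[j] <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]] else 1000
    gpa <- xml2::xml_find_first(node, ".//*[local-name()='geneProductAssociation']")
    gr[j] <- if (inherits(gpa, "xml_missing")) "" else sbml_gpa_to_rule(gpa)
  }
  gp <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  genes <- xml2::xml_attr(gp, "label")
  genes <- genes[!is.na(genes)]
  colnames(S) <- rxns
  metabolic_model(S, lb, ub, rxns, rxnNames, mets, genes, gr)
}

sbml_gpa_to_rule <- function(node) {
  recurse <- function(nd) {
    nm <- xml2::xml_name(nd)
    if (nm == "geneProductRef") {
      lab <- xml2::xml_attr(nd, "label")
      if (is.na(lab)) lab <- xml2::xml_attr(nd, "geneProduct")
      return(lab)
    }
    kids <- xml2::xml_children(nd)
    parts <- vapply(kids, recurse, "")
    if (nm == "and") paste0("(", paste(parts, collapse = " and "), ")")
    else if (nm == "or") paste0("(", paste(parts, collapse = " or "), ")")
    else if (length(parts) == 1) parts
    else paste(parts, collapse = " ")
  }
  kids <- xml2::xml_children(node)
  if (!length(kids)) return("")
  recurse(kids[[1]])
}

# Synonym table applied by normalize_subsystem_names(); collapses the naming
# variants observed for amino-acid metabolism, exchange, lipid/cell-wall and
# unannotated reactions.
subsystem_synonyms <- c(
  "Amino Acid Metabolisms" = "Amino acid metabolism",
  "Amino Acid Metabolism" = "Amino acid metabolism",
  "Exchange Reaction" = "Exchange",
  "Lipid and Cell Wall Metabolism" = "Lipid metabolism and Cell wall",
  "None" = "Unassigned",
  "Other" = "Unassigned")

#' Normalize subsystem names
#'
#' Applies the curation synonym table (merging spelling variants of amino acid
#' metabolism, exchange, lipid/cell-wall annotations; mapping
#' `'None'`/`'Other'`/empty to `'Unassigned'`). Idempotent.
#'
#' @param model a [metabolic_model()].
#' @return The model with curated `subSystems`.
#' @export
normalize_subsystem_names <- function(model) {
  model$subSystems <- lapply(model$subSystems, function(ss) {
    ss <- as.character(ss)
    ss[is.na(ss) | !nzchar(trimws(ss))] <- "Unassigned"
    hit <- ss %in% names(subsystem_synonyms)
    ss[hit] <- unname(subsystem_synonyms[ss[hit]])
    ss
  })
  model
}

# Names whose own 'and' must survive splitting: rewritten with '&' first.
protected_and_names <- c(
  "Metabolism of terpenoids and polyketides" = "Metabolism of terpenoids & polyketides",
  "Metabolism of cofactors and vitamins" = "Metabolism of cofactors & vitamins",
  "Coenzymes and prosthetic groups" = "Coenzymes & prosthetic groups",
  "Glycan biosynthesis and metabolism" = "Glycan biosynthesis & metabolism",
  "Nucleotides and nucleic acids" = "Nucleotides & nucleic acids")

#' Split multi-subsystem annotations
#'
#' Annotation strings that pack several pathways into one name joined by the
#' word `and` are split into separate subsystem entries. Names whose own
#' wording contains `and` (e.g. "Metabolism of terpenoids and polyketides")
#' are protected by rewriting with `&` before the split. The split is a
#' case-insensitive word-boundary match, so names like "Island" are never cut.
#' Fragments are trimmed, empty fragments dropped, and reactions left with no
#' name get `"Unassigned"`.
#'
#' @param model a [metabolic_model()] (after [normalize_subsystem_names()]).
#' @return The model with per-reaction subsystem vectors.
#' @export
split_multi_subsystems <- function(model) {
  model$subSystems <- lapply(model$subSystems, function(ss) {
    ss <- as.character(ss)
    hit <- ss %in% names(protected_and_names)
    ss[hit] <- unname(protected_and_names[ss[hit]])
    parts <- unlist(strsplit(ss, "(?i)\\band\\b", perl = TRUE))
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    if (!length(parts)) parts <- "Unassigned"
    parts
  })
  model
}

#' Select the objective pair
#'
#' Sets the one-hot indicator vectors `f` (primary) and `g` (secondary) by
#' reaction name, clearing any previous selection. In the protocol the primary
#' objective is the biomass reaction and the secondary is switched between ATP
#' maintenance and the two photosystem reactions.
#'
#' @param model a [metabolic_model()].
#' @param primary_name,secondary_name reaction names (matched against
#'   `rxnNames`, falling back to `rxns`).
#' @return The model with `f` and `g` set.
#' @export
set_objective_pair <- function(model, primary_name, secondary_name) {
  find1 <- function(nm) {
    ix <- which(model$rxnNames == nm)
    if (!length(ix)) ix <- which(model$rxns == nm)
    if (!length(ix)) stop("no reaction named '", nm, "'")
    if (length(ix) > 1) stop("reaction name '", nm, "' is not unique")
    ix
  }
  ip <- find1(primary_name); is <- find1(secondary_name)
  if (ip == is) stop("primary and secondary objectives must differ")
  model$f <- numeric(ncol(model$S)); model$f[ip] <- 1
  model$g <- numeric(ncol(model$S)); model$g[is] <- 1
  model
}

objective_pair_indices <- function(model) {
  list(primary = which(model$f == 1), secondary = which(model$g == 1))
}

#' Build the subsystem membership index
#'
#' Produces, for each unique subsystem name, the member reaction indices and
#' the cardinality (reactions per subsystem). A reaction annotated with k
#' subsystems appears in k membership entries, mirroring the multi-membership
#' indexing used by pathway-level aggregation.
#'
#' @param model a [metabolic_model()] after [split_multi_subsystems()].
#' @return A list with `names` (sorted unique subsystem names), `membership`
#'   (named list of integer vectors) and `cardinality` (named integer vector);
#'   class `subsystem_index`.
#' @export
build_subsystem_index <- function(model) {
  nms <- sort(unique(unlist(model$subSystems)))
  membership <- lapply(nms, function(s)
    which(vapply(model$subSystems, function(ss) s %in% ss, TRUE)))
  names(membership) <- nms
  idx <- list(names = nms, membership = membership,
              cardinality = vapply(membership, length, 0L))
  class(idx) <- "subsystem_index"
  idx
}
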