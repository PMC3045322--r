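## Delimited tabular export of reaction and metabolite lists.

#' Human-readable equation text of a reaction
#'
#' Terms are `stoich abbr[compartment]` (the coefficient omitted when 1),
#' joined by `+`, sides separated by `<=>` (reversible) or `=>`.
#'
#' @param rxn Reaction record or abbreviation.
#' @param model The model resolving it (only needed when `rxn` is an
#'   abbreviation).
#' @return Single equation string.
#' @export
#' @examples
#' r <- reaction("r1", reactants = rbind(
#'   reactants("h2", 2, "c", "substrate"),
#'   reactants("o2", 1, "c", "substrate"),
#'   reactants("h2o", 2, "c", "product")))
#' formatEquation(r)
formatEquation <- function(rxn, model = NULL) {
  if (is.character(rxn)) rxn <- getReaction(model, rxn)
  df <- rxn$reactants
  term <- function(k) {
    s <- df$stoichiometry[k]
    paste0(if (s != 1) paste0(fmtNum(s), " ") else "",
           df$metabolite[k], "[", df$compartment[k], "]")
  }
  side <- function(which) {
    ks <- which(df$side == which)
    if (length(ks) == 0L) "" else paste(vapply(ks, term, character(1)), collapse = " + ")
  }
  paste0(side("substrate"), if (rxn$reversible) " <=> " else " => ", side("product"))
}

#' Parse equation text back into a reactant table
#'
#' Inverse of [formatEquation()]: accepts `<=>`/`=>` separators and
#' `stoich abbr[compartment]` terms with an optional coefficient.
#'
#' @param text Equation string.
#' @return List with `reactants` (a reactant table) and `reversible`.
#' @export
parseEquation <- function(text) {
  reversible <- grepl("<=>", text, fixed = TRUE)
  parts <- strsplit(text, if (reversible) "<=>" else "=>", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    gsmvParseError("equation must have exactly one '=>' or '<=>': %s", text)
  parseSide <- function(txt, side) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(emptyReactants())
    terms <- trimws(strsplit(txt, " + ", fixed = TRUE)[[1]])
    rows <- lapply(terms, function(tm) {
      m <- regexec("^(?:([0-9]+(?:\\.[0-9]+)?)\\s+)?(\\S+)\\[([^\\]]+)\\]$", tm,
                   perl = TRUE)
      g <- regmatches(tm, m)[[1]]
      if (length(g) == 0L)
        gsmvParseError("cannot parse equation term '%s'", tm)
      reactants(g[3], if (nzchar(g[2])) as.numeric(g[2]) else 1, g[4], side)
    })
    do.call(rbind, rows)
  }
  df <- rbind(parseSide(parts[1], "substrate"), parseSide(parts[2], "product"))
  rownames(df) <- NULL
  list(reactants = df, reversible = reversible)
}

#' Export an entity list as a delimited table
#'
#' One row per entity with a fixed, documented column set: for reactions
#' `abbreviation`, `name`, `equation`, `ec_number`, `kegg_id`, `subsystem`;
#' for metabolites `abbreviation`, `name`, `formula`, `chebi_id`, `kegg_id`.
#'
#' @param entities List of reaction or metabolite records (all of one kind),
#'   or a character vector of abbreviations resolved in `model`.
#' @param kind `"reactions"` or `"metabolites"`.
#' @param model The model resolving abbreviations and equations.
#' @param file Optional path; when given the table is written as TSV
#'   (UTF-8, header + one row per entity) and the path returned invisibly.
#' @param sep Field separator for file output.
#' @return The table as a data.frame (invisibly when `file` is given).
#' @export
exportTable <- function(entities, kind = c("reactions", "metabolites"),
                        model = NULL, file = NULL, sep = "\t") {
  kind <- match.arg(kind)
  if (is.character(entities)) {
    if (is.null(model)) gsmvArgError("resolving abbreviations requires a model")
    entities <- lapply(entities, function(ab)
      if (kind == "reactions") getReaction(model, ab) else getMetabolite(model, ab))
  }
  expected <- if (kind == "reactions") "gsmReaction" else "gsmMetabolite"
  ok <- vapply(entities, inherits, logical(1), expected)
  if (!all(ok))
    gsmvArgError("all entities must be %s records (element %d is not)",
                 sub("^gsm", "", tolower(expected)), which(!ok)[1])

  if (kind == "reactions") {
    tab <- data.frame(
      abbreviation = vapply(entities, function(r) r$abbreviation, character(1)),
      name = vapply(entities, function(r) r$name, character(1)),
      equation = vapply(entities, function(r) formatEquation(r), character(1)),
      ec_number = vapply(entities, function(r) r$ecNumber %||% "", character(1)),
      kegg_id = vapply(entities, function(r) r$keggId %||% "", character(1)),
      subsystem = vapply(entities, function(r) r$subsystem %||% "", character(1)),
      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(
      abbreviation = vapply(entities, function(m) m$abbreviation, character(1)),
      name = vapply(entities, function(m) m$name, character(1)),
      formula = vapply(entities, function(m) m$formula %||% "", character(1)),
      chebi_id = vapply(entities, function(m) m$chebiId %||% "", character(1)),
      kegg_id = vapply(entities, function(m) m$keggId %||% "", character(1)),
      stringsAsFactors = FALSE)
  }
  if (length(entities) == 0L) tab <- tab[0, , drop = FALSE]
  if (!is.null(file)) {
    utils::write.table(tab, file, sep = sep, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
    return(invisible(tab))
  }
  tab
}
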