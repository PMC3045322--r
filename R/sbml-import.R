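## SBML import.
##
## Accepts SBML Level 2 (any version) and Level 3 core. XPath is
## namespace-agnostic (local-name matching) so documents from different SBML
## dialects parse uniformly. Species carrying a compartment-suffixed id
## (abbr_comp, the usual convention of compartmentalized exports) are folded
## back into one metabolite per base abbreviation.

xpathAll <- function(node, localName) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", localName))
}

xpathFirst <- function(node, localName) {
  xml2::xml_find_first(node, sprintf(".//*[local-name()='%s']", localName))
}

childrenNamed <- function(node, localName) {
  xml2::xml_find_all(node, sprintf("./*[local-name()='%s']", localName))
}

attrOr <- function(node, attr, default = NULL) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else v
}

## "KEY: value" lines from an SBML notes block.
parseNotesLines <- function(node) {
  notes <- childrenNamed(node, "notes")
  if (length(notes) == 0L) return(character(0))
  txt <- xml2::xml_text(xml2::xml_find_all(notes[[1]], ".//text()"))
  txt <- trimws(txt)
  txt[nzchar(txt)]
}

notesValue <- function(lines, key) {
  pat <- paste0("^", key, ":\\s*")
  hit <- grep(pat, lines)
  if (length(hit) == 0L) return(NULL)
  sub(pat, "", lines[hit[1]])
}

notesValues <- function(lines, key) {
  pat <- paste0("^", key, ":\\s*")
  sub(pat, "", lines[grep(pat, lines)])
}

## MIRIAM URNs attached to one element (direct annotation child only).
annotationURNs <- function(node) {
  ann <- childrenNamed(node, "annotation")
  if (length(ann) == 0L) return(character(0))
  li <- xml2::xml_find_all(ann[[1]], ".//*[local-name()='li']")
  res <- xml2::xml_attr(li, "resource")
  res[!is.na(res)]
}

## Split URNs into known fields vs. passthrough annotations.
splitURNs <- function(urns, wanted) {
  fields <- list()
  rest <- character(0)
  for (u in urns) {
    ref <- tryCatch(parseMiriam(u), error = function(e) NULL)
    if (!is.null(ref) && ref$datatype %in% names(wanted) &&
        is.null(fields[[wanted[[ref$datatype]]]])) {
      fields[[wanted[[ref$datatype]]]] <- ref$identifier
    } else {
      rest <- c(rest, if (is.null(ref)) u else miriamURN(ref$datatype, ref$identifier))
    }
  }
  list(fields = fields, annotations = rest)
}

parseGeneNotesLine <- function(line) {
  parts <- trimws(strsplit(line, ";", fixed = TRUE)[[1]])
  abbr <- parts[1]
  kv <- list()
  for (p in parts[-1]) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq > 0L) kv[[substr(p, 1L, eq - 1L)]] <- substr(p, eq + 1L, nchar(p))
  }
  gene(abbr,
       name = kv$NAME %||% abbr,
       ecNumber = kv$EC, keggId = kv$KEGG, uniprotId = kv$UNIPROT,
       annotations = if (!is.null(kv$ANNOTATIONS))
         strsplit(kv$ANNOTATIONS, " ", fixed = TRUE)[[1]] else character(0))
}

#' Import a model from SBML
#'
#' Reads compartments (with their outside/parent relations), species
#' (formula, charge, ChEBI and KEGG references from notes and MIRIAM
#' annotations), reactions (reversibility, explicit stoichiometry,
#' EC/KEGG annotations, `GENE_ASSOCIATION` and `SUBSYSTEM` notes) and gene
#' metadata from model-level `GENE` notes lines; genes referenced by GPRs but
#' not described in notes are created from their abbreviation with a warning
#' in the report.
#'
#' @param x Path to an SBML file, or a single string containing the document.
#' @return List with `model` (a [MetabolicModel-class]) and `report`
#'   (entity counts, source level/version, character vector of warnings).
#' @export
importSBML <- function(x) {
  doc <- tryCatch({
    if (length(x) == 1L && !grepl("<", x, fixed = TRUE) && file.exists(x))
      xml2::read_xml(x)
    else xml2::read_xml(paste(x, collapse = "\n"))
  }, error = function(e) gsmvParseError("malformed SBML document: %s", conditionMessage(e)))

  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml")
    gsmvParseError("not an SBML document (root element '%s')", xml2::xml_name(root))
  level <- attrOr(root, "level", "?")
  version <- attrOr(root, "version", "?")
  modelNode <- xpathFirst(root, "model")
  if (inherits(modelNode, "xml_missing"))
    gsmvParseError("SBML document has no model element")

  warningsOut <- character(0)
  modelLines <- parseNotesLines(modelNode)
  modelURNs <- annotationURNs(modelNode)

  ## compartments
  comps <- list()
  compNodes <- xml2::xml_find_all(modelNode,
    "./*[local-name()='listOfCompartments']/*[local-name()='compartment']")
  for (nd in compNodes) {
    cid <- attrOr(nd, "id")
    comps[[cid]] <- compartment(cid, name = attrOr(nd, "name", cid),
                                parentId = attrOr(nd, "outside"),
                                annotations = annotationURNs(nd))
  }

  ## species -> metabolites (fold compartment-suffixed ids)
  mets <- list()
  species2met <- character(0)
  spNodes <- xml2::xml_find_all(modelNode,
    "./*[local-name()='listOfSpecies']/*[local-name()='species']")
  for (nd in spNodes) {
    sid <- attrOr(nd, "id")
    comp <- attrOr(nd, "compartment", "")
    abbr <- if (nzchar(comp) && endsWith(sid, paste0("_", comp)))
      substr(sid, 1L, nchar(sid) - nchar(comp) - 1L) else sid
    species2met[[sid]] <- abbr
    if (!is.null(mets[[abbr]])) next
    lines <- parseNotesLines(nd)
    sp <- splitURNs(annotationURNs(nd),
                    c("chebi" = "chebiId", "kegg.compound" = "keggId"))
    chargeTxt <- notesValue(lines, "CHARGE") %||% attrOr(nd, "charge")
    mets[[abbr]] <- metabolite(abbr, name = attrOr(nd, "name", abbr),
      formula = notesValue(lines, "FORMULA"),
      charge = if (!is.null(chargeTxt)) as.integer(chargeTxt) else NULL,
      chebiId = sp$fields$chebiId, keggId = sp$fields$keggId,
      annotations = sp$annotations)
  }
  species2comp <- stats::setNames(
    vapply(spNodes, function(nd) attrOr(nd, "compartment", ""), character(1)),
    vapply(spNodes, function(nd) attrOr(nd, "id"), character(1)))

  ## genes from model notes
  gns <- list()
  for (line in notesValues(modelLines, "GENE")) {
    g <- parseGeneNotesLine(line)
    gns[[g$abbreviation]] <- g
  }

  ## reactions
  rxns <- list()
  badRefs <- character(0)
  rxNodes <- xml2::xml_find_all(modelNode,
    "./*[local-name()='listOfReactions']/*[local-name()='reaction']")
  for (nd in rxNodes) {
    rid <- attrOr(nd, "id")
    lines <- parseNotesLines(nd)
    rp <- splitURNs(annotationURNs(nd),
                    c("ec-code" = "ecNumber", "kegg.reaction" = "keggId"))
    readSide <- function(listName, side) {
      refs <- xml2::xml_find_all(nd, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", listName))
      if (length(refs) == 0L) return(emptyReactants())
      out <- lapply(refs, function(ref) {
        sid <- attrOr(ref, "species", "")
        if (!(sid %in% names(species2met))) {
          badRefs <<- c(badRefs, sprintf("%s -> %s", rid, sid))
          return(NULL)
        }
        reactants(species2met[[sid]],
                  as.numeric(attrOr(ref, "stoichiometry", "1")),
                  species2comp[[sid]], side)
      })
      out <- Filter(Negate(is.null), out)
      if (length(out)) do.call(rbind, out) else emptyReactants()
    }
    df <- rbind(readSide("listOfReactants", "substrate"),
                readSide("listOfProducts", "product"))
    rownames(df) <- NULL
    gprTxt <- notesValue(lines, "GENE_ASSOCIATION")
    gpr <- if (!is.null(gprTxt) && nzchar(gprTxt)) parseGPR(gprTxt) else NULL
    citTxt <- notesValue(lines, "CITATIONS")
    rxns[[rid]] <- reaction(rid, name = attrOr(nd, "name", rid),
      reactants = df,
      reversible = !identical(attrOr(nd, "reversible", "true"), "false"),
      ecNumber = rp$fields$ecNumber, keggId = rp$fields$keggId,
      subsystem = notesValue(lines, "SUBSYSTEM"), gpr = gpr,
      enzyme = notesValue(lines, "ENZYME"), orf = notesValue(lines, "ORF"),
      citations = if (!is.null(citTxt))
        trimws(strsplit(citTxt, ";", fixed = TRUE)[[1]]) else character(0),
      annotations = rp$annotations)
  }
  if (length(badRefs))
    gsmvParseError("reaction(s) reference unknown species: %s",
                   paste(unique(badRefs), collapse = "; "))

  ## genes referenced by GPRs but absent from notes
  gprRefs <- unique(unlist(lapply(rxns, function(r) gprGenes(r$gpr)), use.names = FALSE))
  for (g in setdiff(gprRefs %||% character(0), names(gns))) {
    gns[[g]] <- gene(g)
    warningsOut <- c(warningsOut,
                     sprintf("gene '%s' referenced by a GPR but not described; created from its abbreviation", g))
  }

  sp <- splitURNs(modelURNs, character(0))
  model <- metabolicModel(
    attrOr(modelNode, "id", "imported_model"),
    name = attrOr(modelNode, "name", attrOr(modelNode, "id", "imported_model")),
    organism = notesValue(modelLines, "ORGANISM") %||% "",
    compartments = unname(comps[sortIds(names(comps))]),
    metabolites = unname(mets[sortIds(names(mets))]),
    reactions = unname(rxns[sortIds(names(rxns))]),
    genes = unname(gns[sortIds(names(gns))]),
    annotations = sp$annotations,
    notes = notesValue(modelLines, "DESCRIPTION") %||% "",
    versionLabel = notesValue(modelLines, "VERSION") %||% "")

  report <- list(
    counts = c(compartments = length(comps), metabolites = length(mets),
               reactions = length(rxns), genes = length(gns)),
    sourceLevelVersion = sprintf("L%sV%s", level, version),
    warnings = warningsOut)
  class(report) <- "ImportReport"
  list(model = model, report = report)
}

#' @export
print.ImportReport <- function(x, ...) {
  cat(sprintf("SBML import (%s): %s\n", x$sourceLevelVersion,
              paste(sprintf("%d %s", x$counts, names(x$counts)), collapse = ", ")))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
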