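## SBML export.
##
## Emits SBML Level 2 Version 4 as a deterministic byte stream: entities are
## sorted by identifier, reactant order is preserved as stored, notes lines
## follow a fixed key order, and every speciesReference carries an explicit
## stoichiometry attribute (including 1). Model-level fields that core SBML
## has no element for (organism, version label, gene metadata) travel in
## XHTML notes lines with documented keys, so that import/export round-trips
## are lossless.

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

## SBML SId sanitizer.
sbmlId <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[A-Za-z_]", x), x, paste0("x", x))
}

#' Export options
#'
#' @param mode Compartmentalization mode: `"complete"` (as stored),
#'   `"partial_decomp"` (compartments within the cytoplasm merged into it),
#'   `"full_decomp"` (single unsegregated system).
#' @param subsystems Optional subsystem names; only reactions in them are
#'   exported.
#' @param reactionFilter Optional reaction abbreviations (e.g. the result of a
#'   query) to export; combines with `subsystems` by intersection.
#' @param profile `"full"` (everything the model stores) or `"cobra"`
#'   (additionally flux bounds and objective coefficients in kinetic-law
#'   parameters, for constraint-based analysis tools).
#' @param cytoplasmId Compartment id to merge into under `partial_decomp`;
#'   auto-detected by name (`cytoplasm`/`cytosol`, case-insensitive) when
#'   unset.
#' @return An `ExportOptions` list.
#' @export
exportOptions <- function(mode = c("complete", "partial_decomp", "full_decomp"),
                          subsystems = NULL, reactionFilter = NULL,
                          profile = c("full", "cobra"), cytoplasmId = NULL) {
  structure(list(mode = match.arg(mode), subsystems = subsystems,
                 reactionFilter = reactionFilter, profile = match.arg(profile),
                 cytoplasmId = cytoplasmId), class = "ExportOptions")
}

notesLines <- function(pairs) {
  pairs <- Filter(function(p) !is.null(p[[2]]) && nzchar(p[[2]]), pairs)
  vapply(pairs, function(p) sprintf("%s: %s", p[[1]], p[[2]]), character(1))
}

## Reaction/species/compartment MIRIAM URNs in canonical order.
entityURNs <- function(kind, rec) {
  urns <- character(0)
  if (kind == "metabolite") {
    if (!is.null(rec$chebiId)) urns <- c(urns, miriamURN("chebi", rec$chebiId))
    if (!is.null(rec$keggId)) urns <- c(urns, miriamURN("kegg.compound", rec$keggId))
  } else if (kind == "reaction") {
    if (!is.null(rec$ecNumber)) urns <- c(urns, miriamURN("ec-code", rec$ecNumber))
    if (!is.null(rec$keggId)) urns <- c(urns, miriamURN("kegg.reaction", rec$keggId))
  }
  c(urns, sortIds(rec$annotations %||% character(0)))
}

emitAnnotation <- function(lines, indent, metaid, urns) {
  if (length(urns) == 0L) return(lines)
  pad <- function(n) strrep("  ", n)
  lines <- c(lines,
    paste0(pad(indent), "<annotation>"),
    paste0(pad(indent + 1L),
           "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\" ",
           "xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\">"),
    paste0(pad(indent + 2L), sprintf("<rdf:Description rdf:about=\"#%s\">", metaid)),
    paste0(pad(indent + 3L), "<bqbiol:is>"),
    paste0(pad(indent + 4L), "<rdf:Bag>"))
  for (u in urns)
    lines <- c(lines, paste0(pad(indent + 5L),
                             sprintf("<rdf:li rdf:resource=\"%s\"/>", xmlEscape(u))))
  c(lines,
    paste0(pad(indent + 4L), "</rdf:Bag>"),
    paste0(pad(indent + 3L), "</bqbiol:is>"),
    paste0(pad(indent + 2L), "</rdf:Description>"),
    paste0(pad(indent + 1L), "</rdf:RDF>"),
    paste0(pad(indent), "</annotation>"))
}

emitNotes <- function(lines, indent, keyvals) {
  txt <- notesLines(keyvals)
  if (length(txt) == 0L) return(lines)
  pad <- function(n) strrep("  ", n)
  lines <- c(lines, paste0(pad(indent), "<notes>"),
             paste0(pad(indent + 1L), "<body xmlns=\"http://www.w3.org/1999/xhtml\">"))
  for (t in txt)
    lines <- c(lines, paste0(pad(indent + 2L), "<p>", xmlEscape(t), "</p>"))
  c(lines, paste0(pad(indent + 1L), "</body>"), paste0(pad(indent), "</notes>"))
}

geneNotesLine <- function(g) {
  parts <- c(g$abbreviation,
             sprintf("NAME=%s", g$name),
             if (!is.null(g$ecNumber)) sprintf("EC=%s", g$ecNumber),
             if (!is.null(g$keggId)) sprintf("KEGG=%s", g$keggId),
             if (!is.null(g$uniprotId)) sprintf("UNIPROT=%s", g$uniprotId),
             if (length(g$annotations))
               sprintf("ANNOTATIONS=%s", paste(sortIds(g$annotations), collapse = " ")))
  paste(parts, collapse = "; ")
}

#' Export a model to SBML
#'
#' Writes SBML Level 2 Version 4. The compartmentalization mode is applied
#' first (see [decompartmentalize()]), then subsystem/reaction filters select
#' the emitted reactions, with species and genes restricted to participants.
#' Under the `cobra` profile every reaction additionally carries a kinetic
#' law with `LOWER_BOUND`/`UPPER_BOUND`/`OBJECTIVE_COEFFICIENT` parameters
#' derived from reversibility (reversible: -1000..1000, irreversible:
#' 0..1000, objective 0).
#'
#' @param model A valid [MetabolicModel-class] (no error-severity issues from
#'   [validateModel()]).
#' @param file Path to write to, or `NULL` to return the document only.
#' @param options An [exportOptions()] list.
#' @return List with `xml` (single string, UTF-8) and `report` (entity
#'   counts, warnings, target level/version; plus the decompartmentalization
#'   change report when a mode was applied).
#' @export
exportSBML <- function(model, file = NULL, options = exportOptions()) {
  issues <- validateModel(model)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs))
    gsmvStateError("model '%s' is not exportable: %s", model@modelId,
                   paste(sprintf("%s (%s)", errs$message, errs$entity), collapse = "; "))

  warnings <- character(0)
  decompReport <- NULL
  if (options$mode != "complete") {
    dec <- decompartmentalize(model, options$mode, options$cytoplasmId)
    model <- dec$model
    decompReport <- dec$report
    if (length(dec$report$droppedReactions))
      warnings <- c(warnings, sprintf("dropped %d reaction(s) that cancelled to empty: %s",
                                      length(dec$report$droppedReactions),
                                      paste(dec$report$droppedReactions, collapse = ", ")))
  }

  rxnIds <- sortIds(names(model@reactions))
  if (!is.null(options$subsystems)) {
    unknown <- setdiff(options$subsystems, model@subsystems)
    if (length(unknown))
      gsmvArgError("unknown subsystem(s) in export filter: %s",
                   paste(unknown, collapse = ", "))
    rxnIds <- rxnIds[vapply(rxnIds, function(id) {
      s <- model@reactions[[id]]$subsystem
      !is.null(s) && s %in% options$subsystems
    }, logical(1))]
  }
  if (!is.null(options$reactionFilter)) {
    unknown <- setdiff(options$reactionFilter, names(model@reactions))
    if (length(unknown))
      gsmvArgError("unknown reaction(s) in export filter: %s",
                   paste(unknown, collapse = ", "))
    rxnIds <- intersect(rxnIds, options$reactionFilter)
  }
  filtered <- !is.null(options$subsystems) || !is.null(options$reactionFilter)

  ## species = (metabolite, compartment) pairs in use; unfiltered exports also
  ## carry metabolites unused by any reaction, placed in the first compartment
  compIds <- sortIds(names(model@compartments))
  syntheticComp <- length(compIds) == 0L
  if (syntheticComp) compIds <- "cell"
  usedPairs <- list()
  for (id in rxnIds) {
    df <- model@reactions[[id]]$reactants
    if (nrow(df))
      for (k in seq_len(nrow(df)))
        usedPairs[[paste(df$metabolite[k], df$compartment[k], sep = "\r")]] <- TRUE
  }
  pairKeys <- names(usedPairs) %||% character(0)
  if (!filtered) {
    usedMets <- unique(vapply(strsplit(pairKeys, "\r", fixed = TRUE), `[`, character(1), 1))
    for (ab in setdiff(names(model@metabolites), usedMets))
      pairKeys <- c(pairKeys, paste(ab, compIds[1], sep = "\r"))
  }
  pairs <- do.call(rbind, lapply(strsplit(sortIds(pairKeys), "\r", fixed = TRUE),
                                 function(p) data.frame(met = p[1], comp = p[2],
                                                        stringsAsFactors = FALSE)))
  if (is.null(pairs)) pairs <- data.frame(met = character(0), comp = character(0))

  geneIds <- sortIds(names(model@genes))
  if (filtered) {
    used <- unique(unlist(lapply(rxnIds, function(id)
      gprGenes(model@reactions[[id]]$gpr)), use.names = FALSE))
    geneIds <- intersect(geneIds, used %||% character(0))
  }

  cobra <- options$profile == "cobra"
  speciesId <- function(met, comp) paste0(sbmlId(met), "_", sbmlId(comp))

  L <- character(0)
  add <- function(...) L <<- c(L, paste0(...))
  pad <- function(n) strrep("  ", n)

  add("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  add("<sbml xmlns=\"http://www.sbml.org/sbml/level2/version4\" level=\"2\" version=\"4\">")
  hasModelAnn <- length(model@annotations) > 0L
  add(pad(1), sprintf("<model%s id=\"%s\" name=\"%s\">",
                      if (hasModelAnn) sprintf(" metaid=\"meta_%s\"", sbmlId(model@modelId)) else "",
                      sbmlId(model@modelId), xmlEscape(model@name)))
  modelNotes <- c(
    list(list("ORGANISM", model@organism),
         list("VERSION", model@versionLabel),
         list("DESCRIPTION", model@notes)),
    lapply(geneIds, function(g) list("GENE", geneNotesLine(model@genes[[g]]))))
  L <- emitNotes(L, 2L, modelNotes)
  L <- emitAnnotation(L, 2L, paste0("meta_", sbmlId(model@modelId)),
                      sortIds(model@annotations))

  if (cobra) {
    add(pad(2), "<listOfUnitDefinitions>")
    add(pad(3), "<unitDefinition id=\"mmol_per_gDW_per_hr\">")
    add(pad(4), "<listOfUnits>")
    add(pad(5), "<unit kind=\"mole\" scale=\"-3\"/>")
    add(pad(5), "<unit kind=\"gram\" exponent=\"-1\"/>")
    add(pad(5), "<unit kind=\"second\" exponent=\"-1\" multiplier=\"0.00027778\"/>")
    add(pad(4), "</listOfUnits>")
    add(pad(3), "</unitDefinition>")
    add(pad(2), "</listOfUnitDefinitions>")
  }

  add(pad(2), "<listOfCompartments>")
  if (syntheticComp) {
    add(pad(3), "<compartment id=\"cell\" name=\"cell\" size=\"1\"/>")
  } else {
    for (cid in compIds) {
      cc <- model@compartments[[cid]]
      urns <- entityURNs("compartment", cc)
      attrs <- sprintf(" id=\"%s\" name=\"%s\" size=\"1\"%s",
                       sbmlId(cid), xmlEscape(cc$name),
                       if (!is.null(cc$parentId))
                         sprintf(" outside=\"%s\"", sbmlId(cc$parentId)) else "")
      if (length(urns)) {
        add(pad(3), sprintf("<compartment metaid=\"meta_%s\"%s>", sbmlId(cid), attrs))
        L <- emitAnnotation(L, 4L, paste0("meta_", sbmlId(cid)), urns)
        add(pad(3), "</compartment>")
      } else {
        add(pad(3), sprintf("<compartment%s/>", attrs))
      }
    }
  }
  add(pad(2), "</listOfCompartments>")

  add(pad(2), "<listOfSpecies>")
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      met <- model@metabolites[[pairs$met[k]]]
      sid <- speciesId(pairs$met[k], pairs$comp[k])
      urns <- entityURNs("metabolite", met)
      notes <- list(
        list("FORMULA", if (!is.null(met$formula))
          formatFormula(parseFormula(met$formula)) else NULL),
        list("CHARGE", if (!is.null(met$charge)) sprintf("%d", met$charge) else NULL))
      hasBody <- length(urns) > 0L || length(notesLines(notes)) > 0L
      attrs <- sprintf(" id=\"%s\" name=\"%s\" compartment=\"%s\"",
                       sid, xmlEscape(met$name), sbmlId(pairs$comp[k]))
      if (hasBody) {
        add(pad(3), sprintf("<species metaid=\"meta_%s\"%s>", sid, attrs))
        L <- emitNotes(L, 4L, notes)
        L <- emitAnnotation(L, 4L, paste0("meta_", sid), urns)
        add(pad(3), "</species>")
      } else {
        add(pad(3), sprintf("<species%s/>", attrs))
      }
    }
  }
  add(pad(2), "</listOfSpecies>")

  add(pad(2), "<listOfReactions>")
  for (id in rxnIds) {
    r <- model@reactions[[id]]
    rid <- sbmlId(id)
    urns <- entityURNs("reaction", r)
    notes <- list(
      list("GENE_ASSOCIATION", if (!is.null(r$gpr)) gprToString(r$gpr, "cobra") else NULL),
      list("SUBSYSTEM", r$subsystem),
      list("ENZYME", r$enzyme),
      list("ORF", r$orf),
      list("CITATIONS", if (length(r$citations))
        paste(r$citations, collapse = "; ") else NULL))
    add(pad(3), sprintf("<reaction%s id=\"%s\" name=\"%s\" reversible=\"%s\">",
                        if (length(urns)) sprintf(" metaid=\"meta_%s\"", rid) else "",
                        rid, xmlEscape(r$name),
                        if (r$reversible) "true" else "false"))
    L <- emitNotes(L, 4L, notes)
    L <- emitAnnotation(L, 4L, paste0("meta_", rid), urns)
    df <- r$reactants
    for (side in c("substrate", "product")) {
      sel <- df[df$side == side, , drop = FALSE]
      if (nrow(sel) == 0L) next
      tag <- if (side == "substrate") "listOfReactants" else "listOfProducts"
      add(pad(4), sprintf("<%s>", tag))
      for (k in seq_len(nrow(sel)))
        add(pad(5), sprintf("<speciesReference species=\"%s\" stoichiometry=\"%s\"/>",
                            speciesId(sel$metabolite[k], sel$compartment[k]),
                            fmtNum(sel$stoichiometry[k])))
      add(pad(4), sprintf("</%s>", tag))
    }
    if (cobra) {
      lb <- if (r$reversible) "-1000" else "0"
      add(pad(4), "<kineticLaw>")
      add(pad(5), "<math xmlns=\"http://www.w3.org/1998/Math/MathML\">")
      add(pad(6), "<ci> FLUX_VALUE </ci>")
      add(pad(5), "</math>")
      add(pad(5), "<listOfParameters>")
      add(pad(6), sprintf("<parameter id=\"LOWER_BOUND\" value=\"%s\" units=\"mmol_per_gDW_per_hr\"/>", lb))
      add(pad(6), "<parameter id=\"UPPER_BOUND\" value=\"1000\" units=\"mmol_per_gDW_per_hr\"/>")
      add(pad(6), "<parameter id=\"FLUX_VALUE\" value=\"0\" units=\"mmol_per_gDW_per_hr\"/>")
      add(pad(6), "<parameter id=\"OBJECTIVE_COEFFICIENT\" value=\"0\"/>")
      add(pad(5), "</listOfParameters>")
      add(pad(4), "</kineticLaw>")
    }
    add(pad(3), "</reaction>")
  }
  add(pad(2), "</listOfReactions>")
  add(pad(1), "</model>")
  add("</sbml>")

  xml <- paste0(paste(L, collapse = "\n"), "\n")
  xml2::read_xml(xml)  # self-check well-formedness

  report <- list(
    counts = c(compartments = length(compIds), species = nrow(pairs),
               metabolites = length(unique(pairs$met)),
               reactions = length(rxnIds), genes = length(geneIds)),
    warnings = warnings, levelVersion = "L2V4", profile = options$profile,
    mode = options$mode, decompartmentalization = decompReport)
  class(report) <- "ExportReport"

  if (!is.null(file)) writeLines(xml, file, sep = "", useBytes = TRUE)
  list(xml = xml, report = report)
}

#' @export
print.ExportReport <- function(x, ...) {
  cat(sprintf("SBML export (%s, %s profile, %s mode): %s\n", x$levelVersion,
              x$profile, x$mode,
              paste(sprintf("%d %s", x$counts, names(x$counts)), collapse = ", ")))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
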