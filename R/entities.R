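## Entity records. These are deliberately plain named lists (with a class tag
## for printing): the version store applies field-level deltas to them
## generically, and the SBML/tabular writers treat them as flat field sets.
## Field order is canonical so that reconstructed snapshots compare equal to
## freshly constructed records.

entityFields <- list(
  model = c("name", "organism", "notes", "subsystems", "annotations"),
  compartment = c("id", "name", "parentId", "annotations"),
  metabolite = c("abbreviation", "name", "formula", "charge",
                 "chebiId", "keggId", "annotations"),
  reaction = c("abbreviation", "name", "reactants", "reversible", "ecNumber",
               "keggId", "subsystem", "gpr", "enzyme", "orf", "citations",
               "annotations"),
  gene = c("abbreviation", "name", "ecNumber", "keggId", "uniprotId",
           "annotations")
)

entityClass <- c(
  model = "gsmModelInfo", compartment = "gsmCompartment",
  metabolite = "gsmMetabolite", reaction = "gsmReaction", gene = "gsmGene"
)

entityKinds <- names(entityFields)

asEntity <- function(rec, kind) {
  fields <- entityFields[[kind]]
  out <- rec[fields]
  names(out) <- fields
  structure(out, class = c(entityClass[[kind]], "gsmEntity"))
}

entityId <- function(rec) rec[["abbreviation"]] %||% rec[["id"]]

#' Create a compartment record
#'
#' Compartments form a forest: each compartment may name a parent compartment
#' (e.g. a peroxisome whose parent is the cytoplasm). The hierarchy drives the
#' partial-decompartmentalization export mode and [isWithin()].
#'
#' @param id Unique compartment identifier within a model.
#' @param name Human-readable name (used for cytoplasm auto-detection).
#' @param parentId Identifier of the enclosing compartment, or `NULL` for a
#'   root compartment.
#' @param annotations Character vector of MIRIAM URNs
#'   (`"urn:miriam:<datatype>:<identifier>"`).
#' @return A compartment record (named list).
#' @export
#' @examples
#' compartment("p", "peroxisome", parentId = "c")
compartment <- function(id, name = id, parentId = NULL, annotations = character(0)) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    gsmvArgError("compartment id must be a non-empty string")
  asEntity(list(id = id, name = as.character(name),
                parentId = chrOrNull(parentId),
                annotations = as.character(annotations)), "compartment")
}

#' Create a metabolite record
#'
#' @param abbreviation Unique metabolite identifier within a model.
#' @param name Full metabolite name.
#' @param formula Chemical formula string (see [parseFormula()]), or `NULL`
#'   when unknown; reactions touching such metabolites report an
#'   `undetermined` balance status.
#' @param charge Integer charge, or `NULL` when unknown.
#' @param chebiId,keggId Optional database accessions used by the comparator
#'   (ChEBI takes precedence over KEGG, which takes precedence over the name).
#' @param annotations Character vector of MIRIAM URNs.
#' @return A metabolite record (named list).
#' @export
#' @examples
#' metabolite("glc", "glucose", formula = "C6H12O6", keggId = "C00031")
metabolite <- function(abbreviation, name = abbreviation, formula = NULL,
                       charge = NULL, chebiId = NULL, keggId = NULL,
                       annotations = character(0)) {
  if (!is.character(abbreviation) || length(abbreviation) != 1L || !nzchar(abbreviation))
    gsmvArgError("metabolite abbreviation must be a non-empty string")
  if (!is.null(formula)) parseFormula(formula)  # fail early on bad formulas
  asEntity(list(abbreviation = abbreviation, name = as.character(name),
                formula = chrOrNull(formula),
                charge = if (isAbsent(charge)) NULL else as.integer(charge),
                chebiId = chrOrNull(chebiId), keggId = chrOrNull(keggId),
                annotations = as.character(annotations)), "metabolite")
}

#' Create a gene record
#'
#' @param abbreviation Unique gene identifier within a model.
#' @param name Gene name.
#' @param ecNumber,keggId,uniprotId Optional accessions; the comparator matches
#'   genes on UniProt ID when both sides carry one, otherwise on the name.
#' @param annotations Character vector of MIRIAM URNs.
#' @return A gene record (named list).
#' @export
gene <- function(abbreviation, name = abbreviation, ecNumber = NULL,
                 keggId = NULL, uniprotId = NULL, annotations = character(0)) {
  if (!is.character(abbreviation) || length(abbreviation) != 1L || !nzchar(abbreviation))
    gsmvArgError("gene abbreviation must be a non-empty string")
  asEntity(list(abbreviation = abbreviation, name = as.character(name),
                ecNumber = chrOrNull(ecNumber), keggId = chrOrNull(keggId),
                uniprotId = chrOrNull(uniprotId),
                annotations = as.character(annotations)), "gene")
}

#' Build a reactant table
#'
#' One row per participant of a reaction: the metabolite, its stoichiometric
#' coefficient, the compartment it is consumed from or produced into, and the
#' side of the equation it sits on.
#'
#' @param metabolite Character vector of metabolite abbreviations.
#' @param stoichiometry Positive numeric coefficients.
#' @param compartment Character vector of compartment ids.
#' @param side `"substrate"` or `"product"`, recycled.
#' @return A `data.frame` with columns `metabolite`, `stoichiometry`,
#'   `compartment`, `side`.
#' @export
#' @examples
#' rbind(reactants("h2", 2, "c", "substrate"),
#'       reactants("o2", 1, "c", "substrate"),
#'       reactants("h2o", 2, "c", "product"))
reactants <- function(metabolite, stoichiometry, compartment, side) {
  n <- max(length(metabolite), length(stoichiometry), length(compartment), length(side))
  df <- data.frame(
    metabolite = rep_len(as.character(metabolite), n),
    stoichiometry = rep_len(as.numeric(stoichiometry), n),
    compartment = rep_len(as.character(compartment), n),
    side = rep_len(as.character(side), n),
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$stoichiometry)) || any(df$stoichiometry <= 0))
    gsmvArgError("stoichiometric coefficients must be positive")
  bad <- setdiff(unique(df$side), c("substrate", "product"))
  if (length(bad))
    gsmvArgError("reactant side must be 'substrate' or 'product' (got '%s')", bad[1])
  df
}

emptyReactants <- function() {
  data.frame(metabolite = character(0), stoichiometry = numeric(0),
             compartment = character(0), side = character(0),
             stringsAsFactors = FALSE)
}

#' Create a reaction record
#'
#' The central entity of a metabolic model: an equation over reactants with a
#' reversibility flag, an optional gene-protein-reaction (GPR) Boolean rule,
#' a subsystem (pathway) assignment, and annotations.
#'
#' @param abbreviation Unique reaction identifier within a model.
#' @param name Reaction name.
#' @param reactants Reactant table from [reactants()] (possibly empty for
#'   exchange/boundary placeholders).
#' @param reversible Logical reversibility flag.
#' @param ecNumber,keggId,subsystem Optional classification fields.
#' @param gpr A GPR tree from [parseGPR()], a GPR string (parsed on the spot),
#'   or `NULL`.
#' @param enzyme,orf Free-text searchable attributes (enzyme name, ORF id).
#' @param citations Character vector of literature references.
#' @param annotations Character vector of MIRIAM URNs.
#' @return A reaction record (named list).
#' @export
#' @examples
#' reaction("R_hex", "hexokinase",
#'          rbind(reactants("glc", 1, "c", "substrate"),
#'                reactants("g6p", 1, "c", "product")),
#'          gpr = "hxk1 OR hxk2", subsystem = "glycolysis")
reaction <- function(abbreviation, name = abbreviation,
                     reactants = emptyReactants(), reversible = FALSE,
                     ecNumber = NULL, keggId = NULL, subsystem = NULL,
                     gpr = NULL, enzyme = NULL, orf = NULL,
                     citations = character(0), annotations = character(0)) {
  if (!is.character(abbreviation) || length(abbreviation) != 1L || !nzchar(abbreviation))
    gsmvArgError("reaction abbreviation must be a non-empty string")
  if (is.character(gpr)) gpr <- parseGPR(gpr)
  if (!is.null(gpr) && !inherits(gpr, "GeneAssociation"))
    gsmvArgError("gpr must be NULL, a GPR string, or a GeneAssociation tree")
  if (!is.data.frame(reactants))
    gsmvArgError("reactants must be a data.frame (see reactants())")
  rownames(reactants) <- NULL
  asEntity(list(abbreviation = abbreviation, name = as.character(name),
                reactants = reactants, reversible = isTRUE(reversible),
                ecNumber = chrOrNull(ecNumber), keggId = chrOrNull(keggId),
                subsystem = chrOrNull(subsystem), gpr = gpr,
                enzyme = chrOrNull(enzyme), orf = chrOrNull(orf),
                citations = as.character(citations),
                annotations = as.character(annotations)), "reaction")
}

#' @export
print.gsmEntity <- function(x, ...) {
  kind <- sub("^gsm", "", class(x)[1])
  cat(sprintf("<%s> %s\n", tolower(kind), entityId(x)))
  for (f in names(x)) {
    v <- x[[f]]
    if (is.null(v) || (is.atomic(v) && length(v) == 0L)) next
    if (is.data.frame(v)) {
      cat(sprintf("  %s: %d row(s)\n", f, nrow(v)))
    } else if (inherits(v, "GeneAssociation")) {
      cat(sprintf("  %s: %s\n", f, gprToString(v)))
    } else if (is.atomic(v)) {
      cat(sprintf("  %s: %s\n", f, paste(v, collapse = ", ")))
    }
  }
  invisible(x)
}
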