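#' MetabolicModel: an in-memory genome-scale metabolic model
#'
#' A named container of compartments, metabolites, reactions and genes, plus
#' the subsystem (pathway) vocabulary, organism, MIRIAM annotations and free
#' notes. Entity slots are named lists keyed by entity identifier; use the
#' accessors ([reactions()], [metabolites()], [genes()], [compartments()])
#' rather than reaching into slots.
#'
#' Construction-time validity checks cover types and identifier uniqueness
#' only; full referential integrity (dangling metabolite/compartment/gene
#' references, compartment cycles) is checked by [validateModel()], which can
#' therefore also diagnose deliberately broken models.
#'
#' @slot modelId Unique model identifier within a store.
#' @slot name Model name.
#' @slot organism Organism the model describes.
#' @slot versionLabel User-defined version label (assigned at approval time by
#'   the store; free text).
#' @slot compartments,metabolites,reactions,genes Named lists of entity
#'   records (see [compartment()], [metabolite()], [reaction()], [gene()]).
#' @slot subsystems Character vector of subsystem names.
#' @slot annotations Character vector of MIRIAM URNs on the model itself.
#' @slot notes Free-text notes.
#' @export
setClass("MetabolicModel", representation(
  modelId = "character",
  name = "character",
  organism = "character",
  versionLabel = "character",
  compartments = "list",
  metabolites = "list",
  reactions = "list",
  genes = "list",
  subsystems = "character",
  annotations = "character",
  notes = "character"
))

setValidity("MetabolicModel", function(object) {
  msgs <- character(0)
  for (slot in c("modelId", "name", "organism", "versionLabel", "notes")) {
    if (length(methods::slot(object, slot)) != 1L)
      msgs <- c(msgs, sprintf("slot '%s' must be a single string", slot))
  }
  if (length(object@modelId) == 1L && !nzchar(object@modelId))
    msgs <- c(msgs, "modelId must be non-empty")
  for (slot in c("compartments", "metabolites", "reactions", "genes")) {
    ents <- methods::slot(object, slot)
    ids <- vapply(ents, entityId, character(1))
    if (length(ids) && (is.null(names(ents)) || !identical(unname(ids), names(ents))))
      msgs <- c(msgs, sprintf("slot '%s' must be named by entity id", slot))
    if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicate identifiers in '%s': %s", slot,
                              paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MetabolicModel
#'
#' @param modelId Unique model identifier.
#' @param name Model name (defaults to the id).
#' @param organism Organism name.
#' @param compartments,metabolites,reactions,genes Lists of entity records.
#' @param subsystems Subsystem vocabulary; subsystems referenced by reactions
#'   are added automatically.
#' @param annotations MIRIAM URNs on the model.
#' @param notes Free-text notes.
#' @param versionLabel User-defined version label.
#' @return A [MetabolicModel-class] object.
#' @export
#' @examples
#' m <- metabolicModel("demo", organism = "Escherichia coli",
#'   compartments = list(compartment("c", "cytoplasm")),
#'   metabolites = list(metabolite("h2o", "water", formula = "H2O")))
#' m
metabolicModel <- function(modelId, name = modelId, organism = "",
                           compartments = list(), metabolites = list(),
                           reactions = list(), genes = list(),
                           subsystems = character(0),
                           annotations = character(0), notes = "",
                           versionLabel = "") {
  ## entities are kept sorted by identifier: one canonical order everywhere
  ## (snapshots, emission, comparison) regardless of construction order
  nameBy <- function(ents) {
    if (length(ents) == 0L) return(list())
    ents <- stats::setNames(ents, vapply(ents, entityId, character(1)))
    ents[sortIds(names(ents))]
  }
  reactions <- nameBy(reactions)
  rxnSub <- unlist(lapply(reactions, function(r) r$subsystem), use.names = FALSE)
  methods::new("MetabolicModel",
    modelId = as.character(modelId), name = as.character(name),
    organism = as.character(organism), versionLabel = as.character(versionLabel),
    compartments = nameBy(compartments), metabolites = nameBy(metabolites),
    reactions = reactions, genes = nameBy(genes),
    subsystems = sortIds(unique(c(as.character(subsystems), rxnSub))),
    annotations = as.character(annotations), notes = as.character(notes))
}

#' ModelStore: an append-only, revision-numbered model repository
#'
#' Holds users, pending and approved changes, revisions and comment threads.
#' All mutation goes through [proposeChange()] / [approveChanges()]; accepted
#' model states are reconstructed from the approved change log by
#' [modelAtRevision()]. State lives in an environment slot so store-mutating
#' functions have reference semantics, as repository objects should.
#'
#' @slot state Environment holding users, changes, revisions, model metadata,
#'   comments and counters.
#' @seealso [modelStore()], [writeStore()], [readStore()]
#' @export
setClass("ModelStore", representation(state = "environment"))

#' ModelComparison: result of comparing two model snapshots
#'
#' For each category (reactions, metabolites, genes) the comparison yields the
#' list of matched pairs with the identifier rule that matched them, the
#' entities unique to either operand, and the derived Venn counts.
#'
#' @slot operands List of two descriptors (`modelId`, `revision`).
#' @slot restrictions List with elements `compartments` and `subsystems`
#'   (`NULL` when unrestricted).
#' @slot categories Named list (`reactions`, `metabolites`, `genes`); each
#'   element has `shared` (data.frame with columns `a`, `b`, `rule`),
#'   `uniqueA` and `uniqueB` (character vectors).
#' @seealso [compareModels()], [vennCounts()], [comparisonTable()]
#' @export
setClass("ModelComparison", representation(
  operands = "list",
  restrictions = "list",
  categories = "list"
))
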