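## Quick search across entity fields.

searchFields <- list(
  reactions = c("abbreviation", "name", "ecNumber", "enzyme", "orf", "keggId"),
  metabolites = c("abbreviation", "name", "formula", "chebiId", "keggId"),
  genes = c("abbreviation", "name", "ecNumber", "keggId", "uniprotId")
)

emptyHits <- function() data.frame(model = character(0), entity = character(0),
                                   field = character(0), text = character(0),
                                   stringsAsFactors = FALSE)

scanEntities <- function(modelId, ents, fields, needle) {
  rows <- list()
  for (id in names(ents)) {
    rec <- ents[[id]]
    for (f in fields) {
      v <- rec[[f]]
      if (is.null(v) || !nzchar(v)) next
      if (grepl(needle, tolower(v), fixed = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          model = modelId, entity = id, field = f, text = as.character(v),
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else emptyHits()
}

#' Quick search across models in a store
#'
#' Case-insensitive substring search over the searchable fields of each
#' entity kind: reactions by abbreviation, name, EC number, enzyme, ORF and
#' KEGG ID; metabolites by abbreviation, name, formula, ChEBI ID and KEGG ID;
#' genes by abbreviation, name, EC number, KEGG ID and UniProt ID; organisms
#' by name. Reaction hits honour the model selection (reactions belong to
#' models); the other kinds are searched across all accepted models in the
#' store.
#'
#' @param store A [ModelStore-class].
#' @param term Non-empty search term.
#' @param selectedModels Model ids the reaction search is restricted to
#'   (`NULL`: all models with an accepted state).
#' @return A `SearchResult`: list of data.frames `reactions`, `metabolites`,
#'   `genes` (columns `model`, `entity`, `field`, `text`) and `organisms`
#'   (columns `model`, `field`, `text`).
#' @export
quickSearch <- function(store, term, selectedModels = NULL) {
  if (!is.character(term) || length(term) != 1L || !nzchar(term))
    gsmvArgError("search term must be a non-empty string")
  needle <- tolower(term)
  allIds <- storeModels(store)
  snapshots <- list()
  for (mid in allIds) {
    m <- tryCatch(modelAtRevision(store, mid), error = function(e) NULL)
    if (!is.null(m)) snapshots[[mid]] <- m
  }
  if (is.null(selectedModels)) selectedModels <- names(snapshots)

  res <- list(reactions = emptyHits(), metabolites = emptyHits(),
              genes = emptyHits(),
              organisms = data.frame(model = character(0), field = character(0),
                                     text = character(0), stringsAsFactors = FALSE))
  for (mid in names(snapshots)) {
    m <- snapshots[[mid]]
    if (mid %in% selectedModels)
      res$reactions <- rbind(res$reactions,
        scanEntities(mid, m@reactions, searchFields$reactions, needle))
    res$metabolites <- rbind(res$metabolites,
      scanEntities(mid, m@metabolites, searchFields$metabolites, needle))
    res$genes <- rbind(res$genes,
      scanEntities(mid, m@genes, searchFields$genes, needle))
    if (nzchar(m@organism) && grepl(needle, tolower(m@organism), fixed = TRUE))
      res$organisms <- rbind(res$organisms,
        data.frame(model = mid, field = "organism", text = m@organism,
                   stringsAsFactors = FALSE))
  }
  for (k in names(res)) rownames(res[[k]]) <- NULL
  structure(res, class = "SearchResult")
}

#' @export
print.SearchResult <- function(x, ...) {
  cat("Quick search results\n")
  for (k in c("reactions", "metabolites", "genes", "organisms")) {
    cat(sprintf("  %-11s %d hit(s)\n", k, nrow(x[[k]])))
  }
  invisible(x)
}
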