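## Compartmentalization transforms applied at export time (or standalone).

## Aggregate duplicate (metabolite, compartment, side) rows by summing
## stoichiometries; preserves the elemental net exactly.
aggregateReactants <- function(df) {
  if (nrow(df) < 2L) return(df)
  key <- paste(df$side, df$metabolite, df$compartment, sep = "\r")
  if (!anyDuplicated(key)) return(df)
  agg <- stats::aggregate(stoichiometry ~ side + metabolite + compartment,
                          data = df, FUN = sum)
  firstPos <- vapply(paste(agg$side, agg$metabolite, agg$compartment, sep = "\r"),
                     function(k) match(k, key), integer(1))
  agg <- agg[order(firstPos), c("metabolite", "stoichiometry", "compartment", "side")]
  rownames(agg) <- NULL
  agg
}

## Detect the cytoplasm by name when no explicit id is given.
detectCytoplasm <- function(model, cytoplasmId = NULL) {
  if (!is.null(cytoplasmId)) {
    getCompartment(model, cytoplasmId)
    return(cytoplasmId)
  }
  hits <- names(model@compartments)[vapply(model@compartments, function(cc)
    tolower(cc$name) %in% c("cytoplasm", "cytosol"), logical(1))]
  if (length(hits) == 0L)
    gsmvArgError("no cytoplasm compartment found (looked for a compartment named 'cytoplasm' or 'cytosol'); pass cytoplasmId explicitly")
  sortIds(hits)[1]
}

#' Reassign reactions and metabolites to compartments
#'
#' Three modes mirror the usual export needs of analysis tools:
#' * `complete` — the identity: compartments exactly as stored.
#' * `partial_decomp` — every reactant in a compartment within the cytoplasm
#'   (peroxisome, nucleus, ...) is reassigned to the cytoplasm; the emptied
#'   descendant compartments are removed; compartments outside the cytoplasm
#'   (e.g. extracellular space) are untouched. The number of reactions is
#'   preserved.
#' * `full_decomp` — all compartment assignments collapse into a single
#'   unsegregated compartment (`cell`); reactants that then appear identically
#'   on both sides with equal stoichiometry cancel, and reactions that cancel
#'   to empty (pure transports) are dropped and reported. Idempotent, and the
#'   elemental net of every surviving reaction is unchanged.
#'
#' @param model A [MetabolicModel-class].
#' @param mode `"complete"`, `"partial_decomp"` or `"full_decomp"`.
#' @param cytoplasmId Cytoplasm compartment id for `partial_decomp`;
#'   auto-detected by name (`cytoplasm`/`cytosol`, case-insensitive) when
#'   `NULL`.
#' @return List with `model` (transformed) and `report` (mode, number of
#'   reassigned reactants, removed compartment ids, dropped reaction ids,
#'   number of cancelled reactant pairs).
#' @export
decompartmentalize <- function(model,
                               mode = c("complete", "partial_decomp", "full_decomp"),
                               cytoplasmId = NULL) {
  mode <- match.arg(mode)
  report <- list(mode = mode, reassigned = 0L, removedCompartments = character(0),
                 droppedReactions = character(0), cancelled = 0L)
  if (mode == "complete")
    return(list(model = model, report = report))

  if (mode == "partial_decomp") {
    cyt <- detectCytoplasm(model, cytoplasmId)
    inside <- names(model@compartments)[vapply(names(model@compartments),
      function(cid) isWithin(cid, cyt, model), logical(1))]
    descendants <- setdiff(inside, cyt)
    rxns <- model@reactions
    for (id in names(rxns)) {
      df <- rxns[[id]]$reactants
      if (nrow(df) == 0L) next
      hit <- df$compartment %in% descendants
      if (any(hit)) {
        report$reassigned <- report$reassigned + sum(hit)
        df$compartment[hit] <- cyt
        rxns[[id]]$reactants <- aggregateReactants(df)
      }
    }
    keep <- setdiff(names(model@compartments), descendants)
    comps <- model@compartments[keep]
    ## parents pointing at removed compartments are re-rooted at the cytoplasm
    for (cid in names(comps)) {
      pid <- comps[[cid]]$parentId
      if (!is.null(pid) && !(pid %in% keep)) comps[[cid]]$parentId <- cyt
    }
    report$removedCompartments <- sortIds(descendants)
    out <- metabolicModel(model@modelId, name = model@name,
      organism = model@organism,
      compartments = unname(comps), metabolites = unname(model@metabolites),
      reactions = unname(rxns), genes = unname(model@genes),
      subsystems = model@subsystems, annotations = model@annotations,
      notes = model@notes, versionLabel = model@versionLabel)
    return(list(model = out, report = report))
  }

  ## full_decomp
  unsegregated <- compartment("cell", "cell")
  rxns <- list()
  for (id in names(model@reactions)) {
    r <- model@reactions[[id]]
    df <- r$reactants
    if (nrow(df)) {
      df$compartment <- "cell"
      df <- aggregateReactants(df)
      ## cancel reactants identical on both sides with equal stoichiometry
      subs <- df[df$side == "substrate", , drop = FALSE]
      prods <- df[df$side == "product", , drop = FALSE]
      drop <- rep(FALSE, nrow(df))
      for (k in seq_len(nrow(subs))) {
        j <- which(prods$metabolite == subs$metabolite[k] &
                     abs(prods$stoichiometry - subs$stoichiometry[k]) < 1e-12)
        if (length(j)) {
          drop[which(df$side == "substrate")[k]] <- TRUE
          drop[which(df$side == "product")[j[1]]] <- TRUE
          report$cancelled <- report$cancelled + 1L
        }
      }
      df <- df[!drop, , drop = FALSE]
      rownames(df) <- NULL
    }
    if (nrow(df) == 0L && nrow(r$reactants) > 0L) {
      report$droppedReactions <- c(report$droppedReactions, id)
      next
    }
    r$reactants <- df
    rxns[[id]] <- r
  }
  report$droppedReactions <- sortIds(report$droppedReactions)
  out <- metabolicModel(model@modelId, name = model@name,
    organism = model@organism,
    compartments = list(unsegregated), metabolites = unname(model@metabolites),
    reactions = unname(rxns), genes = unname(model@genes),
    subsystems = model@subsystems, annotations = model@annotations,
    notes = model@notes, versionLabel = model@versionLabel)
  list(model = out, report = report)
}
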