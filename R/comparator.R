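## Model comparison by identifier precedence.
##
## Reactions match on KEGG ID when both sides carry one (no fallback on a
## conflict: KEGG is authoritative when present on both), otherwise on the
## canonical chemical equation (reversibility, metabolites, stoichiometry).
## Metabolites match ChEBI > KEGG > case-insensitive name; genes UniProt >
## case-insensitive name. Many-to-many ambiguity is resolved by greedy
## one-to-one matching in sorted-abbreviation order, which is deterministic.

## Species-level key used both for metabolite identity and inside equations.
metaboliteKey <- function(met) {
  if (!is.null(met$chebiId)) paste0("chebi:", met$chebiId)
  else if (!is.null(met$keggId)) paste0("kegg:", met$keggId)
  else paste0("name:", tolower(met$name))
}

#' Canonical form of a reaction equation
#'
#' Substrate and product multisets of (metabolite key, compartment path,
#' stoichiometry), each side sorted by a total order, plus the reversibility
#' flag. Permuting reactants does not change the result; two reversible
#' reactions written in opposite directions compare equal; irreversible
#' reactions preserve direction. No stoichiometric rescaling is applied
#' (2A -> 2B differs from A -> B).
#'
#' @param rxn Reaction record or abbreviation.
#' @param model The [MetabolicModel-class] resolving its references.
#' @return A `CanonicalEquation`: list with `substrates`, `products`
#'   (data.frames with columns `key`, `path`, `stoichiometry`), `reversible`,
#'   and `signature`, a single string on which equality can be tested.
#' @export
canonicalEquation <- function(rxn, model) {
  if (is.character(rxn)) rxn <- getReaction(model, rxn)
  df <- rxn$reactants
  sideTable <- function(side) {
    sel <- df[df$side == side, , drop = FALSE]
    if (nrow(sel) == 0L)
      return(data.frame(key = character(0), path = character(0),
                        stoichiometry = numeric(0), stringsAsFactors = FALSE))
    out <- data.frame(
      key = vapply(sel$metabolite, function(ab) metaboliteKey(getMetabolite(model, ab)),
                   character(1)),
      path = vapply(sel$compartment, function(cid)
        paste(compartmentChain(model, cid), collapse = "/"), character(1)),
      stoichiometry = sel$stoichiometry,
      stringsAsFactors = FALSE)
    out <- out[order(out$key, out$path, out$stoichiometry), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  subs <- sideTable("substrate")
  prods <- sideTable("product")
  sideSig <- function(tab) {
    if (nrow(tab) == 0L) return("")
    paste(sprintf("%s@%s*%s", tab$key, tab$path, fmtNum(tab$stoichiometry)),
          collapse = "+")
  }
  sigS <- sideSig(subs)
  sigP <- sideSig(prods)
  signature <- if (rxn$reversible) {
    ## orientation-free form for reversible reactions
    paste0("rev|", paste(sortIds(c(paste0("L:", sigS, ">R:", sigP),
                                   paste0("L:", sigP, ">R:", sigS)))[1]))
  } else {
    paste0("irr|", sigS, "=>", sigP)
  }
  structure(list(substrates = subs, products = prods,
                 reversible = rxn$reversible, signature = signature),
            class = "CanonicalEquation")
}

matchResult <- function(matched, rule) {
  structure(list(matched = matched, rule = if (matched) rule else "none"),
            class = "MatchResult")
}

bothPresent <- function(a, b) !is.null(a) && !is.null(b)

#' Match two reactions
#'
#' KEGG ID equality when both reactions carry one (a conflict means no match,
#' with no equation fallback); otherwise canonical-equation equality.
#'
#' @param r1,r2 Reaction records or abbreviations.
#' @param model1,model2 The models resolving them.
#' @return A `MatchResult`: `matched` (logical) and `rule` (`"kegg"`,
#'   `"equation"` or `"none"`).
#' @export
matchReaction <- function(r1, r2, model1, model2) {
  if (is.character(r1)) r1 <- getReaction(model1, r1)
  if (is.character(r2)) r2 <- getReaction(model2, r2)
  if (bothPresent(r1$keggId, r2$keggId))
    return(matchResult(identical(r1$keggId, r2$keggId), "kegg"))
  eq <- identical(canonicalEquation(r1, model1)$signature,
                  canonicalEquation(r2, model2)$signature)
  matchResult(eq, "equation")
}

#' Match two metabolites
#'
#' ChEBI when both present, else KEGG when both present, else case-insensitive
#' name equality.
#'
#' @param m1,m2 Metabolite records.
#' @return A `MatchResult` with rule `"chebi"`, `"kegg"`, `"name"` or `"none"`.
#' @export
matchMetabolite <- function(m1, m2) {
  if (bothPresent(m1$chebiId, m2$chebiId))
    return(matchResult(identical(m1$chebiId, m2$chebiId), "chebi"))
  if (bothPresent(m1$keggId, m2$keggId))
    return(matchResult(identical(m1$keggId, m2$keggId), "kegg"))
  matchResult(tolower(m1$name) == tolower(m2$name), "name")
}

#' Match two genes
#'
#' UniProt when both present, else case-insensitive name equality.
#'
#' @param g1,g2 Gene records.
#' @return A `MatchResult` with rule `"uniprot"`, `"name"` or `"none"`.
#' @export
matchGene <- function(g1, g2) {
  if (bothPresent(g1$uniprotId, g2$uniprotId))
    return(matchResult(identical(g1$uniprotId, g2$uniprotId), "uniprot"))
  matchResult(tolower(g1$name) == tolower(g2$name), "name")
}

## Greedy one-to-one matching in sorted-id order.
greedyMatch <- function(idsA, idsB, matchFun) {
  idsA <- sortIds(idsA)
  idsB <- sortIds(idsB)
  freeB <- idsB
  shared <- list()
  uniqueA <- character(0)
  for (a in idsA) {
    hit <- NULL
    for (b in freeB) {
      mr <- matchFun(a, b)
      if (mr$matched) { hit <- list(b = b, rule = mr$rule); break }
    }
    if (is.null(hit)) uniqueA <- c(uniqueA, a)
    else {
      shared[[length(shared) + 1L]] <- data.frame(a = a, b = hit$b, rule = hit$rule,
                                                  stringsAsFactors = FALSE)
      freeB <- setdiff(freeB, hit$b)
    }
  }
  sharedDf <- if (length(shared)) do.call(rbind, shared)
              else data.frame(a = character(0), b = character(0), rule = character(0),
                              stringsAsFactors = FALSE)
  list(shared = sharedDf, uniqueA = uniqueA, uniqueB = freeB)
}

## Entities surviving a compartment/subsystem restriction.
restrictEntities <- function(model, restrictCompartments, restrictSubsystems) {
  rxnIds <- names(model@reactions)
  keep <- vapply(rxnIds, function(id) {
    r <- model@reactions[[id]]
    okSub <- is.null(restrictSubsystems) ||
      (!is.null(r$subsystem) && r$subsystem %in% restrictSubsystems)
    okComp <- is.null(restrictCompartments) ||
      (nrow(r$reactants) > 0L && any(r$reactants$compartment %in% restrictCompartments))
    okSub && okComp
  }, logical(1))
  rxnIds <- rxnIds[keep]
  restricted <- !is.null(restrictCompartments) || !is.null(restrictSubsystems)
  if (!restricted) {
    return(list(reactions = rxnIds, metabolites = names(model@metabolites),
                genes = names(model@genes)))
  }
  mets <- unique(unlist(lapply(rxnIds, function(id)
    model@reactions[[id]]$reactants$metabolite), use.names = FALSE)) %||% character(0)
  gns <- unique(unlist(lapply(rxnIds, function(id)
    gprGenes(model@reactions[[id]]$gpr)), use.names = FALSE)) %||% character(0)
  list(reactions = rxnIds,
       metabolites = intersect(names(model@metabolites), mets),
       genes = intersect(names(model@genes), gns))
}

#' Compare two model snapshots
#'
#' Matches reactions, metabolites and genes between two models (or two
#' revisions of the same model) by identifier precedence, optionally after
#' restricting reactions to selected compartments and/or subsystems
#' (metabolites and genes are then restricted to participants of the
#' surviving reactions). Metabolites are compared at species level, ignoring
#' compartments.
#'
#' @param modelA,modelB [MetabolicModel-class] snapshots.
#' @param restrictCompartments Optional character vector of compartment ids;
#'   a reaction survives if any reactant sits in one of them.
#' @param restrictSubsystems Optional character vector of subsystem names.
#' @return A [ModelComparison-class]; see [vennCounts()] and
#'   [comparisonTable()].
#' @export
#' @examples
#' pair <- generateModelPair(seed = 1)
#' vennCounts(compareModels(pair$modelA, pair$modelB))
compareModels <- function(modelA, modelB, restrictCompartments = NULL,
                          restrictSubsystems = NULL) {
  selA <- restrictEntities(modelA, restrictCompartments, restrictSubsystems)
  selB <- restrictEntities(modelB, restrictCompartments, restrictSubsystems)

  rxn <- greedyMatch(selA$reactions, selB$reactions, function(a, b)
    matchReaction(modelA@reactions[[a]], modelB@reactions[[b]], modelA, modelB))
  met <- greedyMatch(selA$metabolites, selB$metabolites, function(a, b)
    matchMetabolite(modelA@metabolites[[a]], modelB@metabolites[[b]]))
  gen <- greedyMatch(selA$genes, selB$genes, function(a, b)
    matchGene(modelA@genes[[a]], modelB@genes[[b]]))

  methods::new("ModelComparison",
    operands = list(
      list(modelId = modelA@modelId, revision = modelA@versionLabel),
      list(modelId = modelB@modelId, revision = modelB@versionLabel)),
    restrictions = list(compartments = restrictCompartments,
                        subsystems = restrictSubsystems),
    categories = list(reactions = rxn, metabolites = met, genes = gen))
}

#' Compare two stored snapshots
#'
#' Pulls both snapshots from the store and delegates to [compareModels()];
#' use it to compare any versions of two models, or two versions of the same
#' model to spot development changes.
#'
#' @param store A [ModelStore-class].
#' @param modelIdA,modelIdB Model ids.
#' @param revisionA,revisionB Revision numbers (`NULL`: head).
#' @inheritParams compareModels
#' @export
compareRevisions <- function(store, modelIdA, revisionA = NULL,
                             modelIdB = modelIdA, revisionB = NULL,
                             restrictCompartments = NULL,
                             restrictSubsystems = NULL) {
  a <- modelAtRevision(store, modelIdA, revisionA)
  b <- modelAtRevision(store, modelIdB, revisionB)
  cmp <- compareModels(a, b, restrictCompartments, restrictSubsystems)
  cmp@operands <- list(
    list(modelId = modelIdA, revision = revisionA %||% currentRevision(store)),
    list(modelId = modelIdB, revision = revisionB %||% currentRevision(store)))
  cmp
}

#' Venn counts of a comparison
#'
#' @param cmp A [ModelComparison-class].
#' @return Integer matrix, one row per category (`reactions`, `metabolites`,
#'   `genes`), columns `uniqueA`, `shared`, `uniqueB`.
#' @export
vennCounts <- function(cmp) {
  out <- t(vapply(cmp@categories, function(cat)
    c(uniqueA = length(cat$uniqueA), shared = nrow(cat$shared),
      uniqueB = length(cat$uniqueB)), integer(3)))
  out
}

#' Comparison result as a delimited-ready table
#'
#' One row per entity involved in the comparison: category, entity id, which
#' model it comes from, whether it is shared or unique, the identifier rule
#' that matched it, and its partner id.
#'
#' @param cmp A [ModelComparison-class].
#' @return A data.frame with columns `category`, `entity`, `model`, `status`,
#'   `rule`, `partner`.
#' @export
comparisonTable <- function(cmp) {
  rows <- list()
  for (cat in names(cmp@categories)) {
    res <- cmp@categories[[cat]]
    if (nrow(res$shared)) {
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, entity = res$shared$a, model = "A", status = "shared",
        rule = res$shared$rule, partner = res$shared$b, stringsAsFactors = FALSE)
    }
    if (length(res$uniqueA))
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, entity = res$uniqueA, model = "A", status = "unique",
        rule = "none", partner = NA_character_, stringsAsFactors = FALSE)
    if (length(res$uniqueB))
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, entity = res$uniqueB, model = "B", status = "unique",
        rule = "none", partner = NA_character_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(category = character(0), entity = character(0),
                      model = character(0), status = character(0),
                      rule = character(0), partner = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

setMethod("show", "ModelComparison", function(object) {
  a <- object@operands[[1]]; b <- object@operands[[2]]
  cat(sprintf("ModelComparison: %s vs %s\n", a$modelId, b$modelId))
  if (!is.null(object@restrictions$subsystems))
    cat("  subsystems:", paste(object@restrictions$subsystems, collapse = ", "), "\n")
  if (!is.null(object@restrictions$compartments))
    cat("  compartments:", paste(object@restrictions$compartments, collapse = ", "), "\n")
  vc <- vennCounts(object)
  for (cat. in rownames(vc))
    cat(sprintf("  %-12s unique A %4d | shared %4d | unique B %4d\n",
                cat., vc[cat., "uniqueA"], vc[cat., "shared"], vc[cat., "uniqueB"]))
  invisible(NULL)
})
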