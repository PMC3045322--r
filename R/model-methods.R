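#' @describeIn MetabolicModel-class Model identifier.
#' @param object A `MetabolicModel`.
#' @export
setMethod("modelId", "MetabolicModel", function(object) object@modelId)

#' @describeIn MetabolicModel-class Organism name.
#' @export
setMethod("organism", "MetabolicModel", function(object) object@organism)

#' @describeIn MetabolicModel-class User-defined version label.
#' @export
setMethod("versionLabel", "MetabolicModel", function(object) object@versionLabel)

#' @describeIn MetabolicModel-class Named list of compartment records.
#' @export
setMethod("compartments", "MetabolicModel", function(object) object@compartments)

#' @describeIn MetabolicModel-class Named list of metabolite records.
#' @export
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)

#' @describeIn MetabolicModel-class Named list of reaction records.
#' @export
setMethod("reactions", "MetabolicModel", function(object) object@reactions)

#' @describeIn MetabolicModel-class Named list of gene records.
#' @export
setMethod("genes", "MetabolicModel", function(object) object@genes)

#' @describeIn MetabolicModel-class Subsystem vocabulary.
#' @export
setMethod("subsystems", "MetabolicModel", function(object) object@subsystems)

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel '%s'%s\n", object@modelId,
              if (nzchar(object@name) && object@name != object@modelId)
                sprintf(" (%s)", object@name) else ""))
  if (nzchar(object@organism)) cat("  organism:", object@organism, "\n")
  if (nzchar(object@versionLabel)) cat("  version label:", object@versionLabel, "\n")
  cat(sprintf("  %d compartment(s), %d metabolite(s), %d reaction(s), %d gene(s), %d subsystem(s)\n",
              length(object@compartments), length(object@metabolites),
              length(object@reactions), length(object@genes),
              length(object@subsystems)))
  invisible(NULL)
})

getCompartment <- function(model, id) {
  cc <- model@compartments[[id]]
  if (is.null(cc)) gsmvLookupError("unknown compartment '%s' in model '%s'", id, model@modelId)
  cc
}

getMetabolite <- function(model, abbr) {
  mm <- model@metabolites[[abbr]]
  if (is.null(mm)) gsmvLookupError("unknown metabolite '%s' in model '%s'", abbr, model@modelId)
  mm
}

getReaction <- function(model, abbr) {
  rr <- model@reactions[[abbr]]
  if (is.null(rr)) gsmvLookupError("unknown reaction '%s' in model '%s'", abbr, model@modelId)
  rr
}

## Chain of compartment ids from the root down to `id`.
compartmentChain <- function(model, id) {
  chain <- character(0)
  cur <- id
  seen <- character(0)
  while (!is.null(cur)) {
    if (cur %in% seen)
      gsmvStateError("compartment hierarchy contains a cycle at '%s'", cur)
    seen <- c(seen, cur)
    chain <- c(cur, chain)
    cur <- getCompartment(model, cur)$parentId
  }
  chain
}

#' Is a compartment within another (ancestor-or-self)?
#'
#' True iff `ancestor` appears on the parent chain of `id`, including `id`
#' itself: the cytoplasm is within the cytoplasm. This reflexive reading is
#' what partial decompartmentalization needs — a reactant already in the
#' cytoplasm maps to the cytoplasm.
#'
#' @param id,ancestor Compartment ids; both must resolve in `model`.
#' @param model A [MetabolicModel-class].
#' @return Logical scalar.
#' @export
#' @examples
#' m <- metabolicModel("demo", compartments = list(
#'   compartment("c", "cytoplasm"), compartment("p", "peroxisome", parentId = "c")))
#' isWithin("p", "c", m)
isWithin <- function(id, ancestor, model) {
  getCompartment(model, ancestor)
  ancestor %in% compartmentChain(model, id)
}

#' Check a model's referential integrity
#'
#' Reports every violation of the container invariants: reactions referencing
#' undeclared metabolites or compartments, duplicate entity identifiers,
#' compartment parent cycles or dangling parents, subsystems used but not
#' declared, and — as warnings, since draft models legitimately reference
#' genes that are not yet annotated — GPR leaves naming unknown genes.
#'
#' @param model A [MetabolicModel-class].
#' @return A data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `entity`, `message`; zero rows iff the model is internally consistent.
#' @export
validateModel <- function(model) {
  issues <- list()
  add <- function(severity, entity, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, entity = entity, message = message,
      stringsAsFactors = FALSE)

  compIds <- names(model@compartments)
  metIds <- names(model@metabolites)
  geneIds <- names(model@genes)

  ## compartment forest: dangling parents and cycles
  for (cid in compIds) {
    pid <- model@compartments[[cid]]$parentId
    if (!is.null(pid) && !(pid %in% compIds))
      add("error", cid, sprintf("compartment parent '%s' does not exist", pid))
  }
  walkable <- vapply(compIds, function(cid) {
    cur <- cid; seen <- character(0)
    while (!is.null(cur)) {
      if (cur %in% seen) return(FALSE)
      seen <- c(seen, cur)
      nxt <- if (cur %in% compIds) model@compartments[[cur]]$parentId else NULL
      cur <- nxt
    }
    TRUE
  }, logical(1))
  for (cid in compIds[!walkable])
    add("error", cid, "compartment parent chain contains a cycle")

  for (rid in names(model@reactions)) {
    r <- model@reactions[[rid]]
    df <- r$reactants
    if (nrow(df)) {
      for (k in seq_len(nrow(df))) {
        if (!(df$metabolite[k] %in% metIds))
          add("error", rid, sprintf("reactant references undeclared metabolite '%s'",
                                    df$metabolite[k]))
        if (!(df$compartment[k] %in% compIds))
          add("error", rid, sprintf("reactant references undeclared compartment '%s'",
                                    df$compartment[k]))
      }
      if (any(df$stoichiometry <= 0))
        add("error", rid, "non-positive stoichiometric coefficient")
    }
    if (!is.null(r$subsystem) && !(r$subsystem %in% model@subsystems))
      add("error", rid, sprintf("subsystem '%s' not declared in the model", r$subsystem))
    unknown <- setdiff(gprGenes(r$gpr), geneIds)
    for (g in unknown)
      add("warning", rid, sprintf("GPR references unknown gene '%s'", g))
  }

  for (mid in metIds) {
    f <- model@metabolites[[mid]]$formula
    if (!is.null(f)) {
      ok <- tryCatch({ parseFormula(f); TRUE }, error = function(e) FALSE)
      if (!ok) add("error", mid, sprintf("formula '%s' does not parse", f))
    }
  }

  if (length(issues) == 0L)
    return(data.frame(severity = character(0), entity = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
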