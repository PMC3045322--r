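## The append-only model store.
##
## Every modification enters as a pending change; an administrator approves a
## set of pending changes into a new globally numbered revision. Accepted
## model states are never stored materialized: modelAtRevision() reconstructs
## them by replaying the approved change log, which makes the log the single
## source of truth and guarantees that pending changes can never leak into a
## browse view.

#' Create an empty model store
#'
#' @param clock Zero-argument function returning the current time; injectable
#'   so tests (and replayed imports) get deterministic timestamps.
#' @return A [ModelStore-class] object.
#' @export
#' @examples
#' st <- modelStore(clock = function() as.POSIXct("2026-01-01", tz = "UTC"))
#' st
modelStore <- function(clock = Sys.time) {
  state <- new.env(parent = emptyenv())
  state$users <- list()
  state$modelsMeta <- list()
  state$changes <- list()
  state$revisions <- list()
  state$comments <- list()
  state$changeCounter <- 0L
  state$commentCounter <- 0L
  state$clock <- clock
  methods::new("ModelStore", state = state)
}

setMethod("show", "ModelStore", function(object) {
  s <- object@state
  nPending <- sum(vapply(s$changes, function(ch) ch$state == "pending", logical(1)))
  cat(sprintf("ModelStore: %d model(s), %d revision(s), %d pending change(s), %d user(s)\n",
              length(s$modelsMeta), length(s$revisions), nPending, length(s$users)))
  invisible(NULL)
})

timestampOf <- function(store) {
  format(store@state$clock(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Manage store users
#'
#' @param store A [ModelStore-class].
#' @param usr A record from [user()].
#' @return `addUser` returns the user record invisibly; `getUser` returns the
#'   record (error when unknown); `storeUsers` the named list of all users.
#' @export
addUser <- function(store, usr) {
  if (!inherits(usr, "gsmUser")) gsmvArgError("usr must come from user()")
  store@state$users[[usr$username]] <- usr
  invisible(usr)
}

#' @rdname addUser
#' @param username Username to look up.
#' @export
getUser <- function(store, username) {
  u <- store@state$users[[username]]
  if (is.null(u)) gsmvNotFound("unknown user '%s'", username)
  u
}

#' @rdname addUser
#' @export
storeUsers <- function(store) store@state$users

#' List the model ids known to a store
#'
#' @param store A [ModelStore-class].
#' @return Character vector of model ids (including not-yet-approved ones).
#' @export
storeModels <- function(store) sortIds(names(store@state$modelsMeta))

#' Set a model's public availability
#'
#' Public availability is model metadata outside version control (like file
#' uploads): administrators flip it directly. Models start private.
#'
#' @param store A [ModelStore-class].
#' @param modelId Model id.
#' @param public Logical.
#' @param admin The administrator performing the change.
#' @export
setModelPublic <- function(store, modelId, public, admin) {
  if (!inherits(admin, "gsmUser") || admin$role != "administrator")
    gsmvPermissionError("only administrators change public availability")
  meta <- store@state$modelsMeta[[modelId]]
  if (is.null(meta)) gsmvNotFound("unknown model '%s'", modelId)
  meta$public <- isTRUE(public)
  store@state$modelsMeta[[modelId]] <- meta
  invisible(store)
}

#' @rdname setModelPublic
#' @export
isModelPublic <- function(store, modelId) {
  meta <- store@state$modelsMeta[[modelId]]
  if (is.null(meta)) gsmvNotFound("unknown model '%s'", modelId)
  isTRUE(meta$public)
}

modelMeta <- function(store, modelId, create = FALSE) {
  meta <- store@state$modelsMeta[[modelId]]
  if (is.null(meta) && create) {
    meta <- list(public = FALSE, labelCounter = 0L)
    store@state$modelsMeta[[modelId]] <- meta
  }
  meta
}

## Permission check against the store's metadata.
storePermission <- function(store, usr, action, modelId, acceptedOnly = TRUE) {
  public <- if (!is.null(store@state$modelsMeta[[modelId]]))
    store@state$modelsMeta[[modelId]]$public else FALSE
  checkPermission(usr, action, modelId, public = public, acceptedOnly = acceptedOnly)
}

requirePermission <- function(store, usr, action, modelId, acceptedOnly = TRUE) {
  d <- storePermission(store, usr, action, modelId, acceptedOnly)
  if (!d$allow)
    gsmvPermissionError("permission denied for %s '%s' on model '%s': %s",
                        usr$role, usr$username, modelId, d$reason)
  invisible(d)
}

## ---- pending changes -------------------------------------------------------

#' Propose a change to a model entity
#'
#' Records a pending change; accepted views of the model are unaffected until
#' an administrator approves it. The proposing user needs edit permission on
#' the target model (administrator anywhere, editor on assigned models).
#'
#' @param store A [ModelStore-class].
#' @param usr The proposing [user()].
#' @param modelId Target model id.
#' @param kind Entity kind: `"model"`, `"compartment"`, `"metabolite"`,
#'   `"reaction"` or `"gene"`.
#' @param action `"create"`, `"update"` or `"delete"`.
#' @param entityId Entity identifier (taken from `value` for creates).
#' @param value Entity record for `action = "create"` (from [compartment()],
#'   [metabolite()], [reaction()], [gene()], or a plain list of model fields
#'   for `kind = "model"`).
#' @param fields Named list of new field values for `action = "update"`
#'   (unknown fields are rejected; `NULL` clears a field).
#' @param comment Free-text comment carried into the audit trail.
#' @return The recorded pending change (invisibly), with its `changeId`.
#' @export
proposeChange <- function(store, usr, modelId, kind, action,
                          entityId = NULL, value = NULL, fields = NULL,
                          comment = "") {
  if (!(kind %in% entityKinds)) gsmvArgError("unknown entity kind '%s'", kind)
  if (!(action %in% c("create", "update", "delete")))
    gsmvArgError("unknown change action '%s'", action)
  requirePermission(store, usr, "edit", modelId)

  fieldSet <- entityFields[[kind]]
  if (action == "create") {
    if (is.null(value)) gsmvArgError("create needs an entity record in 'value'")
    if (kind == "model") {
      entityId <- modelId
      value <- asEntity(utils::modifyList(
        list(name = modelId, organism = "", notes = "",
             subsystems = character(0), annotations = character(0)),
        value[names(value) %in% fieldSet], keep.null = TRUE), "model")
    } else {
      value <- asEntity(value, kind)
      entityId <- entityId %||% entityId(value)
    }
    if (is.null(entityId)) gsmvArgError("cannot determine entity id for create")
    deltas <- lapply(fieldSet, function(f) list(old = NULL, new = value[[f]]))
    names(deltas) <- fieldSet
  } else {
    if (is.null(entityId)) gsmvArgError("'%s' needs an entityId", action)
    current <- headEntity(store, modelId, kind, entityId)
    if (is.null(current))
      gsmvNotFound("%s '%s' does not exist in model '%s'", kind, entityId, modelId)
    if (action == "update") {
      if (is.null(fields) || !length(fields) || is.null(names(fields)))
        gsmvArgError("update needs a named list of fields")
      bad <- setdiff(names(fields), fieldSet)
      if (length(bad))
        gsmvArgError("unknown field(s) for %s: %s", kind, paste(bad, collapse = ", "))
      deltas <- lapply(names(fields), function(f)
        list(old = current[[f]], new = fields[[f]]))
      names(deltas) <- names(fields)
    } else {
      deltas <- lapply(fieldSet, function(f) list(old = current[[f]], new = NULL))
      names(deltas) <- fieldSet
    }
  }

  s <- store@state
  s$changeCounter <- s$changeCounter + 1L
  modelMeta(store, modelId, create = TRUE)
  change <- list(
    changeId = sprintf("ch%06d", s$changeCounter),
    modelId = modelId, kind = kind, entityId = entityId, action = action,
    deltas = deltas, author = usr$username, timestamp = timestampOf(store),
    comment = as.character(comment), state = "pending", revision = NA_integer_)
  s$changes[[change$changeId]] <- change
  invisible(change)
}

#' Propose a whole model as pending creates
#'
#' Convenience wrapper: records one pending create for the model header and
#' one per compartment, metabolite, gene and reaction. Approve the returned
#' change ids to make the model appear.
#'
#' @param store A [ModelStore-class].
#' @param model A [MetabolicModel-class].
#' @param usr The proposing [user()].
#' @param comment Audit comment.
#' @return Character vector of change ids (invisibly).
#' @export
proposeModel <- function(store, model, usr, comment = "initial import") {
  ids <- character(0)
  rec <- function(ch) ids[[length(ids) + 1L]] <<- ch$changeId
  rec(proposeChange(store, usr, model@modelId, "model", "create",
                    value = list(name = model@name, organism = model@organism,
                                 notes = model@notes, subsystems = model@subsystems,
                                 annotations = model@annotations),
                    comment = comment))
  for (cc in model@compartments)
    rec(proposeChange(store, usr, model@modelId, "compartment", "create",
                      value = cc, comment = comment))
  for (mm in model@metabolites)
    rec(proposeChange(store, usr, model@modelId, "metabolite", "create",
                      value = mm, comment = comment))
  for (gg in model@genes)
    rec(proposeChange(store, usr, model@modelId, "gene", "create",
                      value = gg, comment = comment))
  for (rr in model@reactions)
    rec(proposeChange(store, usr, model@modelId, "reaction", "create",
                      value = rr, comment = comment))
  invisible(ids)
}

#' Propose and approve a model in one step
#'
#' Records the model's creation as pending changes by `usr` and immediately
#' approves them as `admin` into one revision — the usual way to seed a store
#' from an import.
#'
#' @param store A [ModelStore-class].
#' @param model A [MetabolicModel-class].
#' @param usr Proposing [user()] (editor of the model or administrator).
#' @param admin Approving administrator (defaults to `usr`).
#' @param versionLabel Optional user-defined label for the new revision.
#' @return The revision record.
#' @export
publishModel <- function(store, model, usr, admin = usr, versionLabel = NULL) {
  ids <- proposeModel(store, model, usr)
  approveChanges(store, ids, admin, versionLabel)
}

#' List pending changes
#'
#' Requires permission to browse unaccepted material of the model (editors of
#' the model and administrators).
#'
#' @param store A [ModelStore-class].
#' @param usr Requesting [user()].
#' @param modelId Restrict to one model (`NULL`: all models the user may see).
#' @return List of pending change records.
#' @export
pendingChanges <- function(store, usr, modelId = NULL) {
  chs <- Filter(function(ch) ch$state == "pending", store@state$changes)
  if (!is.null(modelId)) {
    requirePermission(store, usr, "browse", modelId, acceptedOnly = FALSE)
    chs <- Filter(function(ch) ch$modelId == modelId, chs)
  } else {
    chs <- Filter(function(ch)
      storePermission(store, usr, "browse", ch$modelId, acceptedOnly = FALSE)$allow, chs)
  }
  unname(chs)
}

## ---- approval --------------------------------------------------------------

#' Approve pending changes into a new revision
#'
#' All named changes are applied atomically under one new revision number
#' (previous maximum + 1). Each affected model receives a version label: the
#' supplied one, or an auto-incremented numeric label (`"1"`, `"2"`, ...) per
#' model when none is given.
#'
#' @param store A [ModelStore-class].
#' @param changeIds Non-empty character vector of pending change ids.
#' @param admin The approving administrator.
#' @param versionLabel Optional user-defined version label for the affected
#'   models.
#' @return The revision record (list with `number`, `changeIds`, `approver`,
#'   `timestamp`, `labels`).
#' @export
approveChanges <- function(store, changeIds, admin, versionLabel = NULL) {
  if (!inherits(admin, "gsmUser")) gsmvArgError("admin must come from user()")
  d <- checkPermission(admin, "approve")
  if (!d$allow) gsmvPermissionError("permission denied: %s", d$reason)
  if (length(changeIds) == 0L)
    gsmvArgError("no changes to approve")
  s <- store@state
  for (id in changeIds) {
    ch <- s$changes[[id]]
    if (is.null(ch)) gsmvNotFound("unknown change '%s'", id)
    if (ch$state != "pending")
      gsmvStateError("change '%s' is %s, not pending", id, ch$state)
  }
  number <- length(s$revisions) + 1L
  affected <- unique(vapply(changeIds, function(id) s$changes[[id]]$modelId, character(1)))
  labels <- character(0)
  for (mid in affected) {
    meta <- modelMeta(store, mid, create = TRUE)
    if (is.null(versionLabel)) {
      meta$labelCounter <- meta$labelCounter + 1L
      labels[[mid]] <- as.character(meta$labelCounter)
    } else {
      meta$labelCounter <- meta$labelCounter + 1L
      labels[[mid]] <- as.character(versionLabel)
    }
    s$modelsMeta[[mid]] <- meta
  }
  for (id in changeIds) {
    s$changes[[id]]$state <- "approved"
    s$changes[[id]]$revision <- number
  }
  revision <- list(number = number, changeIds = as.character(changeIds),
                   approver = admin$username, timestamp = timestampOf(store),
                   labels = labels)
  s$revisions[[number]] <- revision
  revision
}

#' Reject pending changes
#'
#' Rejected changes are retained for audit, flagged `rejected`, and excluded
#' from history and snapshots.
#'
#' @inheritParams approveChanges
#' @export
rejectChanges <- function(store, changeIds, admin) {
  if (!inherits(admin, "gsmUser")) gsmvArgError("admin must come from user()")
  d <- checkPermission(admin, "approve")
  if (!d$allow) gsmvPermissionError("permission denied: %s", d$reason)
  if (length(changeIds) == 0L) gsmvArgError("no changes to reject")
  s <- store@state
  for (id in changeIds) {
    ch <- s$changes[[id]]
    if (is.null(ch)) gsmvNotFound("unknown change '%s'", id)
    if (ch$state != "pending")
      gsmvStateError("change '%s' is %s, not pending", id, ch$state)
  }
  for (id in changeIds) s$changes[[id]]$state <- "rejected"
  invisible(store)
}

#' Current (head) revision number of a store
#'
#' @param store A [ModelStore-class].
#' @return Integer; 0 for a store with no approvals yet.
#' @export
currentRevision <- function(store) length(store@state$revisions)

## ---- snapshot reconstruction ----------------------------------------------

## Approved changes for a model up to a revision, in log (= proposal) order
## within ascending revision number.
approvedChanges <- function(store, modelId, revision = NULL, kind = NULL,
                            entityId = NULL) {
  chs <- Filter(function(ch) {
    ch$state == "approved" && ch$modelId == modelId &&
      (is.null(revision) || ch$revision <= revision) &&
      (is.null(kind) || ch$kind == kind) &&
      (is.null(entityId) || identical(ch$entityId, entityId))
  }, store@state$changes)
  if (length(chs) == 0L) return(list())
  ord <- order(vapply(chs, function(ch) ch$revision, integer(1)),
               seq_along(chs))
  unname(chs[ord])
}

applyDeltas <- function(rec, ch, kind) {
  if (ch$action == "create") {
    rec <- lapply(ch$deltas, function(d) d$new)
    names(rec) <- names(ch$deltas)
    return(asEntity(rec, kind))
  }
  if (ch$action == "delete") return(NULL)
  for (f in names(ch$deltas)) rec <- setField(rec, f, ch$deltas[[f]]$new)
  asEntity(rec, kind)
}

#' Reconstruct a model snapshot at a revision
#'
#' Replays every approved change with revision number at most `revision` for
#' the model: each entity appears in the state given by its latest approved
#' change, entities created later are absent, and pending or rejected changes
#' never contribute.
#'
#' @param store A [ModelStore-class].
#' @param modelId Model id.
#' @param revision Revision number (`NULL` for the current head).
#' @return A [MetabolicModel-class] snapshot, with `versionLabel` set to the
#'   label assigned at the latest approval affecting the model.
#' @export
modelAtRevision <- function(store, modelId, revision = NULL) {
  maxRev <- currentRevision(store)
  if (is.null(revision)) revision <- maxRev
  revision <- as.integer(revision)
  if (is.na(revision) || revision < 0L)
    gsmvArgError("revision must be a non-negative integer")
  if (revision > maxRev)
    gsmvArgError("revision %d exceeds the store head (%d)", revision, maxRev)

  ents <- list(model = list(), compartment = list(), metabolite = list(),
               reaction = list(), gene = list())
  for (ch in approvedChanges(store, modelId, revision)) {
    cur <- ents[[ch$kind]][[ch$entityId]]
    if (ch$action != "create" && is.null(cur)) next  # deleted before this edit
    newRec <- applyDeltas(cur, ch, ch$kind)
    ents[[ch$kind]][ch$entityId] <- list(newRec)
    if (is.null(newRec)) ents[[ch$kind]][[ch$entityId]] <- NULL
  }
  info <- ents$model[[modelId]]
  if (is.null(info))
    gsmvNotFound("model '%s' does not exist at revision %d", modelId, revision)

  label <- ""
  for (rev in store@state$revisions) {
    if (rev$number <= revision && modelId %in% names(rev$labels))
      label <- rev$labels[[modelId]]
  }

  pick <- function(kind) {
    recs <- ents[[kind]]
    recs[sortIds(names(recs))]
  }
  metabolicModel(modelId,
    name = info$name %||% modelId, organism = info$organism %||% "",
    compartments = unname(pick("compartment")),
    metabolites = unname(pick("metabolite")),
    reactions = unname(pick("reaction")),
    genes = unname(pick("gene")),
    subsystems = info$subsystems %||% character(0),
    annotations = info$annotations %||% character(0),
    notes = info$notes %||% "",
    versionLabel = label)
}

#' Browse a model snapshot with permission checking
#'
#' The accepted-state view the four user classes get: permission is evaluated
#' for the accepted state of the model, then the snapshot is reconstructed
#' from approved changes only, so pending material cannot appear.
#'
#' @inheritParams modelAtRevision
#' @param usr Requesting [user()].
#' @export
browseModel <- function(store, usr, modelId, revision = NULL) {
  requirePermission(store, usr, "browse", modelId, acceptedOnly = TRUE)
  modelAtRevision(store, modelId, revision)
}

## Head state of one entity (accepted changes only), or NULL.
headEntity <- function(store, modelId, kind, entityId) {
  rec <- NULL
  for (ch in approvedChanges(store, modelId, kind = kind, entityId = entityId)) {
    if (ch$action == "create") rec <- applyDeltas(NULL, ch, kind)
    else if (is.null(rec)) next
    else rec <- applyDeltas(rec, ch, kind)
  }
  ## a pending create also makes the entity addressable for follow-up edits
  if (is.null(rec)) {
    for (ch in store@state$changes) {
      if (ch$state == "pending" && ch$modelId == modelId && ch$kind == kind &&
          identical(ch$entityId, entityId) && ch$action == "create")
        rec <- applyDeltas(NULL, ch, kind)
    }
  }
  rec
}

## ---- history ---------------------------------------------------------------

#' Audit history of an entity
#'
#' Ordered list of approved modifications: the creation first, then each
#' edit with the revision number, author, timestamp, comment, and the field
#' differences against the previous version. Replaying the diffs from the
#' creation reproduces the entity's head state.
#'
#' @param store A [ModelStore-class].
#' @param modelId Model id.
#' @param kind Entity kind.
#' @param entityId Entity identifier.
#' @return An `EntityHistory`: list of entries, each with `revision`,
#'   `author`, `timestamp`, `comment`, `action`, `diffs`.
#' @export
entityHistory <- function(store, modelId, kind, entityId) {
  if (!(kind %in% entityKinds)) gsmvArgError("unknown entity kind '%s'", kind)
  chs <- approvedChanges(store, modelId, kind = kind, entityId = entityId)
  if (length(chs) == 0L)
    gsmvNotFound("no history for %s '%s' in model '%s'", kind, entityId, modelId)
  entries <- lapply(chs, function(ch) {
    list(revision = ch$revision, author = ch$author, timestamp = ch$timestamp,
         comment = ch$comment, action = ch$action, diffs = ch$deltas)
  })
  structure(list(modelId = modelId, kind = kind, entityId = entityId,
                 entries = entries), class = "EntityHistory")
}

#' @export
print.EntityHistory <- function(x, ...) {
  cat(sprintf("History of %s '%s' in model '%s' (%d entr%s)\n", x$kind,
              x$entityId, x$modelId, length(x$entries),
              if (length(x$entries) == 1L) "y" else "ies"))
  for (e in x$entries) {
    cat(sprintf("  r%d %s %s [%s] %s: %s\n", e$revision, e$timestamp, e$author,
                e$action, paste(names(e$diffs), collapse = ","), e$comment))
  }
  invisible(x)
}

#' Replay a history into an entity record
#'
#' Applies the diffs of an [entityHistory()] from the creation entry onward.
#'
#' @param history An `EntityHistory`.
#' @return The entity record after the last entry (or `NULL` if deleted).
#' @export
replayHistory <- function(history) {
  rec <- NULL
  for (e in history$entries) {
    ch <- list(action = e$action, deltas = e$diffs)
    rec <- applyDeltas(rec, ch, history$kind)
  }
  rec
}

## ---- comment threads -------------------------------------------------------

#' Attach a comment thread entry to an entity
#'
#' Discussion threads attachable to any stored entity (or to a model as a
#' whole); create and list only, outside version control.
#'
#' @param store A [ModelStore-class].
#' @param usr Authoring [user()].
#' @param modelId Model id.
#' @param kind,entityId Optional entity address; `NULL` attaches to the model.
#' @param text Comment text.
#' @export
addComment <- function(store, usr, modelId, text, kind = NULL, entityId = NULL) {
  requirePermission(store, usr, "browse", modelId,
                    acceptedOnly = !(usr$role %in% c("editor", "administrator")))
  s <- store@state
  s$commentCounter <- s$commentCounter + 1L
  cm <- list(commentId = sprintf("cm%06d", s$commentCounter),
             modelId = modelId, kind = kind, entityId = entityId,
             author = usr$username, timestamp = timestampOf(store),
             text = as.character(text))
  s$comments[[cm$commentId]] <- cm
  invisible(cm)
}

#' @rdname addComment
#' @export
listComments <- function(store, modelId, kind = NULL, entityId = NULL) {
  unname(Filter(function(cm) {
    cm$modelId == modelId &&
      (is.null(kind) || identical(cm$kind, kind)) &&
      (is.null(entityId) || identical(cm$entityId, entityId))
  }, store@state$comments))
}
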