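## Store persistence: a single JSON file with a versioned header.
##
## Values inside change deltas are heterogeneous (scalars, vectors, reactant
## tables, nested GPR trees), so they are serialized through a small
## type-tagged encoder rather than trusting JSON's native coercions.

storeFormatName <- "gsmvault-store"
storeFormatVersion <- 1L

encodeValue <- function(x) {
  if (is.null(x)) return(list(t = "null"))
  if (inherits(x, "GeneAssociation"))
    return(list(t = "gpr", v = gprToString(x)))
  if (is.data.frame(x))
    return(list(t = "df", cols = lapply(x, encodeValue)))
  if (is.atomic(x)) {
    t <- if (is.logical(x)) "lgl" else if (is.integer(x)) "int"
         else if (is.numeric(x)) "num" else "chr"
    out <- list(t = t, v = as.list(unname(x)))
    if (!is.null(names(x))) out$names <- as.list(names(x))
    return(out)
  }
  if (is.list(x)) {
    out <- list(t = "list", items = lapply(unname(x), encodeValue))
    if (!is.null(names(x))) out$names <- as.list(names(x))
    if (!is.null(attr(x, "class"))) out$class <- as.list(class(x))
    return(out)
  }
  gsmvArgError("cannot serialize value of class %s", paste(class(x), collapse = "/"))
}

decodeValue <- function(e) {
  t <- e$t
  if (t == "null") return(NULL)
  if (t == "gpr") return(parseGPR(e$v))
  if (t == "df") {
    cols <- lapply(e$cols, decodeValue)
    if (length(cols) == 0L) return(data.frame())
    df <- data.frame(cols, stringsAsFactors = FALSE)
    names(df) <- names(e$cols)
    return(df)
  }
  if (t %in% c("lgl", "int", "num", "chr")) {
    v <- unlist(e$v, use.names = FALSE)
    v <- switch(t, lgl = as.logical(v), int = as.integer(v),
                num = as.numeric(v), chr = as.character(v))
    if (is.null(v)) v <- switch(t, lgl = logical(0), int = integer(0),
                                num = numeric(0), chr = character(0))
    if (!is.null(e$names)) names(v) <- unlist(e$names, use.names = FALSE)
    return(v)
  }
  if (t == "list") {
    v <- lapply(e$items, decodeValue)
    if (!is.null(e$names)) names(v) <- unlist(e$names, use.names = FALSE)
    if (!is.null(e$class)) class(v) <- unlist(e$class, use.names = FALSE)
    return(v)
  }
  gsmvParseError("unknown value tag '%s' in store file", t)
}

encodeChange <- function(ch) {
  list(changeId = ch$changeId, modelId = ch$modelId, kind = ch$kind,
       entityId = ch$entityId, action = ch$action,
       deltas = lapply(ch$deltas, function(d)
         list(old = encodeValue(d$old), new = encodeValue(d$new))),
       author = ch$author, timestamp = ch$timestamp, comment = ch$comment,
       state = ch$state, revision = ch$revision)
}

decodeChange <- function(e) {
  deltas <- lapply(e$deltas, function(d)
    list(old = decodeValue(d$old), new = decodeValue(d$new)))
  list(changeId = e$changeId, modelId = e$modelId, kind = e$kind,
       entityId = e$entityId, action = e$action, deltas = deltas,
       author = e$author, timestamp = e$timestamp, comment = e$comment,
       state = e$state,
       revision = if (is.null(e$revision)) NA_integer_ else as.integer(e$revision))
}

#' Save / load a model store
#'
#' The on-disk format is a single JSON document: a header naming the format
#' and its version, the user records, model metadata, the full change log
#' (pending, approved and rejected), revisions and comments. The injected
#' clock is not persisted; `readStore` installs the clock you pass.
#'
#' @param store A [ModelStore-class].
#' @param path File path.
#' @export
writeStore <- function(store, path) {
  s <- store@state
  doc <- list(
    format = storeFormatName, formatVersion = storeFormatVersion,
    users = lapply(unname(s$users), function(u)
      list(username = u$username, role = u$role,
           assignedModels = as.list(u$assignedModels))),
    modelsMeta = lapply(s$modelsMeta, function(m)
      list(public = m$public, labelCounter = m$labelCounter)),
    modelIds = as.list(names(s$modelsMeta)),
    changes = lapply(unname(s$changes), encodeChange),
    revisions = lapply(s$revisions, function(r)
      list(number = r$number, changeIds = as.list(r$changeIds),
           approver = r$approver, timestamp = r$timestamp,
           labels = as.list(r$labels))),
    comments = lapply(unname(s$comments), function(cm) cm),
    changeCounter = s$changeCounter, commentCounter = s$commentCounter)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeStore
#' @param clock Clock function to install on the loaded store.
#' @export
readStore <- function(path, clock = Sys.time) {
  if (!file.exists(path)) gsmvNotFound("store file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, storeFormatName))
    gsmvParseError("not a %s file: %s", storeFormatName, path)
  if (doc$formatVersion > storeFormatVersion)
    gsmvParseError("store format version %s is newer than supported (%d)",
                   doc$formatVersion, storeFormatVersion)
  store <- modelStore(clock = clock)
  s <- store@state
  for (u in doc$users) {
    addUser(store, user(u$username, u$role,
                        unlist(u$assignedModels, use.names = FALSE) %||% character(0)))
  }
  ids <- unlist(doc$modelIds, use.names = FALSE)
  s$modelsMeta <- stats::setNames(lapply(doc$modelsMeta, function(m)
    list(public = isTRUE(m$public), labelCounter = as.integer(m$labelCounter))),
    ids)
  chs <- lapply(doc$changes, decodeChange)
  s$changes <- stats::setNames(chs, vapply(chs, function(ch) ch$changeId, character(1)))
  s$revisions <- lapply(doc$revisions, function(r)
    list(number = as.integer(r$number),
         changeIds = unlist(r$changeIds, use.names = FALSE),
         approver = r$approver, timestamp = r$timestamp,
         labels = vapply(r$labels, as.character, character(1))))
  cms <- lapply(doc$comments, function(cm) {
    cm$kind <- cm$kind %||% NULL
    cm$entityId <- cm$entityId %||% NULL
    cm
  })
  s$comments <- stats::setNames(cms, vapply(cms, function(cm) cm$commentId, character(1)))
  s$changeCounter <- as.integer(doc$changeCounter)
  s$commentCounter <- as.integer(doc$commentCounter)
  store
}
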