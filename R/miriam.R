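## MIRIAM annotation handling.
##
## Each MIRIAM reference is carried as a single URN string
## "urn:miriam:<datatype>:<identifier>"; identifiers.org URIs are accepted on
## input. Resolution to web addresses goes through a flat, user-extensible
## datatype -> URL-template registry bundled under inst/extdata.

#' Load the MIRIAM datatype registry
#'
#' The registry is a two-column tab-separated file mapping datatype keys to
#' URL templates containing an `{id}` placeholder. The bundled file covers the
#' datatypes common in metabolic models (ChEBI, KEGG, EC, UniProt, ...); pass
#' your own file, or append entries to the returned vector, to register
#' additional external databases.
#'
#' @param path Registry file; `NULL` loads the bundled registry.
#' @return Named character vector: datatype -> URL template.
#' @export
#' @examples
#' reg <- loadMiriamRegistry()
#' reg["chebi"]
loadMiriamRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "miriam_registry.tsv", package = "gsmvault")
  if (!nzchar(path) || !file.exists(path))
    gsmvArgError("registry file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("datatype", "url_template") %in% names(tab)))
    gsmvParseError("registry file must have columns 'datatype' and 'url_template'")
  stats::setNames(tab$url_template, tab$datatype)
}

#' Build a MIRIAM URN
#'
#' @param datatype Registry key, e.g. `"chebi"` or `"kegg.reaction"`.
#' @param identifier Accession within that datatype.
#' @return Single URN string `"urn:miriam:<datatype>:<identifier>"` (the
#'   identifier is percent-encoded where needed).
#' @export
miriamURN <- function(datatype, identifier) {
  if (!nzchar(datatype) || !nzchar(identifier))
    gsmvArgError("datatype and identifier must be non-empty")
  paste0("urn:miriam:", datatype, ":", utils::URLencode(identifier, reserved = TRUE))
}

#' Parse a MIRIAM reference string
#'
#' Accepts the URN dialect `"urn:miriam:<datatype>:<identifier>"` and
#' identifiers.org URIs (`"https://identifiers.org/<datatype>/<id>"` or the
#' legacy `"http://identifiers.org/<datatype>:<id>"` form).
#'
#' @param text Reference string.
#' @return List with elements `datatype`, `identifier`, `qualifier`
#'   (always `"is"` for plain references).
#' @export
#' @examples
#' parseMiriam("urn:miriam:ec-code:1.1.1.1")
#' parseMiriam("https://identifiers.org/kegg.reaction/R00299")
parseMiriam <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    gsmvParseError("MIRIAM reference must be a single string")
  if (grepl("^urn:miriam:", text)) {
    rest <- sub("^urn:miriam:", "", text)
    k <- regexpr(":", rest, fixed = TRUE)
    if (k < 1L)
      gsmvParseError("malformed MIRIAM URN: %s", text)
    return(list(datatype = substr(rest, 1L, k - 1L),
                identifier = utils::URLdecode(substr(rest, k + 1L, nchar(rest))),
                qualifier = "is"))
  }
  if (grepl("^https?://identifiers\\.org/", text)) {
    rest <- sub("^https?://identifiers\\.org/", "", text)
    if (grepl("/", rest, fixed = TRUE)) {
      k <- regexpr("/", rest, fixed = TRUE)
      return(list(datatype = substr(rest, 1L, k - 1L),
                  identifier = utils::URLdecode(substr(rest, k + 1L, nchar(rest))),
                  qualifier = "is"))
    }
    k <- regexpr(":", rest, fixed = TRUE)
    if (k > 0L)
      return(list(datatype = substr(rest, 1L, k - 1L),
                  identifier = utils::URLdecode(substr(rest, k + 1L, nchar(rest))),
                  qualifier = "is"))
  }
  gsmvParseError("unrecognized MIRIAM reference: %s", text)
}

#' Resolve a MIRIAM reference to a web address
#'
#' Substitutes the identifier into the registry's URL template for the
#' datatype. Unresolvable datatypes yield the marker string
#' `"unresolved:<datatype>:<identifier>"`, never a malformed URL.
#'
#' @param ref A URN/identifiers.org string or the list from [parseMiriam()].
#' @param registry Registry mapping from [loadMiriamRegistry()].
#' @return URL string, or the `"unresolved:..."` marker.
#' @export
#' @examples
#' miriamToURL("urn:miriam:ec-code:1.1.1.1")
miriamToURL <- function(ref, registry = loadMiriamRegistry()) {
  if (is.character(ref)) ref <- parseMiriam(ref)
  if (!all(c("datatype", "identifier") %in% names(ref)))
    gsmvArgError("ref must be a MIRIAM string or a parsed reference")
  tmpl <- if (ref$datatype %in% names(registry)) registry[[ref$datatype]] else NULL
  if (is.null(tmpl) || is.na(tmpl))
    return(paste0("unresolved:", ref$datatype, ":", ref$identifier))
  gsub("{id}", utils::URLencode(ref$identifier, reserved = TRUE), tmpl, fixed = TRUE)
}
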