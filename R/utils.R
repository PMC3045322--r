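## Internal helpers shared across modules.

## Classed conditions so callers (and the CLI) can map failures to
## machine-readable categories.
gsmvStop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "gsmv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

gsmvArgError   <- function(fmt, ...) gsmvStop("gsmv_argument_error", fmt, ...)
gsmvParseError <- function(fmt, ...) gsmvStop("gsmv_parse_error", fmt, ...)
gsmvLookupError <- function(fmt, ...) gsmvStop("gsmv_lookup_error", fmt, ...)
gsmvNotFound   <- function(fmt, ...) gsmvStop("gsmv_notfound_error", fmt, ...)
gsmvPermissionError <- function(fmt, ...) gsmvStop("gsmv_permission_error", fmt, ...)
gsmvStateError <- function(fmt, ...) gsmvStop("gsmv_state_error", fmt, ...)

## Run code with a temporary RNG state seeded from `seed`, restoring the
## caller's stream afterwards. Keeps fixture generation reproducible without
## clobbering user RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Scalar string with NULL/NA treated as absent.
chrOrNull <- function(x) {
  if (is.null(x) || length(x) == 0L || (length(x) == 1L && is.na(x))) NULL else as.character(x)
}

isAbsent <- function(x) is.null(x) || length(x) == 0L || (length(x) == 1L && is.na(x))

## Assign possibly-NULL value into a list without dropping the slot position.
setField <- function(rec, field, value) {
  rec[field] <- list(value)
  rec
}

## Deterministic sort for entity identifiers (C locale, byte order).
sortIds <- function(x) {
  if (length(x) == 0L) return(character(0))
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x)
}

fmtNum <- function(x) {
  ## Minimal decimal rendering: integers without trailing ".0", decimals trimmed.
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == round(v) && abs(v) < 1e15) return(sprintf("%d", as.integer(round(v))))
    sub("0+$", "", sprintf("%.10f", v))
  }, character(1))
}
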