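## Chemical formula parsing and formatting.
##
## Element counts are the currency of the balance check: a named numeric
## vector, names matching [A-Z][a-z]* (opaque placeholder tokens such as "R"
## or "X", common in lumped biomass species, are accepted unless strict = TRUE),
## counts strictly positive and possibly fractional.

## IUPAC symbols for strict mode.
.knownElements <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
  "Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm",
  "Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os",
  "Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn","Fr","Ra","Ac","Th","Pa",
  "U","Np","Pu")

#' Parse a chemical formula into element counts
#'
#' Grammar: a sequence of element tokens (`[A-Z][a-z]*`), each followed by an
#' optional count (default 1, decimals allowed), and parenthesized groups with
#' a trailing multiplier, e.g. `"Ca(OH)2"`. Counts aggregate across repeats
#' and groups.
#'
#' @param text Formula string.
#' @param strict If `TRUE`, reject symbols that are not IUPAC elements
#'   (placeholder tokens like `"R"` and `"X"` are otherwise allowed).
#' @return Named numeric vector of element counts, names in Hill order
#'   (C, H, then alphabetical).
#' @export
#' @examples
#' parseFormula("C6H12O6")
#' parseFormula("Ca(OH)2")
parseFormula <- function(text, strict = FALSE) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    gsmvParseError("formula parse error: empty formula")
  pat <- "([A-Z][a-z]*)|([0-9]+(\\.[0-9]+)?)|\\(|\\)"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  toks <- if (identical(m[1], -1L)) character(0) else regmatches(text, list(m))[[1]]
  starts <- as.integer(m)
  ## Any character not covered by a token is illegal.
  covered <- rep(FALSE, nchar(text))
  if (length(toks)) {
    for (k in seq_along(toks))
      covered[starts[k]:(starts[k] + nchar(toks[k]) - 1L)] <- TRUE
  }
  if (!all(covered)) {
    bad <- which(!covered)[1]
    gsmvParseError("formula parse error at position %d: illegal character '%s' in \"%s\"",
                   bad, substr(text, bad, bad), text)
  }

  st <- new.env(parent = emptyenv())
  st$i <- 1L
  peek <- function() if (st$i <= length(toks)) toks[st$i] else NA_character_
  pos <- function() if (st$i <= length(toks)) starts[st$i] else nchar(text) + 1L
  advance <- function() { tk <- toks[st$i]; st$i <- st$i + 1L; tk }
  isCount <- function(tk) !is.na(tk) && grepl("^[0-9]", tk)

  readCount <- function() {
    if (!isCount(peek())) return(1)
    v <- as.numeric(advance())
    if (v == 0)
      gsmvParseError("formula parse error at position %d: zero count in \"%s\"",
                     starts[st$i - 1L], text)
    v
  }

  addCounts <- function(acc, add, mult = 1) {
    for (el in names(add)) acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0) + add[[el]] * mult
    acc
  }

  parseSeq <- function(depth) {
    acc <- numeric(0)
    repeat {
      tk <- peek()
      if (is.na(tk)) {
        if (depth > 0L)
          gsmvParseError("formula parse error: unbalanced parentheses in \"%s\"", text)
        break
      }
      if (tk == ")") {
        if (depth == 0L)
          gsmvParseError("formula parse error at position %d: unbalanced ')' in \"%s\"",
                         pos(), text)
        break
      }
      if (tk == "(") {
        advance()
        grp <- parseSeq(depth + 1L)
        if (!identical(peek(), ")"))
          gsmvParseError("formula parse error: unbalanced parentheses in \"%s\"", text)
        advance()
        acc <- addCounts(acc, grp, readCount())
      } else if (isCount(tk)) {
        gsmvParseError("formula parse error at position %d: count without element in \"%s\"",
                       pos(), text)
      } else {
        el <- advance()
        if (strict && !(el %in% .knownElements))
          gsmvParseError("formula parse error: unknown element symbol '%s' in \"%s\"",
                         el, text)
        acc <- addCounts(acc, stats::setNames(readCount(), el))
      }
    }
    acc
  }

  counts <- parseSeq(0L)
  if (length(counts) == 0L)
    gsmvParseError("formula parse error: no elements in \"%s\"", text)
  counts[hillOrder(names(counts))]
}

## Hill order: C first, then H, then everything else alphabetically;
## if no carbon, everything alphabetically.
hillOrder <- function(symbols) {
  if ("C" %in% symbols) {
    c(intersect(c("C", "H"), symbols), sortIds(setdiff(symbols, c("C", "H"))))
  } else {
    sortIds(symbols)
  }
}

#' Format element counts as a formula string
#'
#' Elements are emitted in Hill order; unit counts are omitted. Formatting and
#' re-parsing is the identity on the counts.
#'
#' @param counts Named numeric vector as returned by [parseFormula()].
#' @return Formula string.
#' @export
#' @examples
#' formatFormula(c(C = 6, H = 12, O = 6))
formatFormula <- function(counts) {
  if (length(counts) == 0L || is.null(names(counts)))
    gsmvArgError("counts must be a non-empty named numeric vector")
  if (any(counts <= 0)) gsmvArgError("element counts must be positive")
  ord <- hillOrder(names(counts))
  paste(vapply(ord, function(el) {
    n <- counts[[el]]
    if (n == 1) el else paste0(el, fmtNum(n))
  }, character(1)), collapse = "")
}
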