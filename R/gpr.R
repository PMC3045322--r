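## Gene-protein-reaction (GPR) Boolean rules.
##
## A GPR states which gene combinations enable a reaction, e.g.
## "gene1 AND [gene2 OR gene3]": isoenzymes are OR-ed, complex subunits
## AND-ed. Trees are nested lists: leaf nodes list(kind = "leaf", gene = id),
## operator nodes list(kind = "and"|"or", children = list(...)) with arity
## >= 2. Every node carries class "GeneAssociation".

gprNode <- function(kind, gene = NULL, children = NULL) {
  structure(list(kind = kind, gene = gene, children = children),
            class = "GeneAssociation")
}

#' Combine GPR subtrees
#'
#' @param ... Two or more `GeneAssociation` nodes or gene abbreviation strings
#'   (wrapped as leaves).
#' @return A `GeneAssociation` operator node.
#' @export
#' @examples
#' gprAnd("g1", gprOr("g2", "g3"))
gprAnd <- function(...) gprOp("and", list(...))

#' @rdname gprAnd
#' @export
gprOr <- function(...) gprOp("or", list(...))

#' @rdname gprAnd
#' @param gene Gene abbreviation.
#' @export
gprLeaf <- function(gene) gprNode("leaf", gene = as.character(gene))

gprOp <- function(kind, children) {
  children <- lapply(children, function(ch) {
    if (is.character(ch)) gprLeaf(ch) else ch
  })
  if (length(children) < 2L)
    gsmvArgError("%s nodes need at least two children", toupper(kind))
  ok <- vapply(children, inherits, logical(1), "GeneAssociation")
  if (!all(ok)) gsmvArgError("GPR children must be GeneAssociation nodes or strings")
  gprNode(kind, children = children)
}

gprTokenize <- function(text) {
  m <- gregexpr("\\[|\\]|\\(|\\)|[^\\s\\[\\]()]+", text, perl = TRUE)[[1]]
  if (identical(m[1], -1L)) gsmvParseError("GPR parse error: empty expression")
  data.frame(
    token = regmatches(text, list(m))[[1]],
    pos = as.integer(m),
    stringsAsFactors = FALSE
  )
}

#' Parse a gene-protein-reaction rule
#'
#' Grammar: gene abbreviations and the case-insensitive operators `AND` / `OR`
#' separated by whitespace, with grouping by square brackets or parentheses.
#' Without brackets, `AND` binds tighter than `OR`. Chains of the same
#' operator at one level are flattened into a single node
#' (`"a OR b OR c"` parses to one `OR` with three children); explicit
#' grouping is preserved.
#'
#' @param text GPR string, e.g. `"gene1 AND [gene2 OR gene3]"`.
#' @return A `GeneAssociation` tree. [gprToString()] serializes it back;
#'   re-parsing the serialization yields an identical tree.
#' @export
#' @examples
#' tree <- parseGPR("gene1 AND [gene2 OR gene3]")
#' gprToString(tree)
#' gprToString(tree, style = "cobra")
parseGPR <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    gsmvParseError("GPR parse error: empty expression")
  toks <- gprTokenize(text)
  st <- new.env(parent = emptyenv())
  st$i <- 1L

  peek <- function() if (st$i <= nrow(toks)) toks$token[st$i] else NA_character_
  pos <- function() if (st$i <= nrow(toks)) toks$pos[st$i] else nchar(text) + 1L
  advance <- function() { tk <- toks$token[st$i]; st$i <- st$i + 1L; tk }
  isOp <- function(tk, op) !is.na(tk) && tolower(tk) == op

  parseFactor <- function() {
    tk <- peek()
    if (is.na(tk))
      gsmvParseError("GPR parse error at position %d: unexpected end of expression", pos())
    if (tk %in% c("[", "(")) {
      open <- advance()
      close <- if (open == "[") "]" else ")"
      if (identical(peek(), close))
        gsmvParseError("GPR parse error at position %d: empty group", pos())
      node <- parseExpr()
      if (!identical(peek(), close))
        gsmvParseError("GPR parse error at position %d: expected '%s'", pos(), close)
      advance()
      return(node)
    }
    if (tk %in% c("]", ")"))
      gsmvParseError("GPR parse error at position %d: unmatched '%s'", pos(), tk)
    if (isOp(tk, "and") || isOp(tk, "or"))
      gsmvParseError("GPR parse error at position %d: dangling operator '%s'", pos(), tk)
    gprLeaf(advance())
  }

  parseTerm <- function() {
    factors <- list(parseFactor())
    while (isOp(peek(), "and")) {
      advance()
      factors <- c(factors, list(parseFactor()))
    }
    if (length(factors) == 1L) factors[[1]] else gprNode("and", children = factors)
  }

  parseExpr <- function() {
    terms <- list(parseTerm())
    while (isOp(peek(), "or")) {
      advance()
      terms <- c(terms, list(parseTerm()))
    }
    if (length(terms) == 1L) terms[[1]] else gprNode("or", children = terms)
  }

  node <- parseExpr()
  if (!is.na(peek()))
    gsmvParseError("GPR parse error at position %d: unexpected token '%s'", pos(), peek())
  node
}

#' Serialize a GPR tree
#'
#' Two dialects: `"brackets"` emits upper-case operators with square-bracket
#' grouping (`"gene1 AND [gene2 OR gene3]"`); `"cobra"` emits the COBRA
#' toolbox notes convention, lower-case operators with parentheses
#' (`"gene1 and (gene2 or gene3)"`). Non-leaf children are always grouped,
#' so the output re-parses to the identical tree.
#'
#' @param assoc A `GeneAssociation` tree.
#' @param style `"brackets"` or `"cobra"`.
#' @return A single string.
#' @export
gprToString <- function(assoc, style = c("brackets", "cobra")) {
  style <- match.arg(style)
  if (!inherits(assoc, "GeneAssociation"))
    gsmvArgError("assoc must be a GeneAssociation tree")
  open <- if (style == "brackets") "[" else "("
  close <- if (style == "brackets") "]" else ")"
  opText <- function(kind) {
    if (style == "brackets") toupper(kind) else tolower(kind)
  }
  rec <- function(node) {
    if (node$kind == "leaf") return(node$gene)
    parts <- vapply(node$children, function(ch) {
      s <- rec(ch)
      if (ch$kind == "leaf") s else paste0(open, s, close)
    }, character(1))
    paste(parts, collapse = paste0(" ", opText(node$kind), " "))
  }
  rec(assoc)
}

#' Evaluate a GPR tree against a set of present genes
#'
#' A leaf is true iff its gene is present; `AND`/`OR` nodes are logical
#' conjunction/disjunction. Enables gene-deletion reasoning on stored rules.
#'
#' @param assoc A `GeneAssociation` tree.
#' @param present Character vector of present gene abbreviations.
#' @return Logical scalar.
#' @export
#' @examples
#' evaluateGPR(parseGPR("g1 AND [g2 OR g3]"), c("g1", "g2"))
evaluateGPR <- function(assoc, present) {
  if (!inherits(assoc, "GeneAssociation"))
    gsmvArgError("assoc must be a GeneAssociation tree")
  present <- as.character(present)
  rec <- function(node) {
    switch(node$kind,
      leaf = node$gene %in% present,
      and = all(vapply(node$children, rec, logical(1))),
      or = any(vapply(node$children, rec, logical(1))),
      gsmvArgError("invalid GPR node kind '%s'", node$kind))
  }
  rec(assoc)
}

#' List the genes referenced by a GPR tree
#'
#' @param assoc A `GeneAssociation` tree (or `NULL`).
#' @return Character vector of distinct gene abbreviations (possibly empty).
#' @export
gprGenes <- function(assoc) {
  if (is.null(assoc)) return(character(0))
  out <- character(0)
  rec <- function(node) {
    if (node$kind == "leaf") out[[length(out) + 1L]] <<- node$gene
    else lapply(node$children, rec)
    invisible(NULL)
  }
  rec(assoc)
  unique(out)
}

#' @export
print.GeneAssociation <- function(x, ...) {
  cat("<GPR> ", gprToString(x), "\n", sep = "")
  invisible(x)
}
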