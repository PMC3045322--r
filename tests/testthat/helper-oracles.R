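## Independent oracles and small fixtures shared across the test files.

## ---- GPR ------------------------------------------------------------------

## Random GPR tree over genes g1..gN.
randomGprTree <- function(genePool, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    return(gprLeaf(sample(genePool, 1)))
  }
  op <- sample(c("and", "or"), 1)
  n <- sample(2:3, 1)
  children <- lapply(seq_len(n), function(i) randomGprTree(genePool, depth - 1))
  if (op == "and") do.call(gprAnd, children) else do.call(gprOr, children)
}

## Truth-table oracle: translate the tree into an R logical expression and
## eval() it against an environment binding each gene to TRUE/FALSE. This
## routes evaluation through R's own parser and logic, independent of
## evaluateGPR's recursion.
gprEvalOracle <- function(tree, present, genePool) {
  expr <- local({
    rec <- function(node) {
      if (node$kind == "leaf") return(node$gene)
      op <- if (node$kind == "and") " & " else " | "
      paste0("(", paste(vapply(node$children, rec, character(1)), collapse = op), ")")
    }
    rec(tree)
  })
  env <- new.env()
  for (g in genePool) assign(g, g %in% present, envir = env)
  eval(parse(text = expr), envir = env)
}

## ---- formulas -------------------------------------------------------------

## Naive character-scan oracle for flat (ungrouped) formulas: walk token by
## token with a single regex, accumulating counts.
formulaScanOracle <- function(text) {
  counts <- numeric(0)
  m <- gregexpr("[A-Z][a-z]*|[0-9]+(\\.[0-9]+)?", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  i <- 1
  while (i <= length(toks)) {
    el <- toks[i]
    n <- 1
    if (i + 1 <= length(toks) && grepl("^[0-9]", toks[i + 1])) {
      n <- as.numeric(toks[i + 1]); i <- i + 1
    }
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + n
    i <- i + 1
  }
  counts
}

## Random element counts (ground truth known by construction).
randomCounts <- function(maxElements = 5) {
  pool <- c("C", "H", "O", "N", "P", "S", "Fe", "Mg", "Na", "Cl", "Zn", "R")
  els <- sample(pool, sample(1:maxElements, 1))
  stats::setNames(sample(1:20, length(els), replace = TRUE), els)
}

## Build a formula string with random (possibly nested) grouping whose
## expansion is known by construction. Returns list(text, counts).
randomGroupedFormula <- function(depth = 2) {
  if (depth == 0 || stats::runif(1) < 0.4) {
    counts <- randomCounts(3)
    text <- paste(vapply(names(counts), function(el) {
      if (counts[[el]] == 1 && stats::runif(1) < 0.5) el
      else paste0(el, counts[[el]])
    }, character(1)), collapse = "")
    return(list(text = text, counts = counts))
  }
  nParts <- sample(1:3, 1)
  parts <- lapply(seq_len(nParts), function(i) randomGroupedFormula(depth - 1))
  mult <- sample(1:4, 1)
  counts <- numeric(0)
  for (p in parts)
    for (el in names(p$counts))
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + p$counts[[el]] * mult
  text <- paste0("(", paste(vapply(parts, function(p) p$text, character(1)),
                            collapse = ""), ")",
                 if (mult != 1) mult else "")
  list(text = text, counts = counts)
}

expectSameCounts <- function(got, want) {
  expect_setequal(names(got), names(want))
  ord <- sort(names(want))
  expect_equal(unname(got[ord]), unname(want[ord]))
}

## ---- comparator -----------------------------------------------------------

## All-pairs brute force + maximum bipartite matching (igraph). Independent of
## the greedy strategy used by compareModels.
bruteForceVenn <- function(modelA, modelB) {
  matchMatrix <- function(idsA, idsB, fun) {
    outer(seq_along(idsA), seq_along(idsB), Vectorize(function(i, j)
      fun(idsA[i], idsB[j])$matched))
  }
  countsFor <- function(idsA, idsB, fun) {
    if (length(idsA) == 0 || length(idsB) == 0)
      return(c(uniqueA = length(idsA), shared = 0L, uniqueB = length(idsB)))
    mm <- matchMatrix(idsA, idsB, fun)
    if (!any(mm))
      return(c(uniqueA = length(idsA), shared = 0L, uniqueB = length(idsB)))
    g <- igraph::graph_from_biadjacency_matrix(mm)
    mt <- igraph::max_bipartite_match(g)
    shared <- mt$matching_size
    c(uniqueA = length(idsA) - shared, shared = shared,
      uniqueB = length(idsB) - shared)
  }
  out <- rbind(
    reactions = countsFor(names(reactions(modelA)), names(reactions(modelB)),
      function(a, b) matchReaction(a, b, modelA, modelB)),
    metabolites = countsFor(names(metabolites(modelA)), names(metabolites(modelB)),
      function(a, b) matchMetabolite(metabolites(modelA)[[a]], metabolites(modelB)[[b]])),
    genes = countsFor(names(genes(modelA)), names(genes(modelB)),
      function(a, b) matchGene(genes(modelA)[[a]], genes(modelB)[[b]])))
  storage.mode(out) <- "integer"
  out
}

## ---- search ---------------------------------------------------------------

## Naive full scan over the documented per-kind field lists.
searchScanOracle <- function(store, term, selectedModels = NULL) {
  fields <- list(
    reactions = c("abbreviation", "name", "ecNumber", "enzyme", "orf", "keggId"),
    metabolites = c("abbreviation", "name", "formula", "chebiId", "keggId"),
    genes = c("abbreviation", "name", "ecNumber", "keggId", "uniprotId"))
  needle <- tolower(term)
  hits <- list(reactions = character(0), metabolites = character(0),
               genes = character(0), organisms = character(0))
  ids <- storeModels(store)
  snaps <- list()
  for (mid in ids) {
    m <- tryCatch(modelAtRevision(store, mid), error = function(e) NULL)
    if (!is.null(m)) snaps[[mid]] <- m
  }
  if (is.null(selectedModels)) selectedModels <- names(snaps)
  for (mid in names(snaps)) {
    m <- snaps[[mid]]
    slotOf <- list(reactions = reactions(m), metabolites = metabolites(m),
                   genes = genes(m))
    for (kind in names(fields)) {
      if (kind == "reactions" && !(mid %in% selectedModels)) next
      for (id in names(slotOf[[kind]])) {
        rec <- slotOf[[kind]][[id]]
        for (f in fields[[kind]]) {
          v <- rec[[f]]
          if (!is.null(v) && nzchar(v) && grepl(needle, tolower(v), fixed = TRUE)) {
            hits[[kind]] <- c(hits[[kind]], paste(mid, id, f, sep = "/"))
          }
        }
      }
    }
    if (nzchar(organism(m)) && grepl(needle, tolower(organism(m)), fixed = TRUE))
      hits$organisms <- c(hits$organisms, mid)
  }
  lapply(hits, sort)
}

searchResultKeys <- function(res) {
  list(
    reactions = sort(paste(res$reactions$model, res$reactions$entity,
                           res$reactions$field, sep = "/")),
    metabolites = sort(paste(res$metabolites$model, res$metabolites$entity,
                             res$metabolites$field, sep = "/")),
    genes = sort(paste(res$genes$model, res$genes$entity, res$genes$field, sep = "/")),
    organisms = sort(res$organisms$model))
}

## ---- SBML validation ------------------------------------------------------

## Count libSBML consistency errors (severity >= error) over one or more
## files, via the python binding available in the environment.
libsbmlErrorCount <- function(paths) {
  code <- paste(
    "import sys, libsbml",
    "total = 0",
    "for p in sys.argv[1:]:",
    "    d = libsbml.readSBMLFromFile(p)",
    "    d.checkConsistency()",
    "    total += sum(1 for i in range(d.getNumErrors())",
    "                 if d.getError(i).getSeverity() >= libsbml.LIBSBML_SEV_ERROR)",
    "print(total)",
    sep = "\n")
  out <- suppressWarnings(system2("python", c("-c", shQuote(code), shQuote(paths)),
                                  stdout = TRUE, stderr = FALSE))
  as.integer(utils::tail(out, 1))
}

## ---- fixtures -------------------------------------------------------------

fixedClock <- function() {
  i <- 0
  function() {
    i <<- i + 1
    as.POSIXct("2026-01-01 00:00:00", tz = "UTC") + i
  }
}

## Tiny hand-built model: water formation, one transport, an exchange-ish
## single-sided reaction, a formula-less metabolite.
tinyModel <- function() {
  metabolicModel("tiny", name = "tiny demo", organism = "Escherichia coli",
    compartments = list(
      compartment("e", "extracellular"),
      compartment("c", "cytoplasm", parentId = "e"),
      compartment("p", "peroxisome", parentId = "c")),
    metabolites = list(
      metabolite("h2", "hydrogen", formula = "H2", charge = 0L),
      metabolite("o2", "oxygen", formula = "O2", charge = 0L,
                 chebiId = "15379", keggId = "C00007"),
      metabolite("h2o", "water", formula = "H2O", charge = 0L,
                 chebiId = "15377", keggId = "C00001"),
      metabolite("x", "mystery cofactor")),
    genes = list(
      gene("g1", "gene one", uniprotId = "P00001"),
      gene("g2", "gene two", ecNumber = "1.1.1.1")),
    reactions = list(
      reaction("rh2o", "water formation",
               rbind(reactants("h2", 2, "c", "substrate"),
                     reactants("o2", 1, "c", "substrate"),
                     reactants("h2o", 2, "c", "product")),
               ecNumber = "1.9.3.1", keggId = "R00275",
               subsystem = "energy", gpr = "g1 AND g2",
               enzyme = "oxidase", orf = "ORF001"),
      reaction("rtrans", "water transport",
               rbind(reactants("h2o", 1, "c", "substrate"),
                     reactants("h2o", 1, "e", "product")),
               reversible = TRUE, subsystem = "transport"),
      reaction("rex", "oxygen exchange",
               reactants("o2", 1, "e", "substrate"),
               subsystem = "exchange"),
      reaction("rmyst", "mystery reaction",
               rbind(reactants("x", 1, "p", "substrate"),
                     reactants("h2o", 1, "p", "product")),
               subsystem = "energy")),
    subsystems = c("energy", "transport", "exchange"))
}

## Store seeded with users and one published model.
seededStore <- function(model = tinyModel()) {
  st <- modelStore(clock = fixedClock())
  addUser(st, user("admin", "administrator"))
  addUser(st, user("ed", "editor", assignedModels = model@modelId))
  addUser(st, user("reg", "registered", assignedModels = model@modelId))
  addUser(st, user("guest", "unregistered"))
  publishModel(st, model, getUser(st, "ed"), getUser(st, "admin"))
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a
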