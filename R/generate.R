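## Synthetic model generation.
##
## The generator is first-class: it produces fully valid models with a known
## construction, which makes it the ground-truth side of the balance,
## comparison, search and round-trip properties. Balanced reactions are built
## from formula-conserving metabolite families: composition triples
## (A + B -> AB, where AB's formula is the elementwise sum), isomer pairs
## (same formula, distinct species), and transports (the same species moved
## between compartments). Every construction conserves every element exactly,
## so in balanced mode every generated reaction is elementally balanced by
## construction, not by numerical accident.

.organellePool <- data.frame(
  id = c("per", "nuc", "mit", "gol", "vac", "er", "lys", "gly", "chl", "thy"),
  name = c("peroxisome", "nucleus", "mitochondrion", "golgi", "vacuole",
           "endoplasmic_reticulum", "lysosome", "glyoxysome", "chloroplast",
           "thylakoid"),
  stringsAsFactors = FALSE)

.subsystemPool <- c("glycolysis", "tca_cycle", "pentose_phosphate",
                    "amino_acid_metabolism", "lipid_metabolism",
                    "nucleotide_metabolism")

#' Fixture generator parameters
#'
#' @param nCompartments Number of compartments (>= 1); the first two are the
#'   extracellular space and the cytoplasm, further ones are organelles nested
#'   under the cytoplasm up to `hierarchyDepth`.
#' @param hierarchyDepth Maximum depth of the compartment tree (root = 1).
#' @param nMetabolites,nReactions,nGenes Entity counts (>= 0).
#' @param keggFraction,chebiFraction,uniprotFraction Fractions of entities
#'   carrying the respective annotation, in `[0, 1]`.
#' @param balanced Construct only element-conserving reactions?
#' @param seed Integer seed; the same parameters and seed reproduce the model
#'   bit for bit.
#' @return A `FixtureParams` list.
#' @export
fixtureParams <- function(nCompartments = 4, hierarchyDepth = 3,
                          nMetabolites = 40, nReactions = 60, nGenes = 30,
                          keggFraction = 0.7, chebiFraction = 0.6,
                          uniprotFraction = 0.6, balanced = TRUE, seed = 1) {
  p <- list(nCompartments = as.integer(nCompartments),
            hierarchyDepth = as.integer(hierarchyDepth),
            nMetabolites = as.integer(nMetabolites),
            nReactions = as.integer(nReactions), nGenes = as.integer(nGenes),
            keggFraction = keggFraction, chebiFraction = chebiFraction,
            uniprotFraction = uniprotFraction, balanced = isTRUE(balanced),
            seed = as.integer(seed))
  counts <- c(p$nCompartments, p$hierarchyDepth, p$nMetabolites, p$nReactions, p$nGenes)
  if (any(is.na(counts)) || any(counts < 0) || p$nCompartments < 1)
    gsmvArgError("entity counts must be non-negative (and at least one compartment)")
  fr <- c(p$keggFraction, p$chebiFraction, p$uniprotFraction)
  if (any(is.na(fr)) || any(fr < 0) || any(fr > 1))
    gsmvArgError("annotation fractions must lie in [0, 1]")
  if (p$nReactions > 0 && p$nMetabolites < 2)
    gsmvArgError("cannot generate reactions with fewer than two metabolites")
  structure(p, class = "FixtureParams")
}

randFormula <- function() {
  counts <- c(C = sample(1:8, 1), H = sample(1:14, 1), O = sample(0:6, 1),
              N = sample(0:3, 1), P = sample(0:2, 1), S = sample(0:1, 1))
  counts[counts > 0]
}

sumCounts <- function(a, b) {
  out <- a
  for (el in names(b)) out[el] <- (if (el %in% names(out)) out[[el]] else 0) + b[[el]]
  out
}

#' Generate a deterministic synthetic metabolic model
#'
#' See [fixtureParams()] for the tunable conditions. The output passes
#' [validateModel()] with no errors; in balanced mode every reaction reports
#' `balanced` under [balanceReport()].
#'
#' @param params A [fixtureParams()] list.
#' @param modelId Model id (default derived from the seed).
#' @return A [MetabolicModel-class].
#' @export
#' @examples
#' m <- generateModel(fixtureParams(nMetabolites = 10, nReactions = 8,
#'                                  nGenes = 5, seed = 42))
#' m
generateModel <- function(params = fixtureParams(), modelId = NULL) {
  if (!inherits(params, "FixtureParams")) gsmvArgError("params must come from fixtureParams()")
  if (is.null(modelId)) modelId <- sprintf("model_%d", params$seed)
  withSeed(params$seed, {
    ## compartments ----------------------------------------------------------
    comps <- list()
    depth <- integer(0)
    if (params$nCompartments == 1L) {
      comps[["c"]] <- compartment("c", "cytoplasm")
      depth[["c"]] <- 1L
    } else {
      comps[["e"]] <- compartment("e", "extracellular")
      depth[["e"]] <- 1L
      comps[["c"]] <- compartment("c", "cytoplasm", parentId = "e")
      depth[["c"]] <- 2L
      nOrg <- params$nCompartments - 2L
      for (k in seq_len(nOrg)) {
        id <- if (k <= nrow(.organellePool)) .organellePool$id[k] else sprintf("org%02d", k)
        nm <- if (k <= nrow(.organellePool)) .organellePool$name[k] else sprintf("organelle_%02d", k)
        candidates <- names(depth)[depth < params$hierarchyDepth & names(depth) != "e"]
        if (length(candidates) == 0L) candidates <- "c"
        parent <- if (length(candidates) == 1L) candidates else sample(candidates, 1)
        comps[[id]] <- compartment(id, nm, parentId = parent)
        depth[[id]] <- depth[[parent]] + 1L
      }
    }
    compIds <- names(comps)
    innerIds <- setdiff(compIds, "e")
    if (length(innerIds) == 0L) innerIds <- compIds

    ## metabolite families ---------------------------------------------------
    mets <- list()
    triples <- list()
    pairs <- list()
    i <- 0L
    newMet <- function(counts) {
      i <<- i + 1L
      ab <- sprintf("m%04d", i)
      mets[[ab]] <<- metabolite(ab, name = sprintf("metabolite_%04d", i),
        formula = formatFormula(counts), charge = 0L,
        chebiId = if (stats::runif(1) < params$chebiFraction) as.character(10000L + i) else NULL,
        keggId = if (stats::runif(1) < params$keggFraction) sprintf("C%05d", i) else NULL,
        annotations = if (stats::runif(1) < 0.15)
          miriamURN("pubchem.compound", as.character(90000L + i)) else character(0))
      ab
    }
    familyType <- TRUE  # alternate triple / pair
    while (i < params$nMetabolites) {
      left <- params$nMetabolites - i
      if (left >= 3L && familyType) {
        fa <- randFormula(); fb <- randFormula()
        triples[[length(triples) + 1L]] <-
          c(newMet(fa), newMet(fb), newMet(sumCounts(fa, fb)))
      } else if (left >= 2L) {
        f <- randFormula()
        pairs[[length(pairs) + 1L]] <- c(newMet(f), newMet(f))
      } else {
        newMet(randFormula())
      }
      familyType <- !familyType
    }
    metIds <- names(mets)

    ## genes -----------------------------------------------------------------
    gns <- list()
    for (k in seq_len(params$nGenes)) {
      ab <- sprintf("g%04d", k)
      gns[[ab]] <- gene(ab, name = sprintf("gene_%04d", k),
        ecNumber = if (stats::runif(1) < 0.3)
          sprintf("%d.%d.%d.%d", sample(1:6, 1), sample(1:9, 1), sample(1:9, 1), k) else NULL,
        keggId = if (stats::runif(1) < 0.4) sprintf("syn:g%04d", k) else NULL,
        uniprotId = if (stats::runif(1) < params$uniprotFraction)
          sprintf("P%05d", 10000L + k) else NULL)
    }
    geneIds <- names(gns)

    ## reactions -------------------------------------------------------------
    types <- c(if (length(triples)) c("combination", "decomposition"),
               if (length(pairs)) "isomerization",
               if (length(compIds) >= 2L) "transport")
    if (params$nReactions > 0L && params$balanced && length(types) == 0L)
      gsmvArgError("balanced reactions are infeasible for these parameters")
    rxns <- list()
    for (k in seq_len(params$nReactions)) {
      ab <- sprintf("r%04d", k)
      s <- sample(c(0.5, 1, 1, 2, 3), 1)
      if (params$balanced) {
        type <- if (length(types) == 1L) types else sample(types, 1)
        if (type %in% c("combination", "decomposition")) {
          tr <- triples[[sample(length(triples), 1)]]
          cc <- if (length(innerIds) == 1L) innerIds else sample(innerIds, 1)
          df <- if (type == "combination")
            rbind(reactants(tr[1], s, cc, "substrate"),
                  reactants(tr[2], s, cc, "substrate"),
                  reactants(tr[3], s, cc, "product"))
          else
            rbind(reactants(tr[3], s, cc, "substrate"),
                  reactants(tr[1], s, cc, "product"),
                  reactants(tr[2], s, cc, "product"))
        } else if (type == "isomerization") {
          pr <- pairs[[sample(length(pairs), 1)]]
          cc <- if (length(innerIds) == 1L) innerIds else sample(innerIds, 1)
          df <- rbind(reactants(pr[1], s, cc, "substrate"),
                      reactants(pr[2], s, cc, "product"))
        } else {
          met <- if (length(metIds) == 1L) metIds else sample(metIds, 1)
          cs <- sample(compIds, 2)
          df <- rbind(reactants(met, s, cs[1], "substrate"),
                      reactants(met, s, cs[2], "product"))
        }
      } else {
        type <- "random"
        nS <- sample(1:2, 1); nP <- sample(1:2, 1)
        who <- sample(metIds, nS + nP)
        cc <- if (length(innerIds) == 1L) innerIds else sample(innerIds, 1)
        df <- rbind(
          reactants(who[seq_len(nS)], sample(1:3, nS, replace = TRUE), cc, "substrate"),
          reactants(who[nS + seq_len(nP)], sample(1:3, nP, replace = TRUE), cc, "product"))
      }
      gpr <- NULL
      if (length(geneIds) && stats::runif(1) < 0.8) {
        gs <- sample(geneIds, min(length(geneIds), sample(1:3, 1)))
        gpr <- switch(as.character(length(gs)),
          "1" = gprLeaf(gs[1]),
          "2" = if (stats::runif(1) < 0.5) gprOr(gs[1], gs[2]) else gprAnd(gs[1], gs[2]),
          gprAnd(gs[1], gprOr(gs[2], gs[3])))
      }
      sub <- if (type == "transport") "transport" else sample(.subsystemPool, 1)
      firstGene <- if (!is.null(gpr)) gprGenes(gpr)[1] else NULL
      rxns[[ab]] <- reaction(ab, name = sprintf("%s_%04d", type, k),
        reactants = df, reversible = stats::runif(1) < 0.3,
        ecNumber = if (stats::runif(1) < 0.4)
          sprintf("%d.%d.%d.%d", sample(1:6, 1), sample(1:9, 1), sample(1:9, 1), k) else NULL,
        keggId = if (stats::runif(1) < params$keggFraction) sprintf("R%05d", k) else NULL,
        subsystem = sub, gpr = gpr,
        enzyme = if (!is.null(firstGene)) gns[[firstGene]]$name else NULL,
        orf = firstGene,
        citations = if (stats::runif(1) < 0.2) sprintf("PMID:10%05d", k) else character(0))
    }

    metabolicModel(modelId, name = sprintf("synthetic model %s", modelId),
      organism = sprintf("Synthetica sp. %d", params$seed),
      compartments = unname(comps), metabolites = unname(mets),
      reactions = unname(rxns), genes = unname(gns),
      subsystems = c(.subsystemPool, "transport"))
  })
}

#' Perturb one formula so a balanced reaction becomes unbalanced
#'
#' Picks a participant whose net stoichiometric coefficient in the reaction is
#' nonzero (pure transports have none and are rejected) and increments one
#' element of its formula by one, so the reaction's net acquires exactly that
#' element.
#'
#' @param model A [MetabolicModel-class].
#' @param rxnAbbr Reaction to perturb.
#' @param seed Integer seed controlling the choice of metabolite and element.
#' @return List with `model` (modified copy), `metabolite`, `element`.
#' @export
perturbBalance <- function(model, rxnAbbr, seed = 1) {
  r <- getReaction(model, rxnAbbr)
  df <- r$reactants
  if (nrow(df) == 0L) gsmvArgError("reaction '%s' has no reactants", rxnAbbr)
  coef <- stats::setNames(numeric(0), character(0))
  for (k in seq_len(nrow(df))) {
    ab <- df$metabolite[k]
    sgn <- if (df$side[k] == "product") 1 else -1
    coef[ab] <- (if (ab %in% names(coef)) coef[[ab]] else 0) + sgn * df$stoichiometry[k]
  }
  candidates <- names(coef)[abs(coef) > 1e-12 &
    vapply(names(coef), function(ab) !is.null(getMetabolite(model, ab)$formula), logical(1))]
  if (length(candidates) == 0L)
    gsmvArgError("reaction '%s' has no formula-carrying participant with nonzero net coefficient", rxnAbbr)
  withSeed(seed, {
    met <- if (length(candidates) == 1L) candidates else sample(candidates, 1)
    counts <- parseFormula(getMetabolite(model, met)$formula)
    el <- if (length(counts) == 1L) names(counts) else sample(names(counts), 1)
    counts[el] <- counts[el] + 1
    model@metabolites[[met]]$formula <- formatFormula(counts)
    list(model = model, metabolite = met, element = el)
  })
}

#' Generate a pair of models with known comparison ground truth
#'
#' Builds two models sharing a configurable number of reactions, metabolites
#' and genes, with the shared entities matchable under a configured mix of
#' identifier rules (KEGG-identified vs equation-identified reactions;
#' ChEBI/KEGG/name metabolites; UniProt/name genes), and the unique entities
#' guaranteed unmatchable (distinct accessions, distinct names, equations
#' built over model-private metabolites). The intended pairs are returned as
#' ground truth, so the comparator's Venn counts can be checked exactly.
#'
#' @param overlap Per-category `c(shared, uniqueA, uniqueB)` counts, as a list
#'   with elements `reactions`, `metabolites`, `genes`.
#' @param seed Integer seed.
#' @param keggMatchFraction Fraction of shared reactions matched via KEGG ID
#'   (the rest carry no KEGG ID and match via identical equations).
#' @return List with `modelA`, `modelB`, `truth` (per category a data.frame
#'   `a`, `b`, `rule`), and `overlap` as supplied.
#' @export
#' @examples
#' pair <- generateModelPair(seed = 7)
#' vennCounts(compareModels(pair$modelA, pair$modelB))
generateModelPair <- function(overlap = list(reactions = c(10, 5, 7),
                                             metabolites = c(12, 5, 5),
                                             genes = c(8, 3, 3)),
                              seed = 1, keggMatchFraction = 0.5) {
  for (cat in c("reactions", "metabolites", "genes")) {
    v <- overlap[[cat]]
    if (is.null(v) || length(v) != 3L || any(is.na(v)) || any(v < 0))
      gsmvArgError("overlap$%s must be c(shared, uniqueA, uniqueB), all >= 0", cat)
  }
  nsr <- overlap$reactions[1]; nuA <- overlap$reactions[2]; nuB <- overlap$reactions[3]
  nsm <- overlap$metabolites[1]; muA <- overlap$metabolites[2]; muB <- overlap$metabolites[3]
  nsg <- overlap$genes[1]; guA <- overlap$genes[2]; guB <- overlap$genes[3]
  if (nsr > 0 && nsm < 2)
    gsmvArgError("shared reactions require at least two shared metabolites")
  if ((nuA > 0 && muA < 1) || (nuB > 0 && muB < 1))
    gsmvArgError("unique reactions require at least one unique metabolite on their side")

  withSeed(seed, {
    comps <- list(compartment("e", "extracellular"),
                  compartment("c", "cytoplasm", parentId = "e"),
                  compartment("p", "peroxisome", parentId = "c"))

    metsA <- list(); metsB <- list()
    truthMet <- list()
    for (k in seq_len(nsm)) {
      ab <- sprintf("ms%03d", k)
      rule <- c("chebi", "kegg", "name")[(k - 1L) %% 3L + 1L]
      f <- formatFormula(randFormula())
      base <- sprintf("shared_met_%03d", k)
      mk <- function(nameCase) switch(rule,
        chebi = metabolite(ab, name = base, formula = f,
                           chebiId = as.character(30000L + k),
                           keggId = sprintf("C3%04d", k)),
        kegg = metabolite(ab, name = base, formula = f, keggId = sprintf("C3%04d", k)),
        name = metabolite(ab, name = nameCase, formula = f))
      metsA[[ab]] <- mk(toupper(base))
      metsB[[ab]] <- mk(base)
      truthMet[[k]] <- data.frame(a = ab, b = ab, rule = rule, stringsAsFactors = FALSE)
    }
    uniqueMet <- function(side, k) {
      ab <- sprintf("u%s_m%03d", side, k)
      off <- if (side == "a") 40000L else 50000L
      metabolite(ab, name = sprintf("unique_%s_met_%03d", side, k),
                 formula = formatFormula(randFormula()),
                 chebiId = as.character(off + k), keggId = sprintf("C%d%04d", if (side == "a") 4L else 5L, k))
    }
    for (k in seq_len(muA)) metsA[[sprintf("ua_m%03d", k)]] <- uniqueMet("a", k)
    for (k in seq_len(muB)) metsB[[sprintf("ub_m%03d", k)]] <- uniqueMet("b", k)

    gnsA <- list(); gnsB <- list()
    truthGene <- list()
    for (k in seq_len(nsg)) {
      ab <- sprintf("gs%03d", k)
      rule <- if (k %% 2L == 1L) "uniprot" else "name"
      if (rule == "uniprot") {
        gnsA[[ab]] <- gene(ab, name = sprintf("shared_gene_a_%03d", k),
                           uniprotId = sprintf("P4%04d", k))
        gnsB[[ab]] <- gene(ab, name = sprintf("shared_gene_b_%03d", k),
                           uniprotId = sprintf("P4%04d", k))
      } else {
        gnsA[[ab]] <- gene(ab, name = toupper(sprintf("shared_gene_%03d", k)))
        gnsB[[ab]] <- gene(ab, name = sprintf("shared_gene_%03d", k))
      }
      truthGene[[k]] <- data.frame(a = ab, b = ab, rule = rule, stringsAsFactors = FALSE)
    }
    for (k in seq_len(guA))
      gnsA[[sprintf("ua_g%03d", k)]] <- gene(sprintf("ua_g%03d", k),
        name = sprintf("unique_a_gene_%03d", k), uniprotId = sprintf("P6%04d", k))
    for (k in seq_len(guB))
      gnsB[[sprintf("ub_g%03d", k)]] <- gene(sprintf("ub_g%03d", k),
        name = sprintf("unique_b_gene_%03d", k), uniprotId = sprintf("P7%04d", k))

    sharedSubs <- c("glycolysis", "tca_cycle")
    rxnsA <- list(); rxnsB <- list()
    truthRxn <- list()
    nKegg <- floor(keggMatchFraction * nsr)
    for (k in seq_len(nsr)) {
      ab <- sprintf("rs%03d", k)
      i1 <- (2L * k - 2L) %% nsm + 1L
      i2 <- (2L * k - 1L) %% nsm + 1L
      if (i2 == i1) i2 <- i1 %% nsm + 1L
      cc <- c("c", "c", "p")[(k - 1L) %% 3L + 1L]
      sub <- sharedSubs[(k - 1L) %% 2L + 1L]
      gpr <- if (nsg > 0) gprLeaf(sprintf("gs%03d", (k - 1L) %% nsg + 1L)) else NULL
      if (k <= nKegg) {
        ## KEGG-matched: same accession, deliberately different equations
        mkR <- function(prodStoich) reaction(ab, name = sprintf("shared_rxn_%03d", k),
          reactants = rbind(
            reactants(sprintf("ms%03d", i1), k, cc, "substrate"),
            reactants(sprintf("ms%03d", i2), prodStoich, cc, "product")),
          keggId = sprintf("R3%04d", k), subsystem = sub, gpr = gpr)
        rxnsA[[ab]] <- mkR(k + 0.5)
        rxnsB[[ab]] <- mkR(k + 0.25)
        rule <- "kegg"
      } else {
        ## equation-matched: no KEGG ID, identical equations
        mkR <- function() reaction(ab, name = sprintf("shared_rxn_%03d", k),
          reactants = rbind(
            reactants(sprintf("ms%03d", i1), k, cc, "substrate"),
            reactants(sprintf("ms%03d", i2), k, cc, "product")),
          subsystem = sub, gpr = gpr)
        rxnsA[[ab]] <- mkR()
        rxnsB[[ab]] <- mkR()
        rule <- "equation"
      }
      truthRxn[[k]] <- data.frame(a = ab, b = ab, rule = rule, stringsAsFactors = FALSE)
    }
    uniqueRxn <- function(side, k, mets, nUniqueMets) {
      ## built over model-private metabolites only, so a restricted comparison
      ## can never promote a shared metabolite to unique on one side
      ab <- sprintf("u%s_r%03d", side, k)
      um <- sprintf("u%s_m%03d", side, (k - 1L) %% nUniqueMets + 1L)
      partner <- if (nUniqueMets > 1L)
        sprintf("u%s_m%03d", side, k %% nUniqueMets + 1L) else um
      df <- if (partner == um)
        rbind(reactants(um, 1, "c", "substrate"), reactants(um, 2, "c", "product"))
      else
        rbind(reactants(um, 1, "c", "substrate"), reactants(partner, k + 1, "c", "product"))
      reaction(ab, name = sprintf("unique_%s_rxn_%03d", side, k), reactants = df,
               keggId = if (k %% 2L == 0L) sprintf("R%s%04d", if (side == "a") "4" else "5", k) else NULL,
               subsystem = "transport",
               gpr = if (side == "a" && guA > 0) gprLeaf(sprintf("ua_g%03d", (k - 1L) %% guA + 1L))
                     else if (side == "b" && guB > 0) gprLeaf(sprintf("ub_g%03d", (k - 1L) %% guB + 1L))
                     else NULL)
    }
    for (k in seq_len(nuA)) rxnsA[[sprintf("ua_r%03d", k)]] <- uniqueRxn("a", k, metsA, muA)
    for (k in seq_len(nuB)) rxnsB[[sprintf("ub_r%03d", k)]] <- uniqueRxn("b", k, metsB, muB)

    bindTruth <- function(lst, cols) {
      if (length(lst)) do.call(rbind, lst)
      else data.frame(a = character(0), b = character(0), rule = character(0),
                      stringsAsFactors = FALSE)
    }
    modelA <- metabolicModel("model_A", name = "synthetic pair model A",
      organism = "Synthetica alpha", compartments = comps,
      metabolites = unname(metsA), reactions = unname(rxnsA), genes = unname(gnsA),
      subsystems = c(sharedSubs, "transport"))
    modelB <- metabolicModel("model_B", name = "synthetic pair model B",
      organism = "Synthetica beta", compartments = comps,
      metabolites = unname(metsB), reactions = unname(rxnsB), genes = unname(gnsB),
      subsystems = c(sharedSubs, "transport"))
    list(modelA = modelA, modelB = modelB,
         truth = list(reactions = bindTruth(truthRxn),
                      metabolites = bindTruth(truthMet),
                      genes = bindTruth(truthGene)),
         overlap = overlap)
  })
}
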