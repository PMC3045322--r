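test_that("canonical equations are permutation-invariant and direction-aware", {
  mk <- function(df, reversible = FALSE)
    metabolicModel("eq", compartments = list(compartment("c", "cytoplasm")),
      metabolites = list(metabolite("a", name = "A"), metabolite("b", name = "B"),
                         metabolite("d", name = "D")),
      reactions = list(reaction("r", reactants = df, reversible = reversible)))

  fwd <- rbind(reactants(c("a", "b"), 1, "c", "substrate"),
               reactants("d", 1, "c", "product"))
  prm <- rbind(reactants(c("b", "a"), 1, "c", "substrate"),
               reactants("d", 1, "c", "product"))
  expect_equal(canonicalEquation("r", mk(fwd))$signature,
               canonicalEquation("r", mk(prm))$signature)

  ab <- rbind(reactants("a", 1, "c", "substrate"), reactants("b", 1, "c", "product"))
  ba <- rbind(reactants("b", 1, "c", "substrate"), reactants("a", 1, "c", "product"))
  ## reversible reactions compare equal under side swap ...
  expect_equal(canonicalEquation("r", mk(ab, TRUE))$signature,
               canonicalEquation("r", mk(ba, TRUE))$signature)
  ## ... irreversible ones preserve direction
  expect_false(canonicalEquation("r", mk(ab))$signature ==
                 canonicalEquation("r", mk(ba))$signature)
  ## no stoichiometric rescaling
  ab2 <- rbind(reactants("a", 2, "c", "substrate"), reactants("b", 2, "c", "product"))
  expect_false(canonicalEquation("r", mk(ab))$signature ==
                 canonicalEquation("r", mk(ab2))$signature)
})

test_that("pairwise matching follows the identifier precedence rules", {
  m <- tinyModel()
  r1 <- reactions(m)$rh2o
  r2 <- r1; r2$abbreviation <- "other"

  expect_equal(matchReaction(r1, r2, m, m)$rule, "kegg")
  r2$keggId <- "R99999"
  mr <- matchReaction(r1, r2, m, m)         # conflicting KEGG: no fallback
  expect_false(mr$matched); expect_equal(mr$rule, "none")
  r2$keggId <- NULL
  expect_equal(matchReaction(r1, r2, m, m)$rule, "equation")

  ## metabolites: ChEBI > KEGG > case-insensitive name
  m1 <- metabolite("a", name = "Glucose", chebiId = "17234", keggId = "C00031")
  m2 <- metabolite("b", name = "glucose", chebiId = "17234", keggId = "C99999")
  expect_equal(matchMetabolite(m1, m2)$rule, "chebi")
  m2$chebiId <- NULL
  mm <- matchMetabolite(m1, m2)             # KEGG conflict decides
  expect_false(mm$matched)
  m2$keggId <- "C00031"
  expect_equal(matchMetabolite(m1, m2)$rule, "kegg")
  m1$keggId <- NULL
  expect_equal(matchMetabolite(m1, m2)$rule, "name")
  m2$name <- "fructose"
  expect_false(matchMetabolite(m1, m2)$matched)

  ## genes: UniProt > case-insensitive name
  g1 <- gene("g1", name = "HXK1", uniprotId = "P12345")
  g2 <- gene("g2", name = "hxk1", uniprotId = "P12345")
  expect_equal(matchGene(g1, g2)$rule, "uniprot")
  g2$uniprotId <- NULL
  expect_equal(matchGene(g1, g2)$rule, "name")
  g2$name <- "zzz"
  expect_false(matchGene(g1, g2)$matched)
})

test_that("comparison recovers generator ground truth and matches the brute-force oracle", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (i in 1:15) {
    overlap <- list(reactions = c(sample(0:10, 1), sample(0:6, 1), sample(0:6, 1)),
                    metabolites = c(max(2, sample(2:12, 1)), sample(1:5, 1), sample(1:5, 1)),
                    genes = c(sample(0:8, 1), sample(0:4, 1), sample(0:4, 1)))
    pair <- generateModelPair(overlap, seed = 1000 + i,
                              keggMatchFraction = sample(c(0, 0.5, 1), 1))
    cmp <- compareModels(pair$modelA, pair$modelB)
    vc <- vennCounts(cmp)
    for (cat in c("reactions", "metabolites", "genes")) {
      expect_equal(unname(vc[cat, ]),
                   c(pair$overlap[[cat]][2], pair$overlap[[cat]][1],
                     pair$overlap[[cat]][3]),
                   info = sprintf("case %d, %s", i, cat))
      ## intended pairs and rules are recovered exactly
      got <- cmp@categories[[cat]]$shared
      want <- pair$truth[[cat]][order(pair$truth[[cat]]$a), , drop = FALSE]
      rownames(want) <- NULL
      expect_equal(got, want, info = sprintf("case %d, %s pairs", i, cat))
    }
    expect_equal(unclass(vc), unclass(bruteForceVenn(pair$modelA, pair$modelB)),
                 info = sprintf("case %d oracle", i))
  }
})

test_that("self-comparison yields no unique entities and operand swap mirrors the result", {
  m <- generateModel(fixtureParams(seed = 21, nMetabolites = 20, nReactions = 25,
                                   nGenes = 10))
  self <- vennCounts(compareModels(m, m))
  expect_true(all(self[, "uniqueA"] == 0))
  expect_true(all(self[, "uniqueB"] == 0))

  pair <- generateModelPair(seed = 22)
  ab <- vennCounts(compareModels(pair$modelA, pair$modelB))
  ba <- vennCounts(compareModels(pair$modelB, pair$modelA))
  expect_equal(ab[, "shared"], ba[, "shared"])
  expect_equal(ab[, "uniqueA"], ba[, "uniqueB"])
  expect_equal(ab[, "uniqueB"], ba[, "uniqueA"])
})

test_that("restrictions filter first and never increase counts", {
  pair <- generateModelPair(seed = 23)
  full <- vennCounts(compareModels(pair$modelA, pair$modelB))
  for (sub in c("glycolysis", "tca_cycle", "transport")) {
    vc <- vennCounts(compareModels(pair$modelA, pair$modelB,
                                   restrictSubsystems = sub))
    expect_true(all(vc <= full))
  }
  vc <- vennCounts(compareModels(pair$modelA, pair$modelB,
                                 restrictCompartments = "p"))
  expect_true(all(vc <= full))
  ## restricting reactions restricts metabolites/genes to participants
  cmpGly <- compareModels(pair$modelA, pair$modelB, restrictSubsystems = "glycolysis")
  partMets <- unique(unlist(lapply(cmpGly@categories$reactions$shared$a, function(id)
    reactions(pair$modelA)[[id]]$reactants$metabolite)))
  expect_true(all(c(cmpGly@categories$metabolites$shared$a,
                    cmpGly@categories$metabolites$uniqueA) %in%
                    union(partMets, names(metabolites(pair$modelA)))))

  ## invariant: uniqueA + shared equals the restricted universe size
  selSizes <- vennCounts(cmpGly)
  expect_equal(selSizes["reactions", "uniqueA"] + selSizes["reactions", "shared"],
               sum(vapply(reactions(pair$modelA), function(r)
                 identical(r$subsystem, "glycolysis"), logical(1))))
})

test_that("comparison exports to a tabular report", {
  pair <- generateModelPair(seed = 24)
  cmp <- compareModels(pair$modelA, pair$modelB)
  tab <- comparisonTable(cmp)
  vc <- vennCounts(cmp)
  expect_equal(nrow(tab), sum(vc))
  expect_setequal(unique(tab$category), c("reactions", "metabolites", "genes"))
  shared <- tab[tab$status == "shared", ]
  expect_true(all(shared$rule %in% c("kegg", "equation", "chebi", "name", "uniprot")))
  expect_true(all(!is.na(shared$partner)))
})

test_that("two revisions of one model can be compared through the store", {
  st <- seededStore()
  ed <- getUser(st, "ed"); admin <- getUser(st, "admin")
  ch <- proposeChange(st, ed, "tiny", "metabolite", "create",
                      value = metabolite("glc", "glucose", formula = "C6H12O6",
                                         keggId = "C00031"))
  approveChanges(st, ch$changeId, admin)
  cmp <- compareRevisions(st, "tiny", 1, "tiny", 2)
  vc <- vennCounts(cmp)
  expect_equal(unname(vc["metabolites", ]), c(0L, 4L, 1L))
  expect_equal(unname(vc["reactions", "uniqueA"]), 0L)
})
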