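test_that("a minimal document imports with the right counts", {
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="mini" name="Minimal">',
    '<listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="a_c" name="A" compartment="c"/>',
    '<species id="b_c" name="B" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions><reaction id="r1" reversible="false">',
    '<listOfReactants><speciesReference species="a_c" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="b_c" stoichiometry="1"/></listOfProducts>',
    '</reaction></listOfReactions>',
    '</model></sbml>')
  res <- importSBML(xml)
  expect_equal(unname(res$report$counts[c("compartments", "metabolites", "reactions")]),
               c(1L, 2L, 1L))
  expect_equal(modelId(res$model), "mini")
  ## compartment-suffixed ids fold back to base abbreviations
  expect_setequal(names(metabolites(res$model)), c("a", "b"))
  ## default stoichiometry/reversible attributes are honoured
  expect_false(reactions(res$model)$r1$reversible)
  expect_equal(reactions(res$model)$r1$reactants$stoichiometry, c(1, 1))
})

test_that("malformed or semantically broken documents fail cleanly", {
  expect_error(importSBML("<sbml><model>"), class = "gsmv_parse_error")
  expect_error(importSBML("<notSBML/>"), class = "gsmv_parse_error")
  bad <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies><species id="a" compartment="c"/></listOfSpecies>',
    '<listOfReactions><reaction id="r">',
    '<listOfReactants><speciesReference species="ghost"/></listOfReactants>',
    '</reaction></listOfReactions></model></sbml>')
  expect_error(importSBML(bad), "ghost", class = "gsmv_parse_error")
})

test_that("export emits explicit stoichiometry on every species reference", {
  m <- generateModel(fixtureParams(seed = 31, nMetabolites = 15, nReactions = 15,
                                   nGenes = 6))
  xml <- exportSBML(m)$xml
  doc <- xml2::read_xml(xml)
  refs <- xml2::xml_find_all(doc, ".//*[local-name()='speciesReference']")
  expect_gt(length(refs), 0)
  expect_false(any(is.na(xml2::xml_attr(refs, "stoichiometry"))))
  ## including coefficient 1
  expect_true("1" %in% xml2::xml_attr(refs, "stoichiometry"))
})

test_that("round trip preserves the model and is byte-stable after one cycle", {
  for (seed in c(32, 33)) {
    m <- generateModel(fixtureParams(seed = seed, nMetabolites = 18,
                                     nReactions = 20, nGenes = 8))
    for (profile in c("full", "cobra")) {
      ex1 <- exportSBML(m, options = exportOptions(profile = profile))
      back <- importSBML(ex1$xml)
      ex2 <- exportSBML(back$model, options = exportOptions(profile = profile))
      expect_identical(ex1$xml, ex2$xml, label = sprintf("seed %d %s", seed, profile))
      vc <- vennCounts(compareModels(m, back$model))
      expect_true(all(vc[, c("uniqueA", "uniqueB")] == 0),
                  info = sprintf("seed %d %s", seed, profile))
      ## GPRs, formulas and annotations survive
      expect_equal(lapply(reactions(back$model), function(r) r$gpr),
                   lapply(reactions(m), function(r) r$gpr))
      expect_equal(vapply(metabolites(back$model), function(x) x$formula %||% "", ""),
                   vapply(metabolites(m), function(x)
                     if (is.null(x$formula)) "" else
                       formatFormula(parseFormula(x$formula)), ""))
    }
  }
})

test_that("emitted documents pass libSBML validation with zero errors", {
  dir <- withr::local_tempdir()
  paths <- character(0)
  for (seed in 34:36) {
    m <- generateModel(fixtureParams(seed = seed, nMetabolites = 12,
                                     nReactions = 12, nGenes = 5))
    p1 <- file.path(dir, sprintf("m%d_full.xml", seed))
    p2 <- file.path(dir, sprintf("m%d_cobra.xml", seed))
    exportSBML(m, file = p1)
    exportSBML(m, file = p2, options = exportOptions(profile = "cobra"))
    paths <- c(paths, p1, p2)
  }
  expect_identical(libsbmlErrorCount(paths), 0L)
})

test_that("subsystem and reaction filters restrict the emitted document", {
  m <- tinyModel()
  ex <- exportSBML(m, options = exportOptions(subsystems = "energy"))
  expect_equal(unname(ex$report$counts["reactions"]), 2L)
  doc <- xml2::read_xml(ex$xml)
  rids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//*[local-name()='reaction']"), "id")
  expect_setequal(rids, c("rh2o", "rmyst"))
  ## species restricted to participants
  sids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//*[local-name()='species']"), "id")
  expect_false(any(grepl("^o2_e", sids)))

  ex2 <- exportSBML(m, options = exportOptions(subsystems = "energy",
                                               reactionFilter = "rh2o"))
  expect_equal(unname(ex2$report$counts["reactions"]), 1L)

  expect_error(exportSBML(m, options = exportOptions(subsystems = "nope")),
               class = "gsmv_argument_error")
  expect_error(exportSBML(m, options = exportOptions(reactionFilter = "nope")),
               class = "gsmv_argument_error")

  ## invalid snapshots are refused
  broken <- m
  broken@reactions$rh2o$reactants$metabolite[1] <- "ghost"
  expect_error(exportSBML(broken), class = "gsmv_state_error")
})

test_that("cobra profile carries GPR notes and reversibility-derived bounds", {
  m <- tinyModel()
  xml <- exportSBML(m, options = exportOptions(profile = "cobra"))$xml
  expect_match(xml, "GENE_ASSOCIATION: g1 and g2", fixed = TRUE)
  expect_match(xml, "SUBSYSTEM: energy", fixed = TRUE)
  doc <- xml2::read_xml(xml)
  for (rxn in xml2::xml_find_all(doc, ".//*[local-name()='reaction']")) {
    rev <- xml2::xml_attr(rxn, "reversible")
    lb <- xml2::xml_attr(xml2::xml_find_first(rxn,
      ".//*[local-name()='parameter'][@id='LOWER_BOUND']"), "value")
    expect_equal(lb, if (rev == "true") "-1000" else "0")
  }
  ## nested GPR serialization in notes
  m2 <- metabolicModel("gprdoc",
    compartments = list(compartment("c")),
    metabolites = list(metabolite("a", formula = "C"), metabolite("b", formula = "C")),
    genes = list(gene("gene1"), gene("gene2"), gene("gene3")),
    reactions = list(reaction("r", reactants = rbind(
      reactants("a", 1, "c", "substrate"), reactants("b", 1, "c", "product")),
      gpr = "gene1 AND [gene2 OR gene3]")))
  xmlNested <- exportSBML(m2, options = exportOptions(profile = "cobra"))$xml
  expect_match(xmlNested, "GENE_ASSOCIATION: gene1 and (gene2 or gene3)", fixed = TRUE)
})

test_that("tabular export has one row per entity and parseable equations", {
  m <- tinyModel()
  rtab <- exportTable(names(reactions(m)), "reactions", model = m)
  expect_equal(nrow(rtab), length(reactions(m)))
  expect_equal(names(rtab), c("abbreviation", "name", "equation", "ec_number",
                              "kegg_id", "subsystem"))
  for (k in seq_len(nrow(rtab))) {
    parsed <- parseEquation(rtab$equation[k])
    expect_equal(parsed$reactants, reactions(m)[[rtab$abbreviation[k]]]$reactants)
  }
  mtab <- exportTable(names(metabolites(m)), "metabolites", model = m)
  expect_equal(nrow(mtab), length(metabolites(m)))
  expect_equal(mtab$formula[mtab$abbreviation == "h2o"], "H2O")
  ## empty list gives a header-only table; mixed kinds are refused
  expect_equal(nrow(exportTable(list(), "reactions")), 0)
  expect_error(exportTable(list(reactions(m)$rh2o, metabolites(m)$h2o), "reactions"),
               class = "gsmv_argument_error")
  ## file output round trips
  path <- withr::local_tempfile(fileext = ".tsv")
  exportTable(names(metabolites(m)), "metabolites", model = m, file = path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), length(metabolites(m)))
})
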