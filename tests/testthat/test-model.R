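test_that("compartment containment is reflexive, transitive and forest-aware", {
  m <- tinyModel()
  expect_true(isWithin("p", "c", m))     # peroxisome within cytoplasm
  expect_true(isWithin("c", "c", m))     # ancestor-or-self
  expect_true(isWithin("p", "e", m))     # transitive through the chain
  expect_false(isWithin("e", "c", m))    # parent is not within its child
  expect_error(isWithin("nope", "c", m), class = "gsmv_lookup_error")

  ## disjoint trees never contain each other
  m2 <- metabolicModel("f", compartments = list(
    compartment("a"), compartment("b"), compartment("a1", parentId = "a")))
  expect_false(isWithin("a1", "b", m2))
  expect_false(isWithin("b", "a", m2))
})

test_that("validateModel reports referential violations and is empty on valid models", {
  expect_equal(nrow(validateModel(tinyModel())), 0)
  expect_equal(nrow(validateModel(metabolicModel("empty"))), 0)

  bad <- metabolicModel("bad",
    compartments = list(compartment("c", "cytoplasm")),
    metabolites = list(metabolite("a", formula = "C2")),
    reactions = list(
      reaction("r1", reactants = rbind(
        reactants("ghost", 1, "c", "substrate"),
        reactants("a", 1, "nowhere", "product")),
        subsystem = "undeclared")))
  ## drop the auto-registered subsystem to provoke the subsystem issue
  bad@subsystems <- character(0)
  issues <- validateModel(bad)
  expect_true(any(grepl("undeclared metabolite 'ghost'", issues$message)))
  expect_true(any(grepl("undeclared compartment 'nowhere'", issues$message)))
  expect_true(any(grepl("subsystem 'undeclared'", issues$message)))
  expect_true(all(issues$severity == "error"))

  ## compartment cycle
  cyc <- metabolicModel("cyc", compartments = list(compartment("a"), compartment("b")))
  cyc@compartments$a$parentId <- "b"
  cyc@compartments$b$parentId <- "a"
  expect_true(any(grepl("cycle", validateModel(cyc)$message)))

  ## GPR referencing an unknown gene is a warning, not an error
  draft <- metabolicModel("draft",
    compartments = list(compartment("c")),
    metabolites = list(metabolite("a", formula = "C"), metabolite("b", formula = "C")),
    reactions = list(reaction("r", reactants = rbind(
      reactants("a", 1, "c", "substrate"), reactants("b", 1, "c", "product")),
      gpr = "unannotated_gene")))
  issues <- validateModel(draft)
  expect_equal(issues$severity, "warning")
  expect_match(issues$message, "unannotated_gene")

  ## duplicate abbreviations are rejected at construction
  expect_error(metabolicModel("dup", reactions = list(
    reaction("r1"), reaction("r1"))), "duplicate")
})

test_that("MIRIAM references parse, serialize and resolve through the registry", {
  ref <- parseMiriam("urn:miriam:ec-code:1.1.1.1")
  expect_equal(ref$datatype, "ec-code")
  expect_equal(ref$identifier, "1.1.1.1")
  expect_equal(miriamToURL("urn:miriam:ec-code:1.1.1.1"),
               "https://identifiers.org/ec-code/1.1.1.1")
  expect_equal(miriamToURL("urn:miriam:kegg.reaction:R00299"),
               "https://identifiers.org/kegg.reaction/R00299")
  ## identifiers.org URIs accepted on input
  expect_equal(parseMiriam("https://identifiers.org/chebi/CHEBI:17234")$identifier,
               "CHEBI:17234")
  ## unresolvable datatype is a value, not an error
  expect_equal(miriamToURL(miriamURN("unknown-db", "x")), "unresolved:unknown-db:x")
  ## URN round trip through percent-encoding
  u <- miriamURN("chebi", "CHEBI:17234")
  expect_equal(parseMiriam(u)$identifier, "CHEBI:17234")
  ## registry is user-extensible
  reg <- c(loadMiriamRegistry(), mydb = "https://example.org/{id}")
  expect_equal(miriamToURL(miriamURN("mydb", "42"), reg), "https://example.org/42")
})

test_that("equation text formats and parses back", {
  m <- tinyModel()
  txt <- formatEquation("rh2o", m)
  expect_equal(txt, "2 h2[c] + o2[c] => 2 h2o[c]")
  back <- parseEquation(txt)
  expect_false(back$reversible)
  expect_equal(back$reactants, reactions(m)$rh2o$reactants)
  rev <- parseEquation(formatEquation("rtrans", m))
  expect_true(rev$reversible)
  expect_error(parseEquation("a[c] -> b[c]"), class = "gsmv_parse_error")
})
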