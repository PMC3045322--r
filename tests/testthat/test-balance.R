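test_that("balance report classifies the canonical cases", {
  m <- tinyModel()
  ## 2 H2 + O2 -> 2 H2O conserves every element
  rep <- balanceReport("rh2o", m)
  expect_equal(rep$status, "balanced")
  expect_length(rep$net, 0)

  ## CH4 -> CH3 is short one hydrogen on the product side
  m2 <- metabolicModel("b", compartments = list(compartment("c", "cytoplasm")),
    metabolites = list(metabolite("ch4", formula = "CH4"),
                       metabolite("ch3", formula = "CH3")),
    reactions = list(reaction("r", reactants = rbind(
      reactants("ch4", 1, "c", "substrate"),
      reactants("ch3", 1, "c", "product")))))
  rep2 <- balanceReport("r", m2)
  expect_equal(rep2$status, "unbalanced")
  expect_equal(rep2$net, c(H = -1))
  expect_equal(rep2$missingOnProductSide, "H")
  expect_length(rep2$overproducedOnProductSide, 0)

  ## a participant without a formula makes the check undetermined
  rep3 <- balanceReport("rmyst", m)
  expect_equal(rep3$status, "undetermined")
  expect_equal(rep3$undeterminedMetabolites, "x")

  ## single-sided exchange reactions are unbalanced, not an error
  rep4 <- balanceReport("rex", m)
  expect_equal(rep4$status, "unbalanced")
  expect_equal(rep4$net, c(O = -2))
})

test_that("charge is checked as a pseudo-element when all participants carry one", {
  m <- metabolicModel("q", compartments = list(compartment("c", "cytoplasm")),
    metabolites = list(
      metabolite("hplus", "proton", formula = "H", charge = 1L),
      metabolite("oh", "hydroxide", formula = "HO", charge = -1L),
      metabolite("h2o", "water", formula = "H2O", charge = 0L),
      metabolite("nocharge", "uncharged twin", formula = "H2O")),
    reactions = list(
      reaction("ok", reactants = rbind(
        reactants("hplus", 1, "c", "substrate"),
        reactants("oh", 1, "c", "substrate"),
        reactants("h2o", 1, "c", "product"))),
      reaction("chargeleak", reactants = rbind(
        reactants("hplus", 1, "c", "substrate"),
        reactants("h2o", 1, "c", "product"))),
      reaction("nochargeinfo", reactants = rbind(
        reactants("hplus", 1, "c", "substrate"),
        reactants("nocharge", 1, "c", "product")))))
  expect_equal(balanceReport("ok", m)$status, "balanced")
  leak <- balanceReport("chargeleak", m)
  expect_equal(leak$status, "unbalanced")
  expect_true("charge" %in% names(leak$net))
  expect_equal(unname(leak$net[["charge"]]), -1)
  ## element H also leaks: H1 -> H2O
  expect_true("H" %in% names(leak$net) || "O" %in% names(leak$net))
  ## charge silently skipped when some participant has no charge
  nci <- balanceReport("nochargeinfo", m)
  expect_false("charge" %in% names(nci$net))
})

test_that("generated balanced reactions all pass; perturbations all fail naming the element", {
  m <- generateModel(fixtureParams(seed = 11, nMetabolites = 30, nReactions = 60,
                                   nGenes = 10))
  statuses <- vapply(names(reactions(m)), function(id)
    balanceReport(id, m)$status, character(1))
  expect_true(all(statuses == "balanced"))

  eligible <- Filter(function(id) {
    df <- reactions(m)[[id]]$reactants
    coef <- tapply(ifelse(df$side == "product", 1, -1) * df$stoichiometry,
                   df$metabolite, sum)
    any(abs(coef) > 1e-12)
  }, names(reactions(m)))
  expect_gt(length(eligible), 0)
  for (k in seq_along(eligible)) {
    p <- perturbBalance(m, eligible[k], seed = k)
    rep <- balanceReport(eligible[k], p$model)
    expect_equal(rep$status, "unbalanced")
    expect_true(p$element %in% names(rep$net))
  }
})

test_that("net of a side-swapped reaction is the negation", {
  m <- generateModel(fixtureParams(seed = 12, nMetabolites = 20, nReactions = 20,
                                   nGenes = 5))
  for (id in names(reactions(m))) {
    r <- reactions(m)[[id]]
    p <- perturbBalance(m, id, seed = 1) |> try(silent = TRUE)
    target <- if (inherits(p, "try-error")) m else p$model
    rep1 <- balanceReport(id, target)
    swapped <- r
    swapped$reactants$side <- ifelse(r$reactants$side == "substrate",
                                     "product", "substrate")
    rep2 <- balanceReport(swapped, target)
    els <- union(names(rep1$net), names(rep2$net))
    for (el in els) {
      expect_equal(rep1$net[[el]] %||% 0, -(rep2$net[[el]] %||% 0))
    }
  }
})
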