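## Elemental (and charge) balance checking.

#' Net elemental change of a reaction
#'
#' For each element, the stoichiometry-weighted count over products minus the
#' count over substrates. When every participating metabolite carries a
#' charge, the net charge is included as the pseudo-element `"charge"`
#' (lower-case, so it can never collide with an element symbol).
#'
#' @param rxn A reaction record or reaction abbreviation.
#' @param model A [MetabolicModel-class] resolving the reactant references.
#' @return Named numeric vector of signed per-element nets (zero entries
#'   removed), or `NULL` when some participant lacks a formula.
#' @keywords internal
reactionNet <- function(rxn, model) {
  if (is.character(rxn)) rxn <- getReaction(model, rxn)
  df <- rxn$reactants
  net <- numeric(0)
  allCharged <- TRUE
  chargeNet <- 0
  if (nrow(df)) {
    for (k in seq_len(nrow(df))) {
      met <- getMetabolite(model, df$metabolite[k])
      sign <- if (df$side[k] == "product") 1 else -1
      if (is.null(met$formula)) return(NULL)
      counts <- parseFormula(met$formula)
      for (el in names(counts)) {
        net[el] <- (if (el %in% names(net)) net[[el]] else 0) +
          sign * df$stoichiometry[k] * counts[[el]]
      }
      if (is.null(met$charge)) allCharged <- FALSE
      else chargeNet <- chargeNet + sign * df$stoichiometry[k] * met$charge
    }
  }
  if (allCharged && nrow(df)) net["charge"] <- chargeNet
  net[net != 0]
}

#' Elemental balance report for a reaction
#'
#' Checks that consuming and producing sides carry the same elemental
#' composition, highlighting elements that are missing or overproduced on the
#' product side. Reactions touching a metabolite without a formula are
#' `undetermined`; single-sided exchange/boundary reactions come out
#' `unbalanced` by construction (that is their point, not an error). When all
#' participants carry a charge, charge conservation is checked alongside as
#' the pseudo-element `"charge"`.
#'
#' @param rxn A reaction record or reaction abbreviation.
#' @param model A [MetabolicModel-class].
#' @param tol Per-element tolerance on the net; the default accommodates
#'   fractional biomass stoichiometries.
#' @return A `BalanceReport`: list with `status` (`"balanced"`,
#'   `"unbalanced"`, `"undetermined"`), `net` (signed products-minus-substrates
#'   counts), `missingOnProductSide`, `overproducedOnProductSide`,
#'   `undeterminedMetabolites`.
#' @export
#' @examples
#' m <- metabolicModel("demo",
#'   compartments = list(compartment("c", "cytoplasm")),
#'   metabolites = list(metabolite("h2", formula = "H2"),
#'                      metabolite("o2", formula = "O2"),
#'                      metabolite("h2o", formula = "H2O")),
#'   reactions = list(reaction("r1", reactants = rbind(
#'     reactants("h2", 2, "c", "substrate"),
#'     reactants("o2", 1, "c", "substrate"),
#'     reactants("h2o", 2, "c", "product")))))
#' balanceReport("r1", m)$status
balanceReport <- function(rxn, model, tol = 1e-9) {
  if (is.character(rxn)) rxn <- getReaction(model, rxn)
  df <- rxn$reactants
  undet <- character(0)
  if (nrow(df)) {
    for (abbr in unique(df$metabolite)) {
      met <- getMetabolite(model, abbr)
      if (is.null(met$formula)) undet <- c(undet, abbr)
    }
  }
  if (length(undet)) {
    rep <- list(status = "undetermined", net = numeric(0),
                missingOnProductSide = character(0),
                overproducedOnProductSide = character(0),
                undeterminedMetabolites = sortIds(undet))
    class(rep) <- "BalanceReport"
    return(rep)
  }
  net <- reactionNet(rxn, model)
  net <- net[abs(net) > tol]
  rep <- list(
    status = if (length(net) == 0L) "balanced" else "unbalanced",
    net = net,
    missingOnProductSide = sortIds(names(net)[net < 0]),
    overproducedOnProductSide = sortIds(names(net)[net > 0]),
    undeterminedMetabolites = character(0)
  )
  class(rep) <- "BalanceReport"
  rep
}

#' @export
print.BalanceReport <- function(x, ...) {
  cat("Balance check:", x$status, "\n")
  if (length(x$net)) {
    cat("  net (products - substrates):",
        paste(sprintf("%s %+g", names(x$net), x$net), collapse = ", "), "\n")
    if (length(x$missingOnProductSide))
      cat("  missing on product side:", paste(x$missingOnProductSide, collapse = ", "), "\n")
    if (length(x$overproducedOnProductSide))
      cat("  overproduced on product side:",
          paste(x$overproducedOnProductSide, collapse = ", "), "\n")
  }
  if (length(x$undeterminedMetabolites))
    cat("  metabolites without formula:",
        paste(x$undeterminedMetabolites, collapse = ", "), "\n")
  invisible(x)
}
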