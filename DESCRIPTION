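Package: gsmvault
Title: Versioned Storage, Comparison and SBML Exchange for Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A repository engine for curated genome-scale metabolic models.
    Models (compartments, metabolites, reactions with stoichiometry and
    gene-protein-reaction rules, genes, MIRIAM annotations) live in an
    append-only, revision-numbered store with a pending-change approval
    workflow and role-based permissions, so that any historical state of a
    model can be reconstructed and audited. The package parses chemical
    formulas and checks the elemental (and charge) balance of reactions,
    matches entities between two model snapshots by identifier precedence to
    produce Venn-style shared/unique summaries, searches entity fields, and
    reads and writes SBML Level 2 with MIRIAM annotations, three
    compartmentalization modes, filtered export, a COBRA-compatible profile,
    and delimited tabular export. A deterministic synthetic-model generator
    provides balanced fixtures and ground-truth model pairs for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'entities.R'
    'AllClasses.R'
    'AllGenerics.R'
    'gpr.R'
    'formula.R'
    'miriam.R'
    'model-methods.R'
    'balance.R'
    'permissions.R'
    'store.R'
    'store-io.R'
    'comparator.R'
    'sbml-export.R'
    'sbml-import.R'
    'decompartmentalize.R'
    'tables.R'
    'search.R'
    'generate.R'
    'gsmvault-package.R'
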