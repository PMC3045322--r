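# gsmvault

Versioned storage, elemental balance checking, comparison and SBML exchange
for genome-scale metabolic models (GSMMs), in R.

Reconstructing a metabolic model is an iterative, supervised, collaborative
process: curators propose edits to reactions, metabolites, compartments and
genes; a key researcher approves them; every intermediate version must remain
retrievable, comparable and exportable to analysis tools. gsmvault is the
computational core for that workflow, aimed at curators of GSMMs and at
developers of model-management infrastructure:

* **Model containers** — compartment hierarchies, metabolites with formulas
  and charges, reactions with per-reactant stoichiometry and
  gene–protein–reaction (GPR) Boolean rules, MIRIAM annotations resolved to
  web addresses through an extensible registry.
* **Balance check** — for each element *e*,
  `net(e) = Σ_products s·n(e) − Σ_substrates s·n(e)`; a reaction is balanced
  when every net is 0 (tolerance 1e-9), with missing/overproduced elements
  reported per side and charge checked as a pseudo-element when available.
* **Version store** — append-only change log with pending-change approval,
  global revision numbers, per-model version labels, entity histories with
  field diffs, snapshot reconstruction at any revision, and a four-class
  role-based permission system (unregistered / registered / editor /
  administrator).
* **Comparison** — entities of two snapshots matched by identifier
  precedence (reactions: KEGG ID, else canonical equation; metabolites:
  ChEBI > KEGG > name; genes: UniProt > name) into shared/unique lists and
  Venn counts, optionally restricted by compartment or subsystem.
* **Exchange** — SBML Level 2 Version 4 export (byte-deterministic, explicit
  stoichiometry everywhere, COBRA-compatible profile with
  reversibility-derived flux bounds), import of SBML L2/L3 core, three
  compartmentalization modes, subsystem/query-filtered export, TSV tables.
* **Synthetic models** — a deterministic generator of valid, elementally
  balanced fixture models and of model pairs with exact, known comparison
  ground truth.

## Worked example

```r
library(gsmvault)

m <- metabolicModel("ecoli_demo", organism = "Escherichia coli",
  compartments = list(compartment("e", "extracellular"),
                      compartment("c", "cytoplasm", parentId = "e")),
  metabolites = list(
    metabolite("glc", "glucose", formula = "C6H12O6", chebiId = "17234", keggId = "C00031"),
    metabolite("g6p", "glucose 6-phosphate", formula = "C6H13O9P", keggId = "C00092"),
    metabolite("atp", "ATP", formula = "C10H16N5O13P3", keggId = "C00002"),
    metabolite("adp", "ADP", formula = "C10H15N5O10P2", keggId = "C00008")),
  genes = list(gene("hxk1", "hexokinase 1", uniprotId = "P04806"),
               gene("hxk2", "hexokinase 2", uniprotId = "P04807")),
  reactions = list(reaction("HEX1", "hexokinase",
    rbind(reactants(c("glc", "atp"), 1, "c", "substrate"),
          reactants(c("g6p", "adp"), 1, "c", "product")),
    ecNumber = "2.7.1.1", keggId = "R00299", subsystem = "glycolysis",
    gpr = "hxk1 OR hxk2")))

balanceReport("HEX1", m)
#> Balance check: balanced
```

Glucose + ATP and glucose-6-phosphate + ADP carry identical element totals,
so the net of every element is zero. Supervised editing runs through a store:

```r
st <- modelStore()
addUser(st, user("alice", "administrator"))
addUser(st, user("bob", "editor", assignedModels = "ecoli_demo"))
publishModel(st, m, getUser(st, "bob"), getUser(st, "alice"))  # revision 1

ch <- proposeChange(st, getUser(st, "bob"), "ecoli_demo", "reaction", "update",
                    entityId = "HEX1",
                    fields = list(name = "hexokinase (D-glucose:ATP)"),
                    comment = "match BiGG naming")
approveChanges(st, ch$changeId, getUser(st, "alice"))          # revision 2

entityHistory(st, "ecoli_demo", "reaction", "HEX1")
#> History of reaction 'HEX1' in model 'ecoli_demo' (2 entries)
#>   r1 ... bob [create] abbreviation,name,reactants,... : initial import
#>   r2 ... bob [update] name: match BiGG naming
```

Until `approveChanges`, every accepted view still shows the old name;
`modelAtRevision(st, "ecoli_demo", 1)` retrieves the pre-edit snapshot
forever. Comparing two models with known overlap:

```r
pair <- generateModelPair(seed = 42)
compareModels(pair$modelA, pair$modelB)
#> ModelComparison: model_A vs model_B
#>   reactions    unique A    5 | shared   10 | unique B    7
#>   metabolites  unique A    5 | shared   12 | unique B    5
#>   genes        unique A    3 | shared    8 | unique B    3
```

The counts read: 5 reactions occur only in model A, 10 are shared (matched by
KEGG ID or identical chemical equation), 7 occur only in model B — and
likewise per category. Export for flux-balance tools:

```r
exportSBML(m, file = "ecoli_demo.xml", options = exportOptions(profile = "cobra"))$report
#> SBML export (L2V4, cobra profile, complete mode): 2 compartments, 4 species,
#>   4 metabolites, 1 reactions, 2 genes

miriamToURL("urn:miriam:kegg.reaction:R00299")
#> [1] "https://identifiers.org/kegg.reaction/R00299"
```

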