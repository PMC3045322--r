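---
title: "Managing, balancing and comparing genome-scale metabolic models with gsmvault"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing, balancing and comparing genome-scale metabolic models with gsmvault}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmvault)
```

## The problem

A genome-scale metabolic model (GSMM) is a curated inventory of the
biochemical reactions of an organism: each reaction consumes and produces
metabolites with stoichiometric coefficients in specific cellular
compartments, is gated by a Boolean gene–protein–reaction (GPR) rule, and is
annotated with external database references. Reconstructing such a model is an
iterative, collaborative process producing many intermediate versions, and the
final artifact is only useful if every component is unambiguously identified
and exchangeable with analysis tools through SBML.

gsmvault provides the computational machinery this workflow needs: an
append-only versioned store with supervised (pending → approved) editing,
elemental balance checking of reactions, identifier-precedence comparison of
two model snapshots with Venn-style summaries, field-wise quick search, and
SBML import/export with compartmentalization transforms and a
COBRA-compatible profile.

## Data model

A `MetabolicModel` holds compartments, metabolites, reactions and genes as
records keyed by identifier, plus the subsystem (pathway) vocabulary,
organism, MIRIAM annotations and notes. Compartments form a forest via
`parentId` references (a peroxisome sits inside the cytoplasm, which sits
inside the extracellular space). Each reactant row of a reaction names a
metabolite, a positive stoichiometric coefficient, a compartment and a side.

Entity records are deliberately plain named lists behind constructor
functions: the version store applies field-level deltas to them generically,
and the SBML and tabular writers treat them as flat field sets. Construction
checks types and identifier uniqueness; `validateModel()` performs the full
referential check (dangling references, compartment cycles, undeclared
subsystems) and reports unknown genes in GPR leaves as *warnings* rather than
errors, because draft models legitimately reference genes that have not been
annotated yet.

MIRIAM references are carried as single URN strings
(`urn:miriam:<datatype>:<identifier>`); identifiers.org URIs are accepted on
input. Resolution to web addresses goes through a flat datatype → URL-template
registry bundled as a text file and freely extensible by the user.

## GPR rules

The GPR grammar accepts gene identifiers, the case-insensitive operators
`AND`/`OR`, and grouping with either square brackets or parentheses
(`gene1 AND [gene2 OR gene3]`). Two choices were genuinely open:

* **Precedence.** For unbracketed mixed expressions, `AND` binds tighter than
  `OR`. This follows the dominant GPR convention (isoenzyme alternatives of
  enzyme complexes); fully bracketed inputs are unaffected.
* **Serialization.** `gprToString()` emits square brackets and upper-case
  operators by default, and the COBRA notes dialect (lower-case operators,
  parentheses) with `style = "cobra"`. Non-leaf children are always grouped,
  which makes serialize-then-parse the identity on every tree.

`evaluateGPR()` evaluates a tree against a set of present genes, enabling
gene-deletion reasoning; the test suite checks it against an independent
truth-table oracle over all gene subsets.

## Elemental balance

For a reaction, the net of element $e$ is

$$\mathrm{net}(e) \;=\; \sum_{\text{products } i} s_i\, n_i(e)\;-\;
\sum_{\text{substrates } j} s_j\, n_j(e),$$

where $s$ are stoichiometric coefficients and $n(e)$ the element counts
parsed from each metabolite's formula. A reaction is *balanced* when every
net is zero within a tolerance of $10^{-9}$ per element — a nonzero tolerance
is needed because curated models use fractional stoichiometries (biomass
equations), and that value is far below any meaningful composition difference
while absorbing decimal representation error. Negative entries are reported
as missing on the product side, positive entries as overproduced. A reaction
touching any metabolite without a formula is *undetermined*; single-sided
exchange reactions are reported unbalanced, never errored, because they are
unbalanced by design.

Two further choices: when **every** participant carries a charge, charge
conservation is checked alongside the elements as the pseudo-element
`"charge"` (the lower-case name cannot collide with an element symbol); and
non-IUPAC symbols such as `R` or `X` are accepted as opaque element tokens by
default, because lumped biomass species in published models use them
(`strict = TRUE` rejects them). Formulas are formatted in Hill order
(C, H, then alphabetical), and format-then-parse is the identity.

## The version store

Every modification enters as a *pending change* — a field-delta record with
author, timestamp and comment — and acquires effect only when an
administrator approves it. Approval of an arbitrary set of pending changes
creates one *revision* with a globally incremented number; snapshots are
reconstructed by replaying the approved change log up to a revision, so
pending or rejected material can never leak into a browse view, by
construction rather than by filtering. Rejected changes are retained for
audit but excluded from history and snapshots.

Affected models also receive a user-visible version label at each approval:
the label the approver supplies, or an auto-incremented numeric label
(`"1"`, `"2"`, ...) per model. Entity histories list, per approved change,
the revision, author, timestamp, comment, and the field diffs against the
previous version; replaying the diffs from the creation entry reproduces the
head state, which the tests verify over randomized histories against a
deep-copy-per-revision oracle.

The four user classes and their rights:

| class         | browse                                   | edit     | export | import | approve |
|---------------|------------------------------------------|----------|--------|--------|---------|
| unregistered  | accepted versions of public models        | —        | ✓      | —      | —       |
| registered    | + accepted versions of assigned models    | —        | ✓      | —      | —       |
| editor        | + all versions of assigned models         | assigned | ✓      | ✓      | —       |
| administrator | all models                                | all      | ✓      | ✓      | ✓       |

Export permission follows browse: every class may export what it may browse.
Public availability is model metadata outside version control, flipped
directly by administrators, like file attachments and discussion threads
(plain comment records attachable to any entity, create/list only).

The store persists as a single JSON file with a versioned header; values in
change deltas are serialized through a small type-tagged encoder because they
are heterogeneous (scalars, vectors, reactant tables, GPR trees). Timestamps
come from an injectable clock so that replays and tests are deterministic.
Concurrent multi-process access and authentication are out of scope: users
are declarative records.

## Model comparison

Entities of two snapshots are matched by identifier precedence:

* **Reactions** — KEGG ID when both sides carry one; a conflict means *no
  match*, with no fallback, treating a curated KEGG assignment as
  authoritative. Otherwise the canonical chemical equation: substrate and
  product multisets of (metabolite key, compartment path, stoichiometry),
  each side sorted. Reversible reactions compare equal under side swap;
  irreversible ones preserve direction; no stoichiometric rescaling is
  applied (2A → 2B differs from A → B).
* **Metabolites** — ChEBI, then KEGG, then case-insensitive name; compared at
  species level, ignoring compartments.
* **Genes** — UniProt, then case-insensitive name.

Many-to-many ambiguity is resolved by greedy one-to-one matching in
sorted-identifier order — deterministic and, on fixtures constructed without
matching ambiguity, provably equal to the optimum, which the tests confirm
against an all-pairs brute-force oracle with maximum bipartite matching.
Optional restrictions filter reactions by subsystem and/or compartment first;
metabolites and genes are then restricted to participants of the surviving
reactions. Venn counts and shared/unique lists derive from the match result,
and `comparisonTable()` flattens everything into a delimited-ready table.
Identical names with different ChEBI IDs count as distinct, and no
proton/water tolerance is applied in equation comparison — both are
conservative readings where the convention is genuinely unsettled.

## SBML exchange

Export emits SBML Level 2 Version 4 — the dialect with the broadest support
among constraint-based tools — as a deterministic byte stream: entities
sorted by identifier, fixed notes-line order, and an explicit `stoichiometry`
attribute on **every** species reference, including 1. Species are emitted
per (metabolite, compartment) pair with compartment-suffixed ids
(`glc_c`), and import folds suffixed species back into one metabolite per
base abbreviation. Model-level fields core SBML cannot hold (organism,
version label, gene metadata) travel in documented XHTML notes lines
(`ORGANISM:`, `VERSION:`, `GENE:`), so export → import → export is byte-stable
after the first cycle and the comparator finds zero differences between a
model and its re-import. Import accepts Level 2 (any version) and Level 3
core via namespace-agnostic XPath.

The `cobra` profile additionally writes `GENE_ASSOCIATION`, `SUBSYSTEM` and
`FORMULA` notes plus per-reaction kinetic-law parameters
`LOWER_BOUND`/`UPPER_BOUND`/`OBJECTIVE_COEFFICIENT` derived from
reversibility (reversible −1000..1000, irreversible 0..1000, objective 0) —
the model stores no bounds, so conventional defaults are required for the
export to be loadable by flux-balance tools. Subsystem filters and reaction
query results restrict the emitted reactions, with species and genes
restricted to participants. SBML packages (fbc, groups) and kinetic laws
beyond the bound-carrying placeholder are out of scope.

Three compartmentalization modes serve tools with coarser compartment
support: *complete* (as stored); *partial* — every reactant in a compartment
within the cytoplasm (ancestor-or-self, so cytoplasmic reactants stay put) is
reassigned to the cytoplasm, which is auto-detected by name
(`cytoplasm`/`cytosol`) unless given explicitly, and emptied descendants are
deleted; *full* — a single unsegregated compartment, where reactants
identical on both sides with equal stoichiometry cancel and reactions that
cancel to empty (pure transports) are dropped and reported. Cancellation
removes equal contributions from both sides, so the elemental net of every
surviving reaction is unchanged, and full mode is idempotent.

## The synthetic-model generator

The generator is first-class, tested code: it is the ground-truth side of
the balance, comparison, search and round-trip properties. Balanced reactions
are constructed from formula-conserving metabolite families — composition
triples (A + B → AB with the summed formula), isomer pairs, and transports —
so balance holds exactly by construction, not by numerical accident. Default
conditions, chosen once as representative of a small curated microbial model:
4 compartments in a depth-3 hierarchy (extracellular / cytoplasm /
organelles), 40 metabolites, 60 reactions, 30 genes, KEGG/ChEBI/UniProt
annotation fractions of 0.7/0.6/0.6, charge 0 on all metabolites (so charge
balance is exactly satisfiable), ~30% reversible reactions. Generation is
bit-for-bit reproducible from (parameters, seed) and never disturbs the
caller's RNG stream.

`generateModelPair()` builds two models with exact per-category overlap
counts: shared reactions split between KEGG-matched (same accession,
deliberately different equations) and equation-matched (no accession,
identical equations); shared metabolites cycle through the ChEBI/KEGG/name
rules; shared genes through UniProt/name; unique entities carry
model-private accessions, names and equations over model-private metabolites,
so they are unmatchable by every rule and the intended pairing is the unique
optimum. `perturbBalance()` increments one element of one participant with a
nonzero net coefficient, so the perturbed element provably appears in the
balance net (pure transports have no such participant and are rejected).

What the generator does **not** emulate — and hence what passing tests do not
show about real curated models: biomass-scale equations with dozens of
fractional coefficients, systematically missing or wrong formulas,
proton/water bookkeeping differences between models, duplicated or ambiguous
database accessions, inconsistent naming dialects, and SBML produced by other
tools with vendor-specific annotation layouts. The import path is exercised
only on documents this package emits plus hand-written corner cases.

## Numerical and procedural choices

* Balance tolerance $10^{-9}$ per element; full-decomposition cancellation
  uses $10^{-12}$ on stoichiometry equality.
* All tie-breaks are lexicographic over identifiers in the C locale; entity
  collections are kept sorted by identifier everywhere, which makes
  snapshots, emission and comparison order-independent of construction order.
* Degenerate inputs: empty models validate cleanly; empty reactant tables are
  legal records (exchange placeholders) but are not emitted to SBML, which
  requires at least one species reference; approval of an empty change set is
  an argument error, not a no-op.
* Quick search is a case-insensitive substring scan with no ranking, over
  exactly the documented per-kind field lists. Model selection restricts
  *reaction* hits (reactions belong to models); metabolites, genes and
  organisms are searched store-wide.
* Problem sizes in the property checks — 1000 balanced reactions and 1000
  perturbations, 10,000 formulas, 200-step histories, 100 ground-truth pairs,
  50 SBML round trips, 500 GPR trees with all $2^6$ gene subsets — were
  chosen to exercise every construction branch several hundred times while
  keeping the default check run comfortably fast on one core.

## Known limitations

Single-process store access; no authentication or notification; no UniProt
sequence retrieval; no isotope or hydrate formula dialects; SMILES/InChI
annotations are stored but not parsed; Venn *counts and lists* are the
comparison contract — area-accurate diagram rendering is left to plotting
packages; tabular export is delimited text, not spreadsheet/PDF rendering.
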