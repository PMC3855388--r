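---
title: "Methods: regulatory network extension with RegLinker"
author: "RegLinker authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory network extension with RegLinker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RegLinker)
```

## The problem and the model

Pathway and interaction resources describe what genes and proteins do, but
rarely who regulates them. Transcription factors (TFs) act on genes through
binding sites proximal or distal to the transcription start site; microRNAs
(miRNAs) repress translation or cleave their target mRNAs; drugs and other
small molecules modulate protein activity. Databases of such
regulator–target interactions exist for each class, but they use different
identifier systems, formats and evidence conventions, which makes joint
analysis tedious.

RegLinker works on a simple shared abstraction, the **RegIN** (regulatory
interaction network): one source database release, formatted as a directed
graph whose edges always point regulator → target and whose nodes carry
identifiers in one or more identifier systems. Given a user's **seed
network** and a collection of RegINs, the extension step computes a
**one-hop graft**:

* a seed node *matches* a RegIN node iff any value of the seed's chosen id
  attribute equals any identifier value of the RegIN node (exact,
  case-sensitive string equality);
* an interaction `s → t` of RegIN `R` *qualifies* under direction mode
  `targets` iff `s` matches a seed node, under `regulators` iff `t` matches
  a seed node, and under `both` (the default) iff either does;
* every qualifying interaction contributes exactly one edge tagged with
  `R`'s name. An interaction present in `k` RegINs therefore appears as
  `k` parallel edges, and `support(u → v)` — the number of distinct RegINs
  containing the pair — equals the number of parallel edges between `u`
  and `v`;
* endpoints that match a seed node attach to that node; the rest become
  *added* nodes, merged across RegINs by **canonical key** (below). Added
  nodes are never re-queried: the extension is strictly one hop, so the
  output is a function of the seed, not of what was added. Transitive
  extension, when wanted, is an explicit re-run using a cleaned export as
  the new seed.

The seed subgraph — nodes, edges and all their attributes — is contained
unmodified in the output, and removing every added element recovers it
exactly. Node origin is recorded in plain `origin` / `styleHint`
attributes ("grey circle" for initial nodes, "pink hexagon" for added
ones) so any XGMML consumer can style the graph; no renderer is shipped.

## Canonical keys and node merging

Cross-database integration hinges on deciding when two records denote the
same molecule. RegLinker uses a single deterministic rule: the **canonical
key** of an identifier set is the value of the first identifier whose
system appears earliest in a configurable priority list (default:
`ensembl`, `miRBase-accession`, `drugbank`, `ncbigene`, `uniprot`,
`miRBase-id` — a primary system per biotype, then secondary systems); if
no system matches, the lexicographically smallest value (C-locale radix
order, so the choice is locale-independent). Ties within one system break
lexicographically. Added nodes with equal canonical keys are merged, their
identifier sets unioned.

This rule is transitive and order-independent, which key-equality merging
needs and "merge on any shared identifier" does not give for free.
The more aggressive variant is still available
(`mergeBy = "any-shared-id"`, a transitive union–find over shared
identifier values) for collections whose records lack a common primary
system; it can chain distinct molecules through promiscuous identifiers,
which is why it is not the default.

Matching is deliberately **case-sensitive**: identifier systems such as
miRBase distinguish ids that differ only in case (`hsa-miR-21` vs
`hsa-mir-21` denote mature miRNA vs precursor), so case folding could
silently merge distinct molecules. Seeds annotated in an unsupported
system are translated first with a TSV cross-reference table
(`expandSeedIds()`), which only ever *adds* values — the original ids are
always retained, and many-to-many mappings are kept as sets and reported
rather than resolved silently. Only the seed side is translated; RegINs
already embed several systems per node, so translating the smaller side is
sufficient and keeps RegIN files untouched.

## Ambiguity, duplicates and degenerate inputs

* One seed value hitting several RegIN nodes → the union of their
  interactions is taken and a diagnostic is recorded; dropping would hide
  data and picking one would be arbitrary.
* One RegIN node matching several seed nodes → the interaction attaches to
  every matching seed node (the symmetric choice), with a diagnostic.
* Duplicate `(source, target)` interactions within one RegIN are collapsed
  at load time with evidence concatenated; after endpoint resolution the
  same collapse is applied per RegIN at the resolved-pair level, so each
  RegIN contributes at most one edge per pair and the support count is
  exactly the number of distinct supporting sources. Both collapses emit
  diagnostics.
* Self-loops (autoregulation) are biologically real: they are kept and
  flagged.
* RegIN nodes without identifiers load with a warning, can never match,
  and — if they appear as endpoints of qualifying interactions — become
  unmergeable added nodes with a per-RegIN fallback key.
* A seed whose id attribute is absent from every node yields an empty
  extension plus a warning, not an error.
* Inputs that already carry this package's provenance attributes are
  refused: re-extending an extended network would double-count support.

## Filtering semantics

Both post-extension filters are non-destructive visibility flags and can
be applied and reverted freely. Hiding a RegIN hides its edges; an added
node is visible iff it has at least one visible incident added edge; seed
elements are never hidden. The overlap threshold `k` shows an added edge
iff its RegIN is shown **and** its pair's support is ≥ `k`.

One composition question is genuinely open: when a RegIN is hidden, does
it still count towards support? RegLinker's default counts support over
**shown** RegINs only, because then any sequence of hide/threshold
operations is equivalent to recomputing visibility from scratch from the
final state — an invariant the test suite asserts. The alternative
(support over all loaded RegINs, useful when a source should lend evidence
without being displayed) is one call away: `setSupportMode(x, "loaded")`
or `--support-over loaded`.

## File formats

RegINs and outputs use an XGMML dialect chosen to match Cytoscape-era
conventions: one `<graph>` per file (several is an error), `<att>`
elements with `name`/`value`/`type` ∈ {string, integer, real, list}, list
members as nested string `att` children with order preserved, node
identifiers in a single list attribute `identifiers` with `system:value`
entries (a bare value means system "unknown"), and graph-level
`database`/`version`/`organism`/`type` metadata. Documents with or without
the XGMML namespace are accepted; none is emitted. `<graphics>`
subelements are skipped on read and never written. Writing is
deterministic (insertion order, nodes before edges) and real-valued
attributes are serialised with `%.17g` so doubles round-trip bit-exactly.
Seed networks additionally load from SIF (`source interaction target`) and
one-id-per-line node lists; all readers tolerate Windows line endings and
a UTF-8 BOM.

The table-to-RegIN converter (`buildRegin()`) is schema-driven rather than
per-database: a small YAML file names the identifier columns per system on
each side, label/biotype assignments, evidence columns, metadata and the
delimiter for multi-valued cells (default `|`). Node identity during
building is the canonical key, so one molecule listed under several labels
collapses into one node (with a collision diagnostic); rows missing all
source or all target ids are skipped and counted. No licence-restricted
database content ships with the package — only the converter and synthetic
fixtures.

## The synthetic fixture generator

`generateFixture()` emulates the *shape* of a real RegIN collection at
desk scale: molecules with a primary identifier system (`sysP`) plus
random aliases (`sysA`, `sysB`); seed nodes annotated in a randomly chosen
system, so multi-system matching is always exercised; regulators drawn
from a pool shared across RegINs, so cross-RegIN node merging occurs; a
controlled fraction of qualifying interactions (`overlapFraction`) drawn
from a pool present in *every* RegIN, giving known support sets; a
`directionMix` split between seed-as-target and seed-as-regulator
interactions; and a fixed quarter of each RegIN's interactions touching no
seed node at all, so the extraction rule has something to reject (a fixed
background fraction rather than another knob, to keep the generator's
parameter set small). Non-shared qualifying pairs are kept globally
unique by construction — when the regulator × seed grid is exhausted a
fresh regulator is minted — because accidental duplicates would make a
pair's true support differ from its designed support.

Crucially, the generator records the **ground truth** (every pair's
supporting RegIN set and its qualification under each direction mode)
constructively, while generating — never by running the linker — so the
"linker output equals ground truth" tests are genuine oracle checks. The
same seed produces byte-identical files.

`figure1Toy()` is a fixed four-source miRNA-target workflow fixture: 4
seed miRNAs, two large "predicted" RegINs and two small "validated" ones
with designed per-source added counts (40, 28, 6, 3), exactly 5 pairs
supported by ≥ 2 sources, and 9 edges surviving when the predicted sources
are hidden. All identifiers are synthetic (`SYN-MIMAT-…`, `SYNG…`); the
numbers are design choices of this fixture, not measurements of any real
database.

What passing these tests does *not* show: real collections have heavier
ambiguity (shared symbols across paralogues, retired identifiers),
identifier translation gaps, and interaction-count distributions that are
far from uniform. The generator makes no statistical claim about those;
it validates the algebra of matching, grafting, provenance and filtering,
not database quality.

## Numerical and design choices

* Problem sizes: the randomized suites use up to 50 seed nodes, 5 RegINs
  and 300 interactions per RegIN (200 seeded trials for the extension
  oracle and direction decomposition; 60 trials for the
  conservation/threshold properties; 100 documents for I/O round-trips),
  sizes at which brute-force oracles are still exact and fast.
* Determinism: all iteration orders are insertion orders; RegIN discovery
  in a directory sorts file names; identical inputs give identical outputs
  including node and edge order.
* Identifier-system names are compared exactly, like identifier values.
* Edge colours are cosmetic provenance hints (a fixed palette cycled over
  RegINs, written as the `colour` edge attribute); no visual rendering is
  implemented or planned.
* Reports are JSON; per-RegIN counts recomputed by `linkStats()` are
  defined purely in graph terms (added nodes attributed to the RegIN of
  their first incident added edge), so a recount after serialisation
  agrees with the original run.

## Known limitations

* Matching is exact string equality: no symbol-alias or fuzzy matching,
  by design; use a mapping table for cross-system seeds.
* One-hop extension only; regulatory cascades require iterated runs.
* The mapping layer is file-based; there is no live identifier-mapping
  service connectivity.
* XGMML `<graphics>` styling is ignored; sessions of graphical tools are
  out of scope.
* `canonicalKey` merging assumes the priority list names a system shared
  by the sources being merged; collections without any common system
  should use `mergeBy = "any-shared-id"` and review the merge diagnostics.
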