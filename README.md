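# RegLinker

Gene expression and protein activity are shaped by regulators that most
pathway and interaction resources leave out: transcription factors binding
proximal or distal to the transcription start site, microRNAs silencing
their target mRNAs, and drugs or other small molecules acting on proteins.
RegLinker is an R package for biologists and bioinformaticians who want to
graft that regulatory layer onto a network they already have — a
protein–protein interaction network, a pathway, or a plain gene list — and
then reason about how well the added interactions are supported.

The regulatory knowledge comes from **RegINs** (regulatory interaction
networks): directed regulator → target networks stored as XGMML files, one
per source database and release, whose nodes carry identifiers in several
identifier systems (Ensembl gene, NCBI gene, UniProt, miRBase
accession/id, DrugBank). RegLinker reads a collection of RegINs, matches
the seed network's chosen node attribute against the RegIN identifiers by
exact string equality, and performs a **one-hop extension**: every
interaction in which a seed node participates on the requested side is
added to the graph; newly added molecules are never re-queried.

The result is a provenance-aware multigraph. Writing `E_R` for the edge set
contributed by RegIN `R`, an interaction between a regulator `u` and target
`v` has

```
support(u → v) = |{ R : (u → v) ∈ E_R }|
```

i.e. one parallel edge per supporting source. Two non-destructive filters
operate on this multigraph: per-RegIN show/hide, and the **overlap
threshold** keeping only interactions with `support ≥ k` (support counted,
by default, over currently shown sources). Direction modes follow the
integration semantics of regulator databases: *add targets* keeps
interactions whose regulator is in the seed, *add regulators* keeps
interactions that target a seed node, *both* (default) keeps either.

The package also includes:

* an XGMML reader/writer (dialect documented in `R/xgmml-io.R`), plus SIF
  and node-list seed readers;
* BridgeDb-style identifier translation from TSV cross-reference tables
  (`loadMappingTable()`, `expandSeedIds()`) for seeds annotated in a
  system the RegINs do not carry;
* a converter turning tabular regulator–target dumps into valid RegINs
  (`buildRegin()` + YAML schemas), with a validation report
  (`validateRegin()`);
* a deterministic synthetic-fixture generator with constructive ground
  truth (`generateFixture()`, `figure1Toy()`) used by the test suite;
* a command line, `exec/reglink`, with subcommands `extend`, `filter`,
  `stats`, `build-regin`, `validate-regin`, `simulate`.

## Worked example

Four synthetic miRNAs are extended with targets from four miRNA-target
RegINs — two large "predicted" sources and two small "validated" ones:

```r
library(RegLinker)

toy <- figure1Toy()
ext <- extendNetwork(toy$seed, toy$regins, direction = "targets")
perReginCounts(ext)
#>        regin addedInteractions addedNodes matchedSeedNodes
#>   predictedA                40         40                4
#>   predictedB                28         26                4
#>   validatedA                 6          4                4
#>   validatedB                 3          1                3
```

40 + 28 + 6 + 3 = 77 added parallel edges; `addedNodes` attributes each
new target gene to the source that introduced it first. Keeping only the
validated evidence, or only the consensus interactions:

```r
vali <- setVisibility(setVisibility(ext, "predictedA", FALSE),
                      "predictedB", FALSE)
sum(networkEdges(vali)$visible & networkEdges(vali)$origin == "added")
#> [1] 9                      # the 6 + 3 validated interactions

cons <- applyThreshold(ext, 2)
ed <- networkEdges(cons)
ed <- ed[ed$visible & ed$origin == "added", ]
length(unique(paste(ed$source, ed$target)))
#> [1] 5                      # pairs present in two or more sources
```

Both filters are reversible flags; `exportVisible(cons, "consensus.xgmml")`
materialises the filtered graph. The same pipeline from the shell:

```sh
reglink simulate --rng-seed 11 --out fx
reglink extend --seed fx/seed.xgmml --seed-format xgmml \
    --id-attribute identifier --regins fx/regins \
    --direction targets --priority sysP,sysA,sysB \
    -o extended.xgmml --report report.json
reglink filter --in extended.xgmml --threshold 2 --export-visible consensus.xgmml
```

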