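Package: RegLinker
Title: Extend Biological Networks with Regulatory Interactions from
    RegIN Files
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extends a seed biological network with regulatory
    interactions (microRNA-target, transcription factor-target,
    drug-target) drawn from regulatory interaction network (RegIN)
    files stored in XGMML. Matching is identifier-based across several
    identifier systems with optional cross-reference translation
    tables. Each grafted edge keeps the provenance of the RegIN it came
    from, so the result is a multigraph in which an interaction
    supported by k sources appears as k parallel edges. Post-extension
    filters hide individual sources or keep only interactions supported
    by at least a chosen number of sources. Includes a converter that
    turns tabular regulator-target dumps into RegIN files, a
    deterministic synthetic-fixture generator with constructive ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
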