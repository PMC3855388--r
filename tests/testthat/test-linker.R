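# A tiny hand-built RegIN used across several cases: miRNAs M1, M2 and
# genes G1..G3 with interactions M1->G1, M1->G2, M2->G3.
miniRegin <- function(name = "A") {
  nd <- data.frame(nodeId = c("M1", "M2", "G1", "G2", "G3"),
                   label = c("mir-1", "mir-2", "gene1", "gene2", "gene3"),
                   biotype = c("microRNA", "microRNA", "gene", "gene",
                               "gene"),
                   stringsAsFactors = FALSE)
  nd$identifiers <- I(list(
    c(`miRBase-accession` = "MIMAT1"), c(`miRBase-accession` = "MIMAT2"),
    c(ensembl = "ENSG1"), c(ensembl = "ENSG2"), c(ensembl = "ENSG3")))
  ia <- data.frame(sourceId = c("M1", "M1", "M2"),
                   targetId = c("G1", "G2", "G3"),
                   stringsAsFactors = FALSE)
  regIN(name, nd, ia, database = name, version = "1",
        organism = "synthetic", interactionType = "predicted MTI")
}

test_that("indexRegin maps every identifier value to its node ids", {
  nd <- data.frame(nodeId = c("N", "M"), stringsAsFactors = FALSE)
  nd$identifiers <- I(list(c(ensembl = "E1", ncbigene = "1"),
                           c(uniprot = "X", ncbigene = "1")))
  idx <- indexRegin(regIN("r", nd))
  expect_identical(idx[["E1"]], "N")
  expect_identical(idx[["X"]], "M")
  expect_setequal(idx[["1"]], c("N", "M"))
  # random RegINs: index lookups equal a linear scan over all nodes
  set.seed(21)
  for (trial in 1:20) {
    rg <- randomInstance()$regins[[1]]
    idx <- indexRegin(rg)
    nd <- reginNodes(rg)
    allVals <- unique(unlist(lapply(nd$identifiers, unname)))
    for (v in allVals) {
      scan <- nd$nodeId[vapply(nd$identifiers, function(ids) {
        v %in% unname(ids)
      }, NA)]
      expect_setequal(idx[[v]], scan)
    }
  }
})

test_that("direction modes select the sides the seed participates on", {
  # seed gene G1, add regulators: only M1 -> G1 qualifies
  seed <- seedNetwork("ENSG1", idAttribute = "id")
  ext <- extendNetwork(seed, miniRegin(), direction = "regulators")
  expect_identical(extractedEdges(ext), "A\tadded:MIMAT1\tENSG1")
  expect_identical(extractedAddedNodes(ext), "added:MIMAT1")

  # seed miRNA M1, add targets: G1 and G2 appear
  seed <- seedNetwork("MIMAT1", idAttribute = "id")
  ext <- extendNetwork(seed, miniRegin(), direction = "targets")
  expect_identical(extractedEdges(ext),
                   c("A\tMIMAT1\tadded:ENSG1", "A\tMIMAT1\tadded:ENSG2"))
  expect_identical(extractedAddedNodes(ext),
                   c("added:ENSG1", "added:ENSG2"))
  # wrong direction adds nothing
  ext <- extendNetwork(seed, miniRegin(), direction = "regulators")
  expect_length(extractedEdges(ext), 0L)
})

test_that("the same interaction in two RegINs gives parallel edges, one node", {
  seed <- seedNetwork("ENSG1", idAttribute = "id")
  ext <- extendNetwork(seed, list(miniRegin("A"), miniRegin("B")),
                       direction = "regulators")
  expect_identical(extractedEdges(ext),
                   c("A\tadded:MIMAT1\tENSG1", "B\tadded:MIMAT1\tENSG1"))
  expect_identical(extractedAddedNodes(ext), "added:MIMAT1")
  idx <- buildSupportIndex(ext)
  expect_identical(idx$support, 2L)
  expect_identical(idx$regins[[1]], c("A", "B"))
})

test_that("extension with no RegINs is the identity with a zero report", {
  seed <- seedNetwork(c("a", "b"),
                      edges = data.frame(source = "a", target = "b",
                                         stringsAsFactors = FALSE))
  ext <- extendNetwork(seed, list())
  expect_identical(nrow(networkNodes(ext)), 2L)
  expect_identical(nrow(networkEdges(ext)), 1L)
  expect_identical(nrow(perReginCounts(ext)), 0L)
  expect_identical(sum(networkEdges(ext)$origin == "added"), 0L)
})

test_that("interactions between two seed nodes add an edge but no node", {
  # a TF already present in the seed targets another seed gene
  seed <- seedNetwork(c("MIMAT1", "ENSG1"), idAttribute = "id")
  ext <- extendNetwork(seed, miniRegin(), direction = "both")
  ed <- networkEdges(ext)
  ed <- ed[ed$origin == "added", ]
  expect_identical(ed$source[ed$target == "ENSG1"], "MIMAT1")
  expect_identical(sum(networkNodes(ext)$origin == "added"), 1L)  # G2 only
})

test_that("already-extended inputs are refused", {
  seed <- seedNetwork("ENSG1", idAttribute = "id")
  ext <- extendNetwork(seed, miniRegin(), direction = "regulators")
  p <- withr::local_tempfile(fileext = ".xgmml")
  extendedToXgmml(ext, p)
  reloaded <- extendedFromXgmml(p)
  expect_error(extendNetwork(reloaded@seed, miniRegin()), NA)
  # but a seed carrying provenance attributes is rejected
  sn <- data.frame(nodeId = "x", stringsAsFactors = FALSE)
  sn$attrs <- I(list(list(id = "ENSG1", origin = "added")))
  tainted <- seedNetwork(sn, idAttribute = "id")
  expect_error(extendNetwork(tainted, miniRegin()), "provenance")
})

test_that("ambiguous matches take the union and are reported", {
  # one seed value hits two RegIN nodes
  nd <- data.frame(nodeId = c("N1", "N2", "T"), stringsAsFactors = FALSE)
  nd$identifiers <- I(list(c(ensembl = "X"), c(ensembl = "X"),
                           c(ensembl = "TGT")))
  ia <- data.frame(sourceId = c("N1", "N2"), targetId = c("T", "T"),
                   stringsAsFactors = FALSE)
  rg <- regIN("amb", nd, ia)
  seed <- seedNetwork("X", idAttribute = "id")
  ext <- extendNetwork(seed, rg, direction = "targets")
  # both RegIN nodes resolve to the same seed node; the two interactions
  # collapse onto one resolved pair for this RegIN
  expect_identical(extractedEdges(ext), "amb\tX\tadded:TGT")
  expect_true(any(grepl("matches 2 nodes", diagnostics(ext))))
  expect_true(any(grepl("merged", diagnostics(ext))))
})

test_that("extension is deterministic", {
  set.seed(77)
  inst <- randomInstance()
  e1 <- extendNetwork(inst$seed, inst$regins)
  e2 <- extendNetwork(inst$seed, inst$regins)
  expect_identical(networkNodes(e1), networkNodes(e2))
  expect_identical(networkEdges(e1), networkEdges(e2))
  expect_identical(perReginCounts(e1), perReginCounts(e2))
})

test_that("extend matches the brute-force oracle on random instances", {
  set.seed(22)
  for (trial in 1:25) {
    inst <- randomInstance()
    for (d in c("both", "targets", "regulators")) {
      got <- suppressWarnings(extendNetwork(inst$seed, inst$regins,
                                            direction = d))
      want <- oracleExtend(inst$seed, inst$regins, d)
      expect_identical(extractedEdges(got), want$edges)
      expect_identical(extractedAddedNodes(got), want$addedNodes)
    }
  }
})

test_that("'both' is the union of 'targets' and 'regulators'", {
  set.seed(23)
  for (trial in 1:15) {
    inst <- randomInstance()
    eb <- suppressWarnings(
      extractedEdges(extendNetwork(inst$seed, inst$regins, "both")))
    et <- suppressWarnings(
      extractedEdges(extendNetwork(inst$seed, inst$regins, "targets")))
    er <- suppressWarnings(
      extractedEdges(extendNetwork(inst$seed, inst$regins, "regulators")))
    expect_identical(eb, sort(union(et, er)))
  }
})

test_that("the seed subgraph is conserved and recoverable", {
  set.seed(24)
  for (trial in 1:10) {
    inst <- randomInstance()
    ext <- suppressWarnings(extendNetwork(inst$seed, inst$regins))
    nd <- networkNodes(ext)
    ed <- networkEdges(ext)
    ini <- nd$origin == "initial"
    expect_identical(nd$nodeId[ini], seedNodes(inst$seed)$nodeId)
    expect_identical(nd$attrs[ini], seedNodes(inst$seed)$attrs)
    eini <- ed$origin == "initial"
    expect_identical(ed$source[eini], seedEdges(inst$seed)$source)
    expect_identical(ed$target[eini], seedEdges(inst$seed)$target)
    expect_identical(ed$attrs[eini], seedEdges(inst$seed)$attrs)
    # every added node touches at least one added edge
    addedN <- nd$nodeId[nd$origin == "added"]
    touched <- unique(c(ed$source[!eini], ed$target[!eini]))
    expect_true(all(addedN %in% touched))
  }
})

test_that("linkStats recounts agree with a full edge scan", {
  set.seed(25)
  for (trial in 1:10) {
    inst <- randomInstance()
    ext <- suppressWarnings(extendNetwork(inst$seed, inst$regins))
    pr <- perReginCounts(linkStats(ext))
    ed <- networkEdges(ext)
    added <- ed[ed$origin == "added", ]
    expect_identical(sum(pr$addedInteractions), nrow(added))
    for (i in seq_len(nrow(pr))) {
      expect_identical(pr$addedInteractions[i],
                       sum(added$regin == pr$regin[i]))
    }
    expect_identical(sum(pr$addedNodes),
                     sum(networkNodes(ext)$origin == "added"))
  }
})

test_that("merging by any shared identifier unifies partially overlapping nodes", {
  # same miRNA listed with different primary systems in two RegINs
  mk <- function(name, ids) {
    nd <- data.frame(nodeId = c("M", "G"), stringsAsFactors = FALSE)
    nd$identifiers <- I(list(ids, c(ensembl = "ENSG1")))
    regIN(name, nd, data.frame(sourceId = "M", targetId = "G",
                               stringsAsFactors = FALSE))
  }
  a <- mk("A", c(`miRBase-id` = "mir-9", uniprot = "U1"))
  b <- mk("B", c(uniprot = "U1", ncbigene = "42"))
  seed <- seedNetwork("ENSG1", idAttribute = "id")
  # canonical keys differ (ncbigene outranks miRBase-id), so default
  # merging keeps two added nodes ...
  ext1 <- extendNetwork(seed, list(a, b))
  expect_identical(sum(networkNodes(ext1)$origin == "added"), 2L)
  # ... but any-shared-id merging collapses them via the shared uniprot id
  ext2 <- extendNetwork(seed, list(a, b), mergeBy = "any-shared-id")
  expect_identical(sum(networkNodes(ext2)$origin == "added"), 1L)
  expect_identical(buildSupportIndex(ext2)$support, 2L)
})

test_that("self-loops are kept and flagged", {
  nd <- data.frame(nodeId = "A", stringsAsFactors = FALSE)
  nd$identifiers <- I(list(c(ensembl = "E1")))
  rg <- regIN("auto", nd, data.frame(sourceId = "A", targetId = "A",
                                     stringsAsFactors = FALSE))
  seed <- seedNetwork("E1", idAttribute = "id")
  ext <- extendNetwork(seed, rg)
  expect_identical(extractedEdges(ext), "auto\tE1\tE1")
  expect_true(any(grepl("self-loop", diagnostics(ext))))
})
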