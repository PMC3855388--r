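mtiSchema <- function(...) {
  buildSchema(
    sourceIds = c("miRBase-accession" = "mirna_acc"),
    targetIds = c(ensembl = "gene_ens", ncbigene = "gene_entrez"),
    sourceLabel = "mirna", targetLabel = "gene",
    sourceBiotype = "microRNA", targetBiotype = "gene",
    edgeAttrs = "pmid",
    database = "synthDB", version = "1.0", organism = "synthetic",
    interactionType = "validated MTI", ...)
}

writeTable <- function(rows) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("mirna\tmirna_acc\tgene\tgene_ens\tgene_entrez\tpmid", rows),
             p)
  p
}

test_that("tables convert into RegINs with merged nodes and edges", {
  p <- writeTable(c(
    "miR-a\tMIMAT01\tG1\tENSG01\t111\t77",
    "miR-a\tMIMAT01\tG2\tENSG02\t222\t78",
    "miR-b\tMIMAT02\tG1\tENSG01\t111\t79"))
  built <- buildRegin(p, mtiSchema())
  expect_identical(nrow(reginNodes(built$regin)), 4L)
  expect_identical(nrow(reginInteractions(built$regin)), 3L)
  expect_identical(built$report$rowsSkipped, 0L)
  expect_identical(validateRegin(built$regin)$ok, TRUE)
})

test_that("duplicate rows merge evidence and skipped rows are counted", {
  p <- writeTable(c(
    "miR-a\tMIMAT01\tG1\tENSG01\t111\t77",
    "miR-a\tMIMAT01\tG1\tENSG01\t111\t88",
    "miR-a\tMIMAT01\t\t\t\t99"))
  built <- buildRegin(p, mtiSchema())
  ia <- reginInteractions(built$regin)
  expect_identical(nrow(ia), 1L)
  expect_setequal(ia$evidence[[1]]$pmid, c("77", "88"))
  expect_identical(built$report$duplicatesMerged, 1L)
  expect_identical(built$report$rowsSkipped, 1L)
})

test_that("multi-valued cells split on the schema delimiter", {
  p <- writeTable("miR-a\tMIMAT01\tG1\tENSG01\t111\t77|78")
  built <- buildRegin(p, mtiSchema())
  expect_identical(reginInteractions(built$regin)$evidence[[1]]$pmid,
                   c("77", "78"))
})

test_that("missing schema columns and empty tables are reported", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb", p)
  expect_error(buildRegin(p, mtiSchema()), "missing from table")
  writeLines("mirna\tmirna_acc\tgene\tgene_ens\tgene_entrez\tpmid", p)
  expect_warning(built <- buildRegin(p, mtiSchema()), "empty")
  expect_identical(nrow(reginNodes(built$regin)), 0L)
})

test_that("building is order-insensitive at the set level", {
  set.seed(51)
  rows <- sprintf("m%d\tMIMAT%02d\tG%d\tENSG%02d\t%d\t%d",
                  sample(4, 12, TRUE), sample(4, 12, TRUE),
                  sample(5, 12, TRUE), sample(5, 12, TRUE),
                  sample(999, 12), sample(999, 12))
  # note: mirna_acc column drives identity, label column may disagree
  a <- buildRegin(writeTable(rows), mtiSchema())
  b <- buildRegin(writeTable(sample(rows)), mtiSchema())
  fa <- reginFingerprint(a$regin)
  fb <- reginFingerprint(b$regin)
  expect_identical(fa$edges, fb$edges)
  expect_identical(length(fa$nodes), length(fb$nodes))
})

test_that("build -> write -> read reproduces the same sets", {
  set.seed(52)
  rows <- sprintf("m%d\tMIMAT%02d\tG%d\tENSG%02d\t10%d\t%d",
                  1:8, 1:8, rep(1:4, 2), rep(1:4, 2), rep(1:4, 2), 1:8)
  built <- buildRegin(writeTable(rows), mtiSchema())
  p <- withr::local_tempfile(fileext = ".xgmml")
  reginToXgmml(built$regin, p)
  back <- reginFromXgmml(p, name = reginName(built$regin))
  expect_identical(reginFingerprint(back), reginFingerprint(built$regin))
})

test_that("validateRegin reports exactly the injected faults", {
  toy <- figure1Toy()
  good <- toy$regins[[1]]
  expect_true(validateRegin(good)$ok)

  # identifier-less node
  bad <- good
  nd <- bad@nodes
  nd$identifiers[[1]] <- character()
  bad@nodes <- nd
  rep <- validateRegin(bad)
  expect_false(rep$ok)
  expect_true(any(grepl(nd$nodeId[1], rep$warnings)))

  # dangling interaction (slot surgery bypasses the constructor dedup)
  bad <- good
  ia <- bad@interactions
  ia$sourceId[1] <- "ghost"
  bad@interactions <- ia
  expect_true(any(grepl("ghost", validateRegin(bad)$errors)))

  # duplicate pair
  bad <- good
  bad@interactions <- rbind(bad@interactions, bad@interactions[1, ])
  expect_true(any(grepl("duplicate", validateRegin(bad)$warnings)))

  # missing metadata
  bad <- good
  bad@version <- "unknown"
  expect_true(any(grepl("version", validateRegin(bad)$warnings)))

  # self-loops are info-level only
  nd2 <- data.frame(nodeId = "A", stringsAsFactors = FALSE)
  nd2$identifiers <- I(list(c(ensembl = "E")))
  loopy <- regIN("l", nd2, data.frame(sourceId = "A", targetId = "A",
                                      stringsAsFactors = FALSE),
                 database = "d", version = "1", organism = "o",
                 interactionType = "t")
  rep <- validateRegin(loopy)
  expect_true(rep$ok)
  expect_true(any(grepl("self-loop", rep$info)))
})

test_that("schemas load from YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "sourceIds:",
    "  miRBase-accession: mirna_acc",
    "targetIds:",
    "  ensembl: gene_ens",
    "  ncbigene: gene_entrez",
    "sourceLabel: mirna",
    "targetLabel: gene",
    "sourceBiotype: microRNA",
    "targetBiotype: gene",
    "edgeAttrs: pmid",
    "database: synthDB",
    "version: '1.0'",
    "organism: synthetic",
    "interactionType: validated MTI"), p)
  sch <- schemaFromFile(p)
  expect_identical(unname(sch@sourceIds), "mirna_acc")
  expect_identical(names(sch@targetIds), c("ensembl", "ncbigene"))
  expect_identical(sch@interactionType, "validated MTI")
})
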