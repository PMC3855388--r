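test_that("minimal and malformed XGMML files are handled", {
  p <- withr::local_tempfile(fileext = ".xgmml")
  writeLines('<graph label="g"/>', p)
  doc <- readXgmml(p)
  expect_length(doc@nodes, 0L)
  expect_length(doc@edges, 0L)
  expect_false(doc@directed)
  expect_identical(doc@label, "g")

  writeLines(c('<graph label="g">',
               '<node id="n1"/><edge source="n1" target="n9"/>',
               '</graph>'), p)
  expect_error(readXgmml(p), "n9")

  writeLines(c('<graph label="g">',
               '<node id="n1"/><node id="n1"/></graph>'), p)
  expect_error(readXgmml(p), "duplicate node id")

  writeLines('<graph><graph/></graph>', p)
  expect_error(readXgmml(p), "one network per file")

  writeLines('<notagraph/>', p)
  expect_error(readXgmml(p), "graph")
})

test_that("the XGMML namespace is accepted on read", {
  p <- withr::local_tempfile(fileext = ".xgmml")
  writeLines(paste0(
    '<graph xmlns="http://www.cs.rpi.edu/XGMML" label="ns" directed="1">',
    '<att name="database" value="db" type="string"/>',
    '<node id="n1" label="N1"/></graph>'), p)
  doc <- readXgmml(p)
  expect_true(doc@directed)
  expect_identical(doc@graphAttrs$database$value, "db")
  expect_identical(doc@nodes[[1]]$id, "n1")
})

test_that("writing is deterministic and list attributes keep their order", {
  doc <- xgmmlDocument(
    label = "g", directed = TRUE,
    nodes = list(list(id = "n1",
                      attrs = list(tags = xgmmlAtt(c("a", "b"), "list")))))
  p1 <- withr::local_tempfile(fileext = ".xgmml")
  p2 <- withr::local_tempfile(fileext = ".xgmml")
  writeXgmml(doc, p1)
  writeXgmml(doc, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- readXgmml(p1)
  expect_identical(back@nodes[[1]]$attrs$tags$value, c("a", "b"))
})

test_that("read(write(D)) == D for randomized documents", {
  set.seed(101)
  p <- withr::local_tempfile(fileext = ".xgmml")
  for (i in 1:30) {
    doc <- randomXgmmlDoc()
    writeXgmml(doc, p)
    expect_docs_equal(readXgmml(p), doc)
  }
})

test_that("a RegIN round-trips through XGMML with provenance intact", {
  nd <- data.frame(nodeId = c("R", "T"), label = c("mir", "gene"),
                   biotype = c("microRNA", "gene"),
                   stringsAsFactors = FALSE)
  nd$identifiers <- I(list(c(`miRBase-accession` = "MIMAT1"),
                           c(ensembl = "E1", ncbigene = "1")))
  nd$extra <- I(list(character(), c(family = "ABC")))
  ia <- data.frame(sourceId = "R", targetId = "T",
                   interactionType = "validated MTI",
                   stringsAsFactors = FALSE)
  ia$evidence <- I(list(list(pmid = c("11", "22"))))
  rg <- regIN("mti", nd, ia, database = "db", version = "2",
              organism = "human", interactionType = "validated MTI")
  p <- withr::local_tempfile(fileext = ".xgmml")
  reginToXgmml(rg, p)
  back <- reginFromXgmml(p, name = "mti")
  expect_identical(reginFingerprint(back), reginFingerprint(rg))
  expect_identical(back@database, "db")
  expect_identical(reginInteractions(back)$evidence[[1]]$pmid,
                   c("11", "22"))
})

test_that("reginFromXgmml enforces direction and merges duplicate edges", {
  doc <- xgmmlDocument(
    label = "r", directed = FALSE,
    nodes = list(list(id = "R", attrs = list(identifiers = xgmmlAtt("x", "list")))))
  expect_error(reginFromXgmml(doc), "directed")

  doc <- xgmmlDocument(
    label = "r", directed = TRUE,
    graphAttrs = list(type = "validated MTI"),
    nodes = list(
      list(id = "R", attrs = list(
        identifiers = xgmmlAtt("miRBase-accession:MIMAT1", "list"))),
      list(id = "T", attrs = list(
        identifiers = xgmmlAtt(c("ensembl:E1", "1"), "list")))),
    edges = list(
      list(source = "R", target = "T",
           attrs = list(pmid = xgmmlAtt("1", "list"))),
      list(source = "R", target = "T",
           attrs = list(pmid = xgmmlAtt("2", "list")))))
  expect_warning(rg <- reginFromXgmml(doc), "duplicate")
  ia <- reginInteractions(rg)
  expect_identical(nrow(ia), 1L)
  expect_identical(ia$interactionType, "validated MTI")
  expect_identical(sort(ia$evidence[[1]]$pmid), c("1", "2"))
  # bare identifier entries get system "unknown"
  tIds <- reginNodes(rg)$identifiers[[2]]
  expect_identical(unname(tIds[names(tIds) == "unknown"]), "1")

  # identifier-less node loads with a warning
  doc2 <- xgmmlDocument(label = "r", directed = TRUE,
                        nodes = list(list(id = "lonely")))
  expect_warning(rg2 <- reginFromXgmml(doc2), "cannot match")
  expect_identical(nrow(reginNodes(rg2)), 1L)
})

test_that("seed networks load from nodelist, SIF and XGMML", {
  p <- withr::local_tempfile(fileext = ".txt")
  # CRLF endings and a UTF-8 BOM must be tolerated
  writeBin(charToRaw("\UFEFFg1\r\ng2\r\ng3\r\ng4\r\n"), p)
  seed <- seedFromFile(p, "nodelist", idAttribute = "id")
  expect_identical(nrow(seedNodes(seed)), 4L)
  expect_identical(nrow(seedEdges(seed)), 0L)
  expect_identical(seedNodes(seed)$nodeId[1], "g1")

  writeLines(c("A pp B", "C"), p)
  seed <- seedFromFile(p, "sif")
  expect_identical(nrow(seedNodes(seed)), 3L)
  ed <- seedEdges(seed)
  expect_identical(nrow(ed), 1L)
  expect_identical(ed$attrs[[1]]$interaction, "pp")

  writeLines(character(), p)
  expect_warning(empty <- seedFromFile(p, "nodelist"), "empty")
  expect_identical(nrow(seedNodes(empty)), 0L)

  expect_error(seedFromFile(p, "graphml"), "arg")
})

test_that("a seed whose id attribute is absent everywhere extends to nothing", {
  p <- withr::local_tempfile(fileext = ".xgmml")
  writeLines(c('<graph label="s" directed="0">',
               '<node id="a" label="A">',
               '<att name="symbol" value="ABC" type="string"/>',
               '</node></graph>'), p)
  expect_warning(seed <- seedFromFile(p, "xgmml", idAttribute = "entrez"),
                 "missing from every seed node")
  nd <- data.frame(nodeId = "N", stringsAsFactors = FALSE)
  nd$identifiers <- I(list(c(ensembl = "ABC")))
  ia <- data.frame(sourceId = "N", targetId = "N",
                   stringsAsFactors = FALSE)
  rg <- regIN("r", nd, ia)
  ext <- suppressWarnings(extendNetwork(seed, list(rg)))
  expect_identical(sum(networkEdges(ext)$origin == "added"), 0L)
})

test_that("an extended network survives the XGMML round trip", {
  set.seed(7)
  inst <- randomInstance()
  ext <- extendNetwork(inst$seed, inst$regins)
  ext <- applyThreshold(setVisibility(ext, reginName(inst$regins[[1]]),
                                      FALSE), 1L)
  p <- withr::local_tempfile(fileext = ".xgmml")
  extendedToXgmml(ext, p)
  back <- extendedFromXgmml(p)
  expect_identical(extractedEdges(back), extractedEdges(ext))
  expect_identical(extractedAddedNodes(back), extractedAddedNodes(ext))
  expect_identical(reginVisibility(back), reginVisibility(ext))
  expect_identical(overlapThreshold(back), overlapThreshold(ext))
  expect_identical(networkEdges(back)$visible, networkEdges(ext)$visible)
  # the embedded seed subgraph is recovered exactly
  expect_identical(seedNodes(back@seed)$nodeId, seedNodes(inst$seed)$nodeId)
  expect_identical(seedEdges(back@seed)$source, seedEdges(inst$seed)$source)
})
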