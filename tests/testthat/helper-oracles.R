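# Independent brute-force oracles used throughout the suite. They read
# package objects only through accessors/slots and reimplement the
# contracts from first principles (double/triple loops, row scans), so
# agreement with the package is a genuine check, not circularity.

oracleCanonical <- function(ids, priority) {
  for (sys in priority) {
    hit <- ids[names(ids) == sys]
    if (length(hit)) return(sort(unname(hit), method = "radix")[1L])
  }
  sort(unname(ids), method = "radix")[1L]
}

# Brute-force one-hop extension: triple loop over RegINs x interactions x
# seed nodes. Returns sorted edge keys "regin<TAB>src<TAB>tgt" and sorted
# added node ids, mirroring the endpoint conventions of extendNetwork()
# (seed node ids for matched endpoints, "added:<canonical key>" otherwise).
oracleExtend <- function(seed, regins, direction,
                         priority = defaultSystemPriority()) {
  sn <- seedNodes(seed)
  idAttr <- idAttribute(seed)
  seedVals <- lapply(sn$attrs, function(a) {
    v <- a[[idAttr]]
    if (is.null(v)) character() else as.character(v)
  })
  edges <- character()
  addedNodes <- character()
  for (rg in regins) {
    rn <- reginName(rg)
    nd <- reginNodes(rg)
    ia <- reginInteractions(rg)
    # seed node x regin node double loop
    matches <- vector("list", nrow(nd))
    names(matches) <- nd$nodeId
    for (j in seq_len(nrow(nd))) {
      vals <- unname(nd$identifiers[[j]])
      hits <- character()
      for (i in seq_len(nrow(sn))) {
        if (any(seedVals[[i]] %in% vals)) hits <- c(hits, sn$nodeId[i])
      }
      matches[[j]] <- hits
    }
    addedKey <- function(j) {
      ids <- nd$identifiers[[j]]
      if (!length(ids)) {
        paste0("added:noid:", rn, ":", nd$nodeId[j])
      } else {
        paste0("added:", oracleCanonical(ids, priority))
      }
    }
    reginEdges <- character()
    for (k in seq_len(nrow(ia))) {
      js <- match(ia$sourceId[k], nd$nodeId)
      jt <- match(ia$targetId[k], nd$nodeId)
      srcSeed <- matches[[js]]
      tgtSeed <- matches[[jt]]
      ok <- switch(direction,
        targets = length(srcSeed) > 0L,
        regulators = length(tgtSeed) > 0L,
        both = length(srcSeed) > 0L || length(tgtSeed) > 0L)
      if (!ok) next
      srcEnds <- if (length(srcSeed)) srcSeed else addedKey(js)
      tgtEnds <- if (length(tgtSeed)) tgtSeed else addedKey(jt)
      for (s in srcEnds) for (t in tgtEnds) {
        reginEdges <- c(reginEdges, paste(rn, s, t, sep = "\t"))
        for (endp in c(s, t)) {
          if (startsWith(endp, "added:")) addedNodes <- c(addedNodes, endp)
        }
      }
    }
    edges <- c(edges, unique(reginEdges))
  }
  list(edges = sort(edges), addedNodes = sort(unique(addedNodes)))
}

extractedEdges <- function(ext) {
  ed <- networkEdges(ext)
  ed <- ed[ed$origin == "added", , drop = FALSE]
  sort(paste(ed$regin, ed$source, ed$target, sep = "\t"))
}

extractedAddedNodes <- function(ext) {
  nd <- networkNodes(ext)
  sort(nd$nodeId[nd$origin == "added"])
}

# Brute-force grouping of added edges into (pair -> supporting RegINs).
oracleSupport <- function(ext, shownOnly = FALSE) {
  ed <- networkEdges(ext)
  ed <- ed[ed$origin == "added", , drop = FALSE]
  if (shownOnly) {
    vis <- reginVisibility(ext)
    ed <- ed[vis[ed$regin], , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(ed))) {
    k <- paste(ed$source[i], ed$target[i], sep = "\t")
    out[[k]] <- sort(unique(c(out[[k]], ed$regin[i])))
  }
  out
}

# Row-scan translation oracle.
oracleTranslate <- function(value, from, to, tab) {
  systems <- mappingSystems(tab)
  rows <- tab@rows
  hits <- character()
  for (i in seq_len(nrow(rows))) {
    if (nzchar(rows[i, match(from, systems)]) &&
        rows[i, match(from, systems)] == value) {
      v <- rows[i, match(to, systems)]
      if (nzchar(v)) hits <- c(hits, v)
    }
  }
  sort(unique(hits), method = "radix")
}

# Random adversarial instance: small molecule universe with a shared value
# pool, so ambiguous identifiers, multi-matches, cross-RegIN node merging,
# seed-seed interactions and self-loops all arise naturally.
randomInstance <- function(maxSeed = 12L, maxRegins = 4L, maxInt = 30L,
                           maxNodes = 15L, poolSize = 25L,
                           pIdless = 0.05) {
  systems <- c("ensembl", "ncbigene", "uniprot", "unknown")
  pool <- sprintf("V%03d", seq_len(poolSize))
  nSeed <- sample(0:maxSeed, 1L)
  sn <- data.frame(nodeId = sprintf("s%02d", seq_len(nSeed)),
                   stringsAsFactors = FALSE)
  sn$attrs <- I(lapply(seq_len(nSeed), function(i) {
    if (stats::runif(1L) < 0.1) return(list(label = "unmatched"))
    list(id = sample(pool, sample(1:2, 1L)))
  }))
  seed <- seedNetwork(sn, idAttribute = "id")
  nRegins <- sample(1:maxRegins, 1L)
  regins <- lapply(seq_len(nRegins), function(r) {
    nNodes <- sample(2:maxNodes, 1L)
    nd <- data.frame(nodeId = sprintf("n%02d", seq_len(nNodes)),
                     stringsAsFactors = FALSE)
    nd$identifiers <- I(lapply(seq_len(nNodes), function(j) {
      if (stats::runif(1L) < pIdless) return(character())
      k <- sample(1:3, 1L)
      stats::setNames(sample(pool, k),
                      sample(systems, k, replace = TRUE))
    }))
    nInt <- sample(0:maxInt, 1L)
    ia <- data.frame(
      sourceId = sprintf("n%02d", sample(nNodes, nInt, replace = TRUE)),
      targetId = sprintf("n%02d", sample(nNodes, nInt, replace = TRUE)),
      stringsAsFactors = FALSE)
    ia$evidence <- I(lapply(seq_len(nInt), function(k) {
      list(pmid = as.character(sample(99999L, 1L)))
    }))
    suppressWarnings(regIN(sprintf("regin%02d", r), nd, ia,
                           database = sprintf("db%02d", r),
                           version = "1", organism = "synthetic",
                           interactionType = "predicted MTI"))
  })
  list(seed = seed, regins = regins)
}

# Random XGMML document with typed and list attributes and parallel edges.
randomXgmmlDoc <- function() {
  nNodes <- sample(0:8, 1L)
  nodes <- lapply(seq_len(nNodes), function(i) {
    attrs <- list()
    if (stats::runif(1L) < 0.7) {
      attrs$score <- xgmmlAtt(round(stats::runif(1L), 3))
    }
    if (stats::runif(1L) < 0.5) {
      attrs$count <- xgmmlAtt(sample(100L, 1L))
    }
    if (stats::runif(1L) < 0.6) {
      attrs$tags <- xgmmlAtt(
        sprintf("tag%d", sample(9L, sample(0:4, 1L))), "list")
    }
    list(id = sprintf("n%d", i), label = sprintf("node %d", i),
         attrs = attrs)
  })
  nEdges <- if (nNodes) sample(0:12, 1L) else 0L
  edges <- lapply(seq_len(nEdges), function(i) {
    attrs <- list(weight = xgmmlAtt(stats::runif(1L)))
    if (stats::runif(1L) < 0.5) {
      attrs$provenance <- xgmmlAtt(sprintf("db%d", sample(3L, 1L)))
    }
    list(source = sprintf("n%d", sample(nNodes, 1L)),
         target = sprintf("n%d", sample(nNodes, 1L)), attrs = attrs)
  })
  xgmmlDocument(label = sprintf("g%d", sample(999L, 1L)),
                directed = stats::runif(1L) < 0.5,
                graphAttrs = list(database = xgmmlAtt("synthetic"),
                                  version = xgmmlAtt("1.0")),
                nodes = nodes, edges = edges)
}

# Equality up to attribute ordering.
normaliseDoc <- function(doc) {
  sortAtts <- function(a) {
    if (!length(a)) return(list())
    a[sort(names(a), method = "radix")]
  }
  list(label = doc@label, directed = doc@directed,
       graphAttrs = sortAtts(doc@graphAttrs),
       nodes = lapply(doc@nodes, function(n) {
         list(id = n$id, label = n$label, attrs = sortAtts(n$attrs))
       }),
       edges = lapply(doc@edges, function(e) {
         list(source = e$source, target = e$target,
              attrs = sortAtts(e$attrs))
       }))
}

expect_docs_equal <- function(a, b) {
  expect_identical(normaliseDoc(a), normaliseDoc(b))
}

# Node/interaction set fingerprint of a RegIN (order-insensitive).
reginFingerprint <- function(rg) {
  nd <- reginNodes(rg)
  ia <- reginInteractions(rg)
  nodes <- sort(vapply(seq_len(nrow(nd)), function(i) {
    ids <- nd$identifiers[[i]]
    paste(nd$nodeId[i],
          paste(sort(paste(names(ids), ids, sep = ":")), collapse = ","),
          sep = "|")
  }, ""))
  edges <- sort(paste(ia$sourceId, ia$targetId, sep = "->"))
  list(nodes = nodes, edges = edges)
}
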