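## One-hop network extension: match seed nodes against RegIN nodes by exact
## identifier equality, then graft every qualifying regulator->target
## interaction onto the seed, one provenance-tagged edge per RegIN.

# Fixed palette cycled over RegINs; written as a plain edge attribute only.
.REGIN_COLOURS <- c("orange", "blue", "red", "purple", "green", "brown",
                    "magenta", "cyan", "olive", "navy")

#' Index a RegIN by identifier value
#'
#' Maps every identifier value of every node to the node ids carrying it,
#' giving expected O(1) matching lookups during extension.
#'
#' @param regin A [RegIN-class].
#' @return Named list: identifier value -> character vector of node ids.
#'   Values carried by more than one node (ambiguous values) are kept with
#'   all their node ids.
#' @export
indexRegin <- function(regin) {
  stopifnot(is(regin, "RegIN"))
  env <- new.env(hash = TRUE, parent = emptyenv())
  nd <- regin@nodes
  for (i in seq_len(nrow(nd))) {
    vals <- unique(unname(nd$identifiers[[i]]))
    for (v in vals) {
      env[[v]] <- c(env[[v]], nd$nodeId[i])
    }
  }
  as.list(env, sorted = TRUE)
}

.seedIdValues <- function(seed, idAttribute) {
  lapply(seed@nodes$attrs, function(a) {
    v <- a[[idAttribute]]
    if (is.null(v)) character() else as.character(v)
  })
}

#' Match seed nodes against a RegIN
#'
#' A seed node matches a RegIN node iff any of its id-attribute values
#' equals (exact, case-sensitive) any identifier value of the RegIN node.
#' Seed nodes lacking the attribute match nothing.
#'
#' @param seed A [SeedNetwork-class].
#' @param regin A [RegIN-class].
#' @param idAttribute Node attribute holding the seed identifiers; defaults
#'   to the seed's own id attribute.
#' @return Named list: seed node id -> character vector of matching RegIN
#'   node ids (empty entries omitted).
#' @export
matchSeed <- function(seed, regin, idAttribute = NULL) {
  stopifnot(is(seed, "SeedNetwork"), is(regin, "RegIN"))
  if (is.null(idAttribute)) idAttribute <- seed@idAttribute
  idx <- list2env(indexRegin(regin), hash = TRUE, parent = emptyenv())
  vals <- .seedIdValues(seed, idAttribute)
  out <- list()
  for (i in seq_along(vals)) {
    hits <- character()
    for (v in vals[[i]]) {
      h <- idx[[v]]
      if (!is.null(h)) hits <- c(hits, h)
    }
    hits <- unique(hits)
    if (length(hits)) out[[seed@nodes$nodeId[i]]] <- hits
  }
  out
}

.hasProvenanceAttrs <- function(seed) {
  nodeHit <- any(vapply(seed@nodes$attrs, function(a) {
    any(c("origin", "styleHint") %in% names(a))
  }, NA))
  edgeHit <- nrow(seed@edges) > 0L && any(vapply(seed@edges$attrs,
    function(a) any(c("origin", "sourceRegin") %in% names(a)), NA))
  isTRUE(nodeHit) || isTRUE(edgeHit)
}

#' Extend a seed network with regulatory interactions
#'
#' The core one-hop extension: for every RegIN, every regulator->target
#' interaction in which a seed node participates on the requested side is
#' grafted onto the network. \code{direction = "targets"} keeps
#' interactions whose regulator is in the seed (adding its targets);
#' \code{"regulators"} keeps interactions that target a seed node (adding
#' its regulators); \code{"both"} (default) keeps either. Each qualifying
#' interaction contributes exactly one edge tagged with its RegIN's name,
#' so an interaction supported by k RegINs appears as k parallel edges.
#' Non-matching endpoints become added nodes, merged across RegINs by
#' canonical key (or by any shared identifier with
#' \code{mergeBy = "any-shared-id"}). Added nodes are never re-queried:
#' extension is strictly one hop. The seed subgraph is kept unchanged.
#'
#' Seed inputs that already carry this package's provenance attributes
#' (\code{origin}, \code{styleHint}, \code{sourceRegin}) are refused to
#' prevent double-grafting and inflated support counts; re-extend from the
#' original seed, or export the extended network and strip the attributes,
#' if transitive extension is wanted.
#'
#' When one RegIN endpoint matches several seed nodes the interaction is
#' attached to every matching seed node; when a seed node matches several
#' RegIN nodes the union of their interactions is taken. Both situations
#' produce an ambiguity diagnostic. Within one RegIN, interactions that
#' resolve to the same (source, target) node pair are collapsed into one
#' edge with evidence merged, so every RegIN contributes at most one edge
#' per pair. Self-loops (autoregulation) are kept and flagged.
#'
#' @param seed A [SeedNetwork-class].
#' @param regins A list of [RegIN-class] objects (or a single RegIN) with
#'   pairwise distinct names.
#' @param direction "both", "targets" or "regulators".
#' @param idAttribute Seed attribute used for matching; defaults to the
#'   seed's own.
#' @param priority Identifier-system priority for canonical keys.
#' @param mergeBy "canonical" (default): added nodes merge when their
#'   canonical keys are equal; "any-shared-id": added nodes merge whenever
#'   their identifier sets intersect (transitively).
#' @return An [ExtendedNetwork-class]; its [linkReport()] holds per-RegIN
#'   counts and diagnostics.
#' @examples
#' seed <- seedNetwork("G1", idAttribute = "ensembl")
#' nodes <- data.frame(nodeId = c("M1", "G1"), stringsAsFactors = FALSE)
#' nodes$identifiers <- I(list(c(`miRBase-accession` = "MIMAT1"),
#'                             c(ensembl = "G1")))
#' rg <- regIN("mti", nodes,
#'             data.frame(sourceId = "M1", targetId = "G1"))
#' ext <- extendNetwork(seed, list(rg), direction = "regulators")
#' perReginCounts(ext)
#' @export
extendNetwork <- function(seed, regins,
                          direction = c("both", "targets", "regulators"),
                          idAttribute = NULL,
                          priority = defaultSystemPriority(),
                          mergeBy = c("canonical", "any-shared-id")) {
  stopifnot(is(seed, "SeedNetwork"))
  direction <- match.arg(direction)
  mergeBy <- match.arg(mergeBy)
  if (is(regins, "RegIN")) regins <- list(regins)
  stopifnot(all(vapply(regins, is, NA, "RegIN")))
  rnames <- vapply(regins, reginName, "")
  if (anyDuplicated(rnames)) {
    stop("RegIN names must be pairwise distinct: ",
         paste(unique(rnames[duplicated(rnames)]), collapse = ", "))
  }
  if (.hasProvenanceAttrs(seed)) {
    stop("seed network already carries extension provenance attributes ",
         "(origin/styleHint/sourceRegin); refusing to extend it again")
  }
  if (is.null(idAttribute)) idAttribute <- seed@idAttribute
  diag <- character()

  seedIds <- .seedIdValues(seed, idAttribute)
  if (nrow(seed@nodes) && !any(lengths(seedIds) > 0L)) {
    warning(sprintf(
      "id attribute '%s' missing from every seed node; nothing to match",
      idAttribute))
  }

  ## pass 1: per-RegIN matches and qualifying interactions
  qual <- vector("list", length(regins))     # per regin: list of resolved ia
  addedOcc <- list()                         # occurrences of unmatched nodes
  for (r in seq_along(regins)) {
    rg <- regins[[r]]
    idx <- list2env(indexRegin(rg), hash = TRUE, parent = emptyenv())
    # ambiguous identifier values inside the RegIN
    multi <- names(Filter(function(v) length(v) > 1L, indexRegin(rg)))
    if (length(multi)) {
      diag <- c(diag, sprintf(
        "RegIN '%s': identifier value(s) shared by several nodes: %s",
        rnames[r], paste(multi, collapse = ", ")))
    }
    # invert matching: regin node id -> seed node ids, seed order preserved
    rmatch <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(nrow(seed@nodes))) {
      hits <- character()
      for (v in seedIds[[i]]) {
        h <- idx[[v]]
        if (!is.null(h)) hits <- c(hits, h)
      }
      hits <- unique(hits)
      if (length(hits) > 1L) {
        diag <- c(diag, sprintf(
          "seed node '%s' matches %d nodes of RegIN '%s'; union taken",
          seed@nodes$nodeId[i], length(hits), rnames[r]))
      }
      for (h in hits) {
        rmatch[[h]] <- c(rmatch[[h]], seed@nodes$nodeId[i])
      }
    }
    ia <- rg@interactions
    nodeRow <- stats::setNames(seq_len(nrow(rg@nodes)), rg@nodes$nodeId)
    rows <- list()
    for (j in seq_len(nrow(ia))) {
      srcSeed <- rmatch[[ia$sourceId[j]]]
      tgtSeed <- rmatch[[ia$targetId[j]]]
      ok <- switch(direction,
        targets = length(srcSeed) > 0L,
        regulators = length(tgtSeed) > 0L,
        both = length(srcSeed) > 0L || length(tgtSeed) > 0L)
      if (!ok) next
      if (!length(srcSeed)) {
        k <- nodeRow[[ia$sourceId[j]]]
        addedOcc[[length(addedOcc) + 1L]] <- list(
          regin = r, nodeId = ia$sourceId[j],
          label = rg@nodes$label[k], biotype = rg@nodes$biotype[k],
          identifiers = rg@nodes$identifiers[[k]])
      }
      if (!length(tgtSeed)) {
        k <- nodeRow[[ia$targetId[j]]]
        addedOcc[[length(addedOcc) + 1L]] <- list(
          regin = r, nodeId = ia$targetId[j],
          label = rg@nodes$label[k], biotype = rg@nodes$biotype[k],
          identifiers = rg@nodes$identifiers[[k]])
      }
      rows[[length(rows) + 1L]] <- list(
        row = j, srcSeed = srcSeed, tgtSeed = tgtSeed)
    }
    qual[[r]] <- rows
  }

  ## group unmatched endpoints into added nodes
  groupOf <- character()  # "regin\rnodeId" -> added node id
  addedNodes <- list()    # added node id -> list(label, biotype, ids, regin)
  if (length(addedOcc)) {
    if (mergeBy == "canonical") {
      for (occ in addedOcc) {
        occKey <- paste(occ$regin, occ$nodeId, sep = "\r")
        if (occKey %in% names(groupOf)) next
        # identifier-less endpoints get a per-RegIN key: nothing to merge on
        key <- if (length(occ$identifiers)) {
          canonicalKey(occ$identifiers, priority)
        } else {
          diag <- c(diag, sprintf(
            "node '%s' of RegIN '%s' has no identifiers; kept unmerged",
            occ$nodeId, rnames[occ$regin]))
          paste0("noid:", rnames[occ$regin], ":", occ$nodeId)
        }
        nid <- paste0("added:", key)
        groupOf[occKey] <- nid
        if (is.null(addedNodes[[nid]])) {
          addedNodes[[nid]] <- list(label = occ$label,
                                    biotype = occ$biotype,
                                    identifiers = occ$identifiers,
                                    canonicalKey = key, regin = occ$regin)
        } else {
          merged <- c(addedNodes[[nid]]$identifiers, occ$identifiers)
          addedNodes[[nid]]$identifiers <-
            merged[!duplicated(paste(names(merged), merged, sep = "\r"))]
        }
      }
    } else {
      # union-find over identifier values: occurrences sharing any value
      # (transitively) collapse into one added node
      parent <- seq_along(addedOcc)
      findRoot <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
      }
      byValue <- new.env(hash = TRUE, parent = emptyenv())
      for (i in seq_along(addedOcc)) {
        for (v in unname(addedOcc[[i]]$identifiers)) {
          j <- byValue[[v]]
          if (is.null(j)) byValue[[v]] <- i
          else {
            ri <- findRoot(i); rj <- findRoot(j)
            if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
          }
        }
      }
      roots <- vapply(seq_along(addedOcc), findRoot, 0L)
      for (g in unique(roots)) {
        members <- addedOcc[roots == g]
        ids <- unlist(lapply(members, `[[`, "identifiers"))
        ids <- ids[!duplicated(paste(names(ids), ids, sep = "\r"))]
        key <- if (length(ids)) canonicalKey(ids, priority) else {
          paste0("noid:", rnames[members[[1L]]$regin], ":",
                 members[[1L]]$nodeId)
        }
        nid <- paste0("added:", key)
        addedNodes[[nid]] <- list(label = members[[1L]]$label,
                                  biotype = members[[1L]]$biotype,
                                  identifiers = ids, canonicalKey = key,
                                  regin = members[[1L]]$regin)
        for (occ in members) {
          groupOf[paste(occ$regin, occ$nodeId, sep = "\r")] <- nid
        }
      }
    }
    # avoid clashing with a seed node id (pathological but possible)
    clash <- names(addedNodes) %in% seed@nodes$nodeId
    if (any(clash)) {
      for (nid in names(addedNodes)[clash]) {
        nid2 <- paste0(nid, "#added")
        addedNodes[[nid2]] <- addedNodes[[nid]]
        addedNodes[[nid]] <- NULL
        groupOf[groupOf == nid] <- nid2
      }
    }
  }

  ## pass 2: materialise edges, one per RegIN per resolved pair
  edgeRows <- list()
  edgeKeyIdx <- new.env(hash = TRUE, parent = emptyenv())
  firstSeenNode <- character()   # added node id -> regin name attribution
  for (r in seq_along(regins)) {
    rg <- regins[[r]]
    ia <- rg@interactions
    colour <- .REGIN_COLOURS[(r - 1L) %% length(.REGIN_COLOURS) + 1L]
    for (q in qual[[r]]) {
      j <- q$row
      srcEnds <- if (length(q$srcSeed)) q$srcSeed else
        unname(groupOf[paste(r, ia$sourceId[j], sep = "\r")])
      tgtEnds <- if (length(q$tgtSeed)) q$tgtSeed else
        unname(groupOf[paste(r, ia$targetId[j], sep = "\r")])
      for (s in srcEnds) for (t in tgtEnds) {
        for (endp in c(s, t)) {
          if (startsWith(endp, "added:") && is.na(firstSeenNode[endp])) {
            firstSeenNode[endp] <- rnames[r]
          }
        }
        if (s == t) {
          diag <- c(diag, sprintf(
            "self-loop on '%s' from RegIN '%s'", s, rnames[r]))
        }
        key <- paste(rnames[r], s, t, sep = "\r")
        prev <- edgeKeyIdx[[key]]
        if (!is.null(prev)) {
          ev <- edgeRows[[prev]]$evidence
          for (nm in names(ia$evidence[[j]])) {
            ev[[nm]] <- unique(c(ev[[nm]], ia$evidence[[j]][[nm]]))
          }
          edgeRows[[prev]]$evidence <- ev
          diag <- c(diag, sprintf(
            "RegIN '%s': interactions collapsing onto pair %s -> %s merged",
            rnames[r], s, t))
        } else {
          edgeRows[[length(edgeRows) + 1L]] <- list(
            source = s, target = t, regin = rnames[r],
            interactionType = ia$interactionType[j], colour = colour,
            evidence = ia$evidence[[j]])
          edgeKeyIdx[[key]] <- length(edgeRows)
        }
      }
    }
  }

  ## assemble node/edge tables: seed first, added in first-appearance order
  usedIds <- unique(unlist(lapply(edgeRows, function(e) c(e$source, e$target))))
  addedIds <- names(addedNodes)[names(addedNodes) %in% usedIds]
  # order added nodes by first appearance in the edge list
  if (length(addedIds)) {
    firstPos <- vapply(addedIds, function(nid) {
      for (i in seq_along(edgeRows)) {
        if (edgeRows[[i]]$source == nid || edgeRows[[i]]$target == nid) {
          return(i)
        }
      }
      NA_integer_
    }, 0L)
    addedIds <- addedIds[order(firstPos)]
  }

  sn <- seed@nodes
  nd <- data.frame(
    nodeId = c(sn$nodeId, addedIds),
    label = c(vapply(seq_len(nrow(sn)), function(i) {
      lb <- sn$attrs[[i]]$label
      if (is.null(lb)) sn$nodeId[i] else as.character(lb)[1L]
    }, ""), vapply(addedIds, function(nid) addedNodes[[nid]]$label, "")),
    origin = c(rep("initial", nrow(sn)), rep("added", length(addedIds))),
    styleHint = c(rep("grey circle", nrow(sn)),
                  rep("pink hexagon", length(addedIds))),
    canonicalKey = c(rep(NA_character_, nrow(sn)),
                     vapply(addedIds, function(nid) {
                       addedNodes[[nid]]$canonicalKey
                     }, "")),
    stringsAsFactors = FALSE)
  nd$attrs <- I(c(sn$attrs, lapply(addedIds, function(nid) {
    an <- addedNodes[[nid]]
    list(identifiers = paste(names(an$identifiers), an$identifiers,
                             sep = ":"),
         biotype = an$biotype)
  })))
  nd$visible <- rep(TRUE, nrow(nd))

  se <- seed@edges
  ed <- data.frame(
    source = c(se$source, vapply(edgeRows, `[[`, "", "source")),
    target = c(se$target, vapply(edgeRows, `[[`, "", "target")),
    origin = c(rep("initial", nrow(se)), rep("added", length(edgeRows))),
    regin = c(rep(NA_character_, nrow(se)),
              vapply(edgeRows, `[[`, "", "regin")),
    interactionType = c(rep(NA_character_, nrow(se)),
                        vapply(edgeRows, `[[`, "", "interactionType")),
    colour = c(rep(NA_character_, nrow(se)),
               vapply(edgeRows, `[[`, "", "colour")),
    stringsAsFactors = FALSE)
  ed$evidence <- I(c(rep(list(list()), nrow(se)),
                     lapply(edgeRows, `[[`, "evidence")))
  ed$attrs <- I(c(se$attrs, rep(list(list()), length(edgeRows))))
  ed$visible <- rep(TRUE, nrow(ed))
  rownames(nd) <- NULL
  rownames(ed) <- NULL

  vis <- stats::setNames(rep(TRUE, length(regins)), rnames)
  perRegin <- data.frame(
    regin = rnames,
    addedInteractions = vapply(rnames, function(rn) {
      sum(ed$origin == "added" & ed$regin == rn)
    }, 0L),
    addedNodes = vapply(rnames, function(rn) {
      sum(firstSeenNode[addedIds] == rn)
    }, 0L),
    matchedSeedNodes = vapply(rnames, function(rn) {
      mine <- ed$origin == "added" & ed$regin == rn
      length(intersect(unique(c(ed$source[mine], ed$target[mine])),
                       sn$nodeId))
    }, 0L),
    stringsAsFactors = FALSE)
  rownames(perRegin) <- NULL
  report <- new("LinkReport", perRegin = perRegin, diagnostics = diag)
  new("ExtendedNetwork", seed = seed, nodes = nd, edges = ed,
      visibility = vis, threshold = 1L, supportOver = "shown",
      report = report)
}

# Recount per-RegIN statistics from the node/edge tables (used both by
# linkStats() and when rebuilding an extended network from XGMML).
linkStatsFromEdges <- function(nodes, edges, visibility) {
  rnames <- names(visibility)
  added <- edges[edges$origin == "added", , drop = FALSE]
  seedIds <- nodes$nodeId[nodes$origin == "initial"]
  firstSeen <- character()
  for (i in seq_len(nrow(added))) {
    for (endp in c(added$source[i], added$target[i])) {
      if (!endp %in% seedIds && is.na(firstSeen[endp])) {
        firstSeen[endp] <- added$regin[i]
      }
    }
  }
  perRegin <- data.frame(
    regin = rnames,
    addedInteractions = vapply(rnames, function(rn) {
      sum(added$regin == rn)
    }, 0L),
    addedNodes = vapply(rnames, function(rn) {
      sum(firstSeen == rn)
    }, 0L),
    matchedSeedNodes = vapply(rnames, function(rn) {
      mine <- added$regin == rn
      length(intersect(unique(c(added$source[mine], added$target[mine])),
                       seedIds))
    }, 0L),
    stringsAsFactors = FALSE)
  rownames(perRegin) <- NULL
  new("LinkReport", perRegin = perRegin, diagnostics = character())
}

#' Recount extension statistics from an extended network
#'
#' Recomputes the per-RegIN counts by a full scan of the graph, so the sum
#' of \code{addedInteractions} always equals the number of added parallel
#' edges. Added nodes are attributed to the RegIN of their first incident
#' added edge; \code{matchedSeedNodes} counts distinct seed nodes incident
#' to that RegIN's edges.
#'
#' @param extended An [ExtendedNetwork-class].
#' @return A [LinkReport-class] (diagnostics from the original run are
#'   carried over).
#' @export
linkStats <- function(extended) {
  stopifnot(is(extended, "ExtendedNetwork"))
  rep <- linkStatsFromEdges(extended@nodes, extended@edges,
                            extended@visibility)
  rep@diagnostics <- extended@report@diagnostics
  rep
}
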