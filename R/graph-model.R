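#' Default identifier-system priority
#'
#' Order in which identifier systems are tried when deriving a canonical
#' key: Ensembl gene ids for genes/proteins, miRBase accessions for miRNAs
#' and DrugBank ids for drugs come first, mirroring the per-biotype
#' unifying systems RegIN collections conventionally use; secondary systems
#' follow.
#'
#' @return Character vector of system names, highest priority first.
#' @export
defaultSystemPriority <- function() {
  c("ensembl", "miRBase-accession", "drugbank", "ncbigene", "uniprot",
    "miRBase-id")
}

.normIdentifiers <- function(ids) {
  nms <- names(ids)
  ids <- as.character(ids)  # as.character() drops names; restore them
  if (is.null(nms)) nms <- rep("unknown", length(ids))
  nms[is.na(nms) | nms == ""] <- "unknown"
  names(ids) <- nms
  ids[!is.na(ids) & nzchar(ids)]
}

#' Canonical key of a node's identifier set
#'
#' The single identifier that defines node identity when added nodes are
#' merged across RegINs: the value of the first identifier whose system
#' appears earliest in \code{priority}; if none of the node's systems is in
#' the priority list, the lexicographically smallest identifier value.
#' Comparison is exact and case-sensitive; ties within one system are
#' broken by lexicographic order, so the key is deterministic.
#'
#' @param identifiers Named character vector: names are identifier systems
#'   ("unknown" allowed), values are identifiers.
#' @param priority Ordered character vector of system names; defaults to
#'   [defaultSystemPriority()].
#' @return A single identifier string.
#' @examples
#' canonicalKey(c(ensembl = "ENSG01", ncbigene = "111"))
#' canonicalKey(c(ncbigene = "111"))
#' canonicalKey(c(unknown = "b", unknown = "a"))
#' @export
canonicalKey <- function(identifiers, priority = defaultSystemPriority()) {
  ids <- .normIdentifiers(identifiers)
  if (!length(ids)) stop("no identifiers")
  for (sys in priority) {
    hit <- ids[names(ids) == sys]
    if (length(hit)) return(min(hit))
  }
  # C-locale sort keeps the lexicographic minimum locale-independent
  sort(unname(ids), method = "radix")[1L]
}

#' Construct a RegIN
#'
#' Low-level constructor; most users obtain RegINs from
#' [reginFromXgmml()], [buildRegin()] or [generateFixture()]. Nodes and
#' interactions are given as data.frames in the slot layout documented in
#' [RegIN-class]; convenience coercions fill in missing optional columns.
#'
#' @param name RegIN name, unique within a collection.
#' @param nodes data.frame with at least \code{nodeId} and
#'   \code{identifiers}; \code{label} defaults to the node id,
#'   \code{biotype} to "other".
#' @param interactions data.frame with at least \code{sourceId} and
#'   \code{targetId}; duplicate (source, target) pairs are collapsed with
#'   evidence merged.
#' @param database,version,organism,interactionType Metadata strings;
#'   default "unknown".
#' @return A [RegIN-class] object.
#' @export
regIN <- function(name, nodes = .emptyNodes(),
                  interactions = .emptyInteractions(),
                  database = "unknown", version = "unknown",
                  organism = "unknown", interactionType = "unknown") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!nrow(nodes)) nodes <- .emptyNodes()
  if (is.null(nodes$label)) nodes$label <- nodes$nodeId
  if (is.null(nodes$biotype)) nodes$biotype <- rep("other", nrow(nodes))
  if (is.null(nodes$identifiers)) nodes$identifiers <- I(rep(list(character()), nrow(nodes)))
  if (is.null(nodes$extra)) nodes$extra <- I(rep(list(character()), nrow(nodes)))
  nodes$identifiers <- I(lapply(nodes$identifiers, .normIdentifiers))
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  if (!nrow(interactions)) interactions <- .emptyInteractions()
  if (is.null(interactions$interactionType)) {
    interactions$interactionType <- rep(interactionType, nrow(interactions))
  }
  if (is.null(interactions$evidence)) {
    interactions$evidence <- I(rep(list(list()), nrow(interactions)))
  }
  dd <- .dedupInteractions(interactions)
  rownames(nodes) <- NULL
  new("RegIN", name = name, database = database, version = version,
      organism = organism, interactionType = interactionType,
      nodes = nodes, interactions = dd$interactions)
}

# Collapse duplicate (sourceId, targetId) pairs, concatenating evidence
# values per key; returns the interactions plus how many rows were merged.
.dedupInteractions <- function(ia) {
  if (!nrow(ia)) return(list(interactions = ia, nDuplicates = 0L))
  key <- paste(ia$sourceId, ia$targetId, sep = "\r")
  first <- !duplicated(key)
  nDup <- sum(!first)
  if (nDup > 0L) {
    keep <- which(first)
    merged <- lapply(keep, function(i) {
      grp <- which(key == key[i])
      ev <- list()
      for (j in grp) {
        for (k in names(ia$evidence[[j]])) {
          ev[[k]] <- unique(c(ev[[k]], ia$evidence[[j]][[k]]))
        }
      }
      ev
    })
    ia <- ia[keep, , drop = FALSE]
    ia$evidence <- I(merged)
  }
  rownames(ia) <- NULL
  list(interactions = ia, nDuplicates = nDup)
}

#' Construct a seed network
#'
#' @param nodes Character vector of node ids, or a data.frame with columns
#'   \code{nodeId} and list-column \code{attrs}.
#' @param edges data.frame with columns \code{source}, \code{target} and
#'   optionally a list-column \code{attrs}; may be omitted.
#' @param idAttribute Name of the node attribute used for matching against
#'   RegINs. When \code{nodes} is a character vector, each node gets this
#'   attribute set to its own id.
#' @param directed Whether the seed edges are directed.
#' @return A [SeedNetwork-class] object.
#' @examples
#' seedNetwork(c("ENSG01", "ENSG02"), idAttribute = "ensembl")
#' @export
seedNetwork <- function(nodes, edges = NULL, idAttribute = "id",
                        directed = FALSE) {
  if (is.character(nodes)) {
    ids <- nodes
    nodes <- data.frame(nodeId = ids, stringsAsFactors = FALSE)
    nodes$attrs <- I(lapply(ids, function(x) {
      a <- list(); a[[idAttribute]] <- x; a
    }))
  } else {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    if (is.null(nodes$attrs)) {
      nodes$attrs <- I(rep(list(list()), nrow(nodes)))
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$attrs)) edges$attrs <- I(rep(list(list()), nrow(edges)))
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  new("SeedNetwork", nodes = nodes, edges = edges,
      idAttribute = idAttribute, directed = directed)
}

## ---- accessors ------------------------------------------------------------

#' @rdname accessors
#' @param object A RegLinker object.
#' @export
setGeneric("reginName", function(object) standardGeneric("reginName"))
#' @rdname accessors
#' @export
setGeneric("reginNodes", function(object) standardGeneric("reginNodes"))
#' @rdname accessors
#' @export
setGeneric("reginInteractions",
           function(object) standardGeneric("reginInteractions"))
#' @rdname accessors
#' @export
setGeneric("idAttribute", function(object) standardGeneric("idAttribute"))
#' @rdname accessors
#' @export
setGeneric("seedNodes", function(object) standardGeneric("seedNodes"))
#' @rdname accessors
#' @export
setGeneric("seedEdges", function(object) standardGeneric("seedEdges"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("reginVisibility",
           function(object) standardGeneric("reginVisibility"))
#' @rdname accessors
#' @export
setGeneric("overlapThreshold",
           function(object) standardGeneric("overlapThreshold"))
#' @rdname accessors
#' @export
setGeneric("linkReport", function(object) standardGeneric("linkReport"))
#' @rdname accessors
#' @export
setGeneric("perReginCounts",
           function(object) standardGeneric("perReginCounts"))
#' @rdname accessors
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))
#' @rdname accessors
#' @export
setGeneric("mappingSystems",
           function(object) standardGeneric("mappingSystems"))

#' Accessors for RegLinker objects
#'
#' Read-only access to the slots of [RegIN-class], [SeedNetwork-class],
#' [ExtendedNetwork-class], [LinkReport-class] and [MappingTable-class]
#' objects.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("reginName", "RegIN", function(object) object@name)
#' @rdname accessors
#' @export
setMethod("reginNodes", "RegIN", function(object) object@nodes)
#' @rdname accessors
#' @export
setMethod("reginInteractions", "RegIN",
          function(object) object@interactions)
#' @rdname accessors
#' @export
setMethod("idAttribute", "SeedNetwork", function(object) object@idAttribute)
#' @rdname accessors
#' @export
setMethod("seedNodes", "SeedNetwork", function(object) object@nodes)
#' @rdname accessors
#' @export
setMethod("seedEdges", "SeedNetwork", function(object) object@edges)
#' @rdname accessors
#' @export
setMethod("networkNodes", "ExtendedNetwork", function(object) object@nodes)
#' @rdname accessors
#' @export
setMethod("networkEdges", "ExtendedNetwork", function(object) object@edges)
#' @rdname accessors
#' @export
setMethod("reginVisibility", "ExtendedNetwork",
          function(object) object@visibility)
#' @rdname accessors
#' @export
setMethod("overlapThreshold", "ExtendedNetwork",
          function(object) object@threshold)
#' @rdname accessors
#' @export
setMethod("linkReport", "ExtendedNetwork", function(object) object@report)
#' @rdname accessors
#' @export
setMethod("perReginCounts", "LinkReport", function(object) object@perRegin)
#' @rdname accessors
#' @export
setMethod("perReginCounts", "ExtendedNetwork",
          function(object) object@report@perRegin)
#' @rdname accessors
#' @export
setMethod("diagnostics", "LinkReport", function(object) object@diagnostics)
#' @rdname accessors
#' @export
setMethod("diagnostics", "ExtendedNetwork",
          function(object) object@report@diagnostics)
#' @rdname accessors
#' @export
setMethod("mappingSystems", "MappingTable", function(object) object@systems)

## ---- show methods ---------------------------------------------------------

setMethod("show", "RegIN", function(object) {
  cat(sprintf(
    "RegIN '%s' (%s %s, %s, %s)\n  %d nodes, %d interactions\n",
    object@name, object@database, object@version, object@organism,
    object@interactionType, nrow(object@nodes), nrow(object@interactions)))
})

setMethod("show", "SeedNetwork", function(object) {
  cat(sprintf(
    "SeedNetwork: %d nodes, %d edges (%s), id attribute '%s'\n",
    nrow(object@nodes), nrow(object@edges),
    if (object@directed) "directed" else "undirected",
    object@idAttribute))
})

setMethod("show", "ExtendedNetwork", function(object) {
  added <- object@edges$origin == "added"
  cat(sprintf(
    "ExtendedNetwork: %d nodes (%d added), %d edges (%d added)\n",
    nrow(object@nodes), sum(object@nodes$origin == "added"),
    nrow(object@edges), sum(added)))
  cat(sprintf("  RegINs: %s\n", paste(
    sprintf("%s%s", names(object@visibility),
            ifelse(object@visibility, "", " [hidden]")), collapse = ", ")))
  cat(sprintf("  overlap threshold: %d (support over %s RegINs); %d edges visible\n",
              object@threshold, object@supportOver,
              sum(object@edges$visible)))
})

setMethod("show", "LinkReport", function(object) {
  cat("LinkReport\n")
  print(object@perRegin, row.names = FALSE)
  if (length(object@diagnostics)) {
    cat(sprintf("  %d diagnostic(s); first: %s\n",
                length(object@diagnostics), object@diagnostics[1L]))
  }
})

setMethod("show", "MappingTable", function(object) {
  cat(sprintf("MappingTable: %d rows, systems: %s\n",
              nrow(object@rows), paste(object@systems, collapse = ", ")))
})

setMethod("show", "XgmmlDocument", function(object) {
  cat(sprintf("XgmmlDocument '%s': %d nodes, %d edges, %s\n",
              object@label, length(object@nodes), length(object@edges),
              if (object@directed) "directed" else "undirected"))
})
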