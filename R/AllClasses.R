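#' @import methods
NULL

## Identifier sets are plain named character vectors: names are identifier
## systems ("unknown" when the system is not stated), values are the
## identifiers themselves. Comparison is exact and case-sensitive throughout
## the package; see canonicalKey() for the merging rule built on top.

.emptyNodes <- function() {
  data.frame(
    nodeId = character(), label = character(), biotype = character(),
    identifiers = I(list()), extra = I(list()),
    stringsAsFactors = FALSE
  )
}

.emptyInteractions <- function() {
  data.frame(
    sourceId = character(), targetId = character(),
    interactionType = character(), evidence = I(list()),
    stringsAsFactors = FALSE
  )
}

#' RegIN: a regulatory interaction network
#'
#' A RegIN is a named, versioned directed network of regulator-to-target
#' interactions from one source database. Nodes carry one or more
#' identifiers in (possibly several) identifier systems; edges always point
#' from the regulatory component (miRNA, transcription factor, drug) to the
#' target biomolecule.
#'
#' @slot name Unique name of this RegIN within a collection.
#' @slot database,version,organism,interactionType Source metadata.
#' @slot nodes A data.frame with columns \code{nodeId}, \code{label},
#'   \code{biotype} and list-columns \code{identifiers} (named character
#'   vectors, names = identifier systems) and \code{extra}.
#' @slot interactions A data.frame with columns \code{sourceId},
#'   \code{targetId}, \code{interactionType} and list-column
#'   \code{evidence} (each a named list of character vectors, e.g. PMIDs).
#'
#' @seealso [regIN()], [reginFromXgmml()], [buildRegin()], [validateRegin()]
#' @exportClass RegIN
setClass("RegIN", representation(
  name = "character", database = "character", version = "character",
  organism = "character", interactionType = "character",
  nodes = "data.frame", interactions = "data.frame"
))

setValidity("RegIN", function(object) {
  msg <- character()
  nd <- object@nodes
  ia <- object@interactions
  req <- c("nodeId", "label", "biotype", "identifiers", "extra")
  if (!all(req %in% names(nd))) {
    return(paste("nodes must have columns:", paste(req, collapse = ", ")))
  }
  if (!all(c("sourceId", "targetId", "interactionType", "evidence") %in%
           names(ia))) {
    return("interactions must have columns sourceId, targetId, interactionType, evidence")
  }
  if (anyDuplicated(nd$nodeId)) {
    msg <- c(msg, "duplicate nodeId in RegIN nodes")
  }
  dangling <- setdiff(unique(c(ia$sourceId, ia$targetId)), nd$nodeId)
  if (length(dangling)) {
    msg <- c(msg, paste("interaction references undeclared node(s):",
                        paste(dangling, collapse = ", ")))
  }
  if (anyDuplicated(paste(ia$sourceId, ia$targetId, sep = "\r"))) {
    msg <- c(msg, "duplicate (sourceId, targetId) interaction after dedup")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SeedNetwork: the user's initial network
#'
#' The seed (initial) network whose nodes are matched against RegINs. Every
#' node carries a free-form attribute map; \code{idAttribute} names the
#' attribute holding the identifier(s) used for matching (a scalar or, after
#' [expandSeedIds()], a character vector per node).
#'
#' @slot nodes data.frame with column \code{nodeId} and list-column
#'   \code{attrs} (named lists; values are character vectors).
#' @slot edges data.frame with columns \code{source}, \code{target} and
#'   list-column \code{attrs}.
#' @slot idAttribute Name of the node attribute used for matching.
#' @slot directed Whether seed edges are directed.
#'
#' @seealso [seedFromFile()], [extendNetwork()]
#' @exportClass SeedNetwork
setClass("SeedNetwork", representation(
  nodes = "data.frame", edges = "data.frame",
  idAttribute = "character", directed = "logical"
))

setValidity("SeedNetwork", function(object) {
  msg <- character()
  if (!all(c("nodeId", "attrs") %in% names(object@nodes))) {
    return("nodes must have columns nodeId, attrs")
  }
  if (!all(c("source", "target", "attrs") %in% names(object@edges))) {
    return("edges must have columns source, target, attrs")
  }
  if (anyDuplicated(object@nodes$nodeId)) {
    msg <- c(msg, "duplicate seed nodeId")
  }
  bad <- setdiff(unique(c(object@edges$source, object@edges$target)),
                 object@nodes$nodeId)
  if (length(bad)) {
    msg <- c(msg, paste("edge references unknown node(s):",
                        paste(bad, collapse = ", ")))
  }
  if (length(object@idAttribute) != 1L) {
    msg <- c(msg, "idAttribute must be a single string")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' LinkReport: per-RegIN extension statistics
#'
#' @slot perRegin data.frame with columns \code{regin},
#'   \code{addedInteractions}, \code{addedNodes}, \code{matchedSeedNodes}.
#'   Added nodes are attributed to the RegIN that first introduced them.
#' @slot diagnostics Character vector of warnings (ambiguous matches,
#'   identifier-less nodes, collapsed duplicates, self-loops).
#'
#' @seealso [extendNetwork()], [linkStats()]
#' @exportClass LinkReport
setClass("LinkReport", representation(
  perRegin = "data.frame", diagnostics = "character"
))

#' ExtendedNetwork: seed network plus grafted regulatory edges
#'
#' The result of [extendNetwork()]: a multigraph containing the seed
#' subgraph unchanged plus added nodes and edges. Every added edge carries
#' exactly one RegIN provenance tag, so an interaction supported by k RegINs
#' appears as k parallel edges. Visibility state (per-RegIN show/hide and
#' the overlap threshold) is stored non-destructively on the object.
#'
#' @slot seed The original [SeedNetwork-class], kept verbatim.
#' @slot nodes data.frame: \code{nodeId}, \code{label}, \code{origin}
#'   ("initial"/"added"), \code{styleHint} ("grey circle"/"pink hexagon"),
#'   \code{canonicalKey} (NA for seed nodes), list-column \code{attrs},
#'   logical \code{visible}.
#' @slot edges data.frame: \code{source}, \code{target}, \code{origin},
#'   \code{regin} (NA for seed edges), \code{interactionType},
#'   \code{colour}, list-columns \code{evidence} and \code{attrs}, logical
#'   \code{visible}.
#' @slot visibility Named logical, one flag per loaded RegIN.
#' @slot threshold Integer >= 1; minimum support for an added edge to show.
#' @slot supportOver "shown" (support counted over visible RegINs only) or
#'   "loaded" (over all loaded RegINs).
#' @slot report The [LinkReport-class] from the extension run.
#'
#' @seealso [extendNetwork()], [applyThreshold()], [setVisibility()]
#' @exportClass ExtendedNetwork
setClass("ExtendedNetwork", representation(
  seed = "SeedNetwork", nodes = "data.frame", edges = "data.frame",
  visibility = "logical", threshold = "integer", supportOver = "character",
  report = "LinkReport"
))

setValidity("ExtendedNetwork", function(object) {
  msg <- character()
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("nodeId", "label", "origin", "styleHint", "canonicalKey",
             "attrs", "visible") %in% names(nd))) {
    return("malformed nodes table")
  }
  if (!all(c("source", "target", "origin", "regin", "interactionType",
             "colour", "evidence", "attrs", "visible") %in% names(ed))) {
    return("malformed edges table")
  }
  if (anyDuplicated(nd$nodeId)) msg <- c(msg, "duplicate nodeId")
  if (!all(nd$origin %in% c("initial", "added"))) {
    msg <- c(msg, "node origin must be 'initial' or 'added'")
  }
  added <- ed[ed$origin == "added", , drop = FALSE]
  if (any(is.na(added$regin))) {
    msg <- c(msg, "every added edge must carry a RegIN tag")
  }
  if (nrow(added) && length(object@visibility) &&
      !all(added$regin %in% names(object@visibility))) {
    msg <- c(msg, "added edge tagged with unknown RegIN")
  }
  if (object@threshold < 1L) msg <- c(msg, "threshold must be >= 1")
  if (!object@supportOver %in% c("shown", "loaded")) {
    msg <- c(msg, "supportOver must be 'shown' or 'loaded'")
  }
  # every added node has at least one incident added edge
  an <- nd$nodeId[nd$origin == "added"]
  if (length(an) && !all(an %in% c(added$source, added$target))) {
    msg <- c(msg, "added node with no incident added edge")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' MappingTable: cross-reference table between identifier systems
#'
#' Rows of synonymous identifiers across named identifier systems, the
#' file-based stand-in for a BridgeDb-style mapping service. Many-to-many
#' mappings are allowed: a (system, value) pair may occur in several rows.
#'
#' @slot systems Ordered character vector of system names (the header).
#' @slot rows Character matrix, one column per system; "" = no identifier.
#'
#' @seealso [loadMappingTable()], [translateIds()], [expandSeedIds()]
#' @exportClass MappingTable
setClass("MappingTable", representation(
  systems = "character", rows = "matrix"
))

setValidity("MappingTable", function(object) {
  if (anyDuplicated(object@systems)) return("duplicate system names")
  if (ncol(object@rows) != length(object@systems)) {
    return("rows must have one column per system")
  }
  if (!is.character(object@rows)) return("rows must be a character matrix")
  TRUE
})

#' XgmmlDocument: an in-memory XGMML network document
#'
#' Faithful representation of one XGMML \code{<graph>} element: a label, a
#' directedness flag, graph-level attributes and nodes/edges with typed
#' attributes. Attribute values are stored as \code{list(type=, value=)}
#' with type one of "string", "integer", "real", "list" (list values are
#' character vectors whose order is preserved).
#'
#' @slot label Graph label.
#' @slot directed Logical flag.
#' @slot graphAttrs Named list of typed attributes.
#' @slot nodes List of \code{list(id=, label=, attrs=)} entries.
#' @slot edges List of \code{list(source=, target=, attrs=)} entries.
#'
#' @seealso [readXgmml()], [writeXgmml()], [xgmmlDocument()]
#' @exportClass XgmmlDocument
setClass("XgmmlDocument", representation(
  label = "character", directed = "logical",
  graphAttrs = "list", nodes = "list", edges = "list"
))

setValidity("XgmmlDocument", function(object) {
  ids <- vapply(object@nodes, `[[`, "", "id")
  if (anyDuplicated(ids)) return("duplicate node id")
  for (e in object@edges) {
    if (!e$source %in% ids || !e$target %in% ids) {
      return(sprintf("edge %s -> %s references an undeclared node",
                     e$source, e$target))
    }
  }
  TRUE
})

#' BuildSchema: column roles for converting a table into a RegIN
#'
#' Describes how the columns of a tabular regulator-to-target dump map onto
#' RegIN nodes and interactions, plus the metadata the resulting RegIN
#' carries.
#'
#' @slot sourceLabel,targetLabel Column names holding display labels
#'   (may be empty: the first identifier is used as the label).
#' @slot sourceIds,targetIds Named character vectors mapping identifier
#'   system names to column names; at least one each.
#' @slot sourceBiotype,targetBiotype Fixed biotype strings
#'   (gene/protein/microRNA/drug/other).
#' @slot edgeAttrs Column names copied onto interactions as evidence.
#' @slot database,version,organism,interactionType RegIN metadata.
#' @slot delimiter Delimiter splitting multi-valued identifier cells.
#'
#' @seealso [buildSchema()], [buildRegin()]
#' @exportClass BuildSchema
setClass("BuildSchema", representation(
  sourceLabel = "character", sourceIds = "character",
  sourceBiotype = "character",
  targetLabel = "character", targetIds = "character",
  targetBiotype = "character",
  edgeAttrs = "character",
  database = "character", version = "character", organism = "character",
  interactionType = "character", delimiter = "character"
))

setValidity("BuildSchema", function(object) {
  msg <- character()
  if (!length(object@sourceIds) || is.null(names(object@sourceIds))) {
    msg <- c(msg, "at least one named source id column required")
  }
  if (!length(object@targetIds) || is.null(names(object@targetIds))) {
    msg <- c(msg, "at least one named target id column required")
  }
  if (nchar(object@delimiter) < 1L) msg <- c(msg, "empty delimiter")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' FixtureSpec: parameters of the synthetic fixture generator
#'
#' @slot nSeedNodes,nRegins,regulatorsPerRegin,interactionsPerRegin
#'   Non-negative integer counts.
#' @slot overlapFraction Fraction in [0,1] of qualifying interactions
#'   duplicated into at least two RegINs.
#' @slot directionMix Fraction of qualifying interactions in which the seed
#'   node is the target (i.e. a regulator is added); the rest have the seed
#'   node as regulator.
#' @slot rngSeed Integer seed; identical seeds give byte-identical output.
#'
#' @seealso [fixtureSpec()], [generateFixture()]
#' @exportClass FixtureSpec
setClass("FixtureSpec", representation(
  nSeedNodes = "integer", nRegins = "integer",
  regulatorsPerRegin = "integer", interactionsPerRegin = "integer",
  overlapFraction = "numeric", directionMix = "numeric", rngSeed = "integer"
))

setValidity("FixtureSpec", function(object) {
  msg <- character()
  cnt <- c(object@nSeedNodes, object@nRegins, object@regulatorsPerRegin,
           object@interactionsPerRegin)
  if (any(cnt < 0L)) msg <- c(msg, "counts must be >= 0")
  if (object@overlapFraction < 0 || object@overlapFraction > 1) {
    msg <- c(msg, "overlapFraction must be in [0, 1]")
  }
  if (object@directionMix < 0 || object@directionMix > 1) {
    msg <- c(msg, "directionMix must be in [0, 1]")
  }
  if (object@overlapFraction > 0 && object@nRegins < 2L) {
    msg <- c(msg, "overlapFraction > 0 requires at least 2 RegINs")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
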