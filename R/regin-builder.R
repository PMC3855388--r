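## Convert tabular regulator->target interaction dumps (the export format
## of most interaction databases) into valid RegINs. Node identity during
## building is the canonical key, so one molecule listed under several
## labels but a shared primary identifier collapses into a single node.

#' Describe how a table's columns map onto a RegIN
#'
#' @param sourceIds,targetIds Named character vectors mapping identifier
#'   system names to column names, e.g.
#'   \code{c("miRBase-accession" = "mirna_acc")}; at least one each.
#' @param sourceLabel,targetLabel Columns holding display labels; when
#'   empty the first identifier value is used.
#' @param sourceBiotype,targetBiotype Biotype assigned to the nodes of each
#'   side (gene/protein/microRNA/drug/other).
#' @param edgeAttrs Columns copied onto interactions as evidence (e.g.
#'   "pmid", "score").
#' @param database,version,organism,interactionType RegIN metadata.
#' @param delimiter Delimiter splitting multi-valued cells (default "|").
#' @return A [BuildSchema-class].
#' @seealso [buildRegin()]
#' @export
buildSchema <- function(sourceIds, targetIds,
                        sourceLabel = character(), targetLabel = character(),
                        sourceBiotype = "other", targetBiotype = "other",
                        edgeAttrs = character(),
                        database = "unknown", version = "unknown",
                        organism = "unknown", interactionType = "unknown",
                        delimiter = "|") {
  new("BuildSchema",
      sourceLabel = as.character(sourceLabel),
      sourceIds = unlist(sourceIds), sourceBiotype = sourceBiotype,
      targetLabel = as.character(targetLabel),
      targetIds = unlist(targetIds), targetBiotype = targetBiotype,
      edgeAttrs = as.character(edgeAttrs),
      database = database, version = version, organism = organism,
      interactionType = interactionType, delimiter = delimiter)
}

#' Read a build schema from a YAML or JSON file
#'
#' The file holds the [buildSchema()] arguments by name; \code{sourceIds}
#' and \code{targetIds} are maps from system name to column name.
#'
#' @param path Path to the YAML/JSON schema file.
#' @return A [BuildSchema-class].
#' @export
schemaFromFile <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list(
    sourceIds = unlist(cfg$sourceIds), targetIds = unlist(cfg$targetIds))
  for (nm in c("sourceLabel", "targetLabel", "sourceBiotype",
               "targetBiotype", "edgeAttrs", "database", "version",
               "organism", "interactionType", "delimiter")) {
    if (!is.null(cfg[[nm]])) args[[nm]] <- unlist(cfg[[nm]])
  }
  do.call(buildSchema, args)
}

.splitCell <- function(cell, delim) {
  if (is.na(cell) || !nzchar(cell)) return(character())
  parts <- strsplit(cell, delim, fixed = TRUE)[[1L]]
  trimws(parts[nzchar(trimws(parts))])
}

# Collect a node side (source or target) from one table row.
.sideIds <- function(row, idCols, delim) {
  out <- character()
  for (sys in names(idCols)) {
    vals <- .splitCell(row[[idCols[[sys]]]], delim)
    if (length(vals)) out <- c(out, stats::setNames(vals, rep(sys, length(vals))))
  }
  out
}

#' Build a RegIN from a tabular interaction dump
#'
#' Reads a TSV with a header row and converts it into a RegIN according to
#' \code{schema}. One node is created per distinct canonical key on each
#' side (labels and identifiers merged across rows); one interaction per
#' distinct (source, target) pair with evidence merged. Rows missing all
#' source ids or all target ids are skipped and counted.
#'
#' @param tablePath Path to the TSV file.
#' @param schema A [BuildSchema-class].
#' @param name RegIN name; defaults to the schema's database name.
#' @param priority Identifier-system priority for canonical keys.
#' @return A list with elements \code{regin} ([RegIN-class]) and
#'   \code{report} (list: \code{rows}, \code{rowsSkipped},
#'   \code{duplicatesMerged}, \code{collisions} — labels that collapsed
#'   onto an existing canonical key).
#' @export
buildRegin <- function(tablePath, schema, name = NULL,
                       priority = defaultSystemPriority()) {
  stopifnot(is(schema, "BuildSchema"))
  validObject(schema)
  if (is.null(name)) name <- schema@database
  tab <- utils::read.delim(tablePath, colClasses = "character",
                           check.names = FALSE, na.strings = NULL,
                           fileEncoding = "UTF-8")
  needed <- c(unname(schema@sourceIds), unname(schema@targetIds),
              schema@sourceLabel, schema@targetLabel, schema@edgeAttrs)
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("schema column(s) missing from table: ",
         paste(missing, collapse = ", "))
  }
  if (!nrow(tab)) {
    warning(sprintf("empty interaction table '%s'", tablePath))
    return(list(regin = regIN(name, database = schema@database,
                              version = schema@version,
                              organism = schema@organism,
                              interactionType = schema@interactionType),
                report = list(rows = 0L, rowsSkipped = 0L,
                              duplicatesMerged = 0L,
                              collisions = character())))
  }
  nodes <- list()        # canonical key -> list(label, biotype, ids)
  nodeOrder <- character()
  collisions <- character()
  rowsSkipped <- 0L
  iaKey <- character()
  iaRows <- list()
  delim <- schema@delimiter

  registerNode <- function(ids, label, biotype) {
    key <- canonicalKey(ids, priority)
    if (is.null(nodes[[key]])) {
      nodes[[key]] <<- list(label = label, biotype = biotype,
                            identifiers = ids)
      nodeOrder <<- c(nodeOrder, key)
    } else {
      if (!identical(nodes[[key]]$label, label)) {
        collisions <<- c(collisions, sprintf(
          "label '%s' collapsed onto node '%s' (label '%s')",
          label, key, nodes[[key]]$label))
      }
      merged <- c(nodes[[key]]$identifiers, ids)
      nodes[[key]]$identifiers <<-
        merged[!duplicated(paste(names(merged), merged, sep = "\r"))]
    }
    key
  }

  for (i in seq_len(nrow(tab))) {
    row <- tab[i, , drop = FALSE]
    srcIds <- .sideIds(row, schema@sourceIds, delim)
    tgtIds <- .sideIds(row, schema@targetIds, delim)
    if (!length(srcIds) || !length(tgtIds)) {
      rowsSkipped <- rowsSkipped + 1L
      next
    }
    srcLabel <- if (length(schema@sourceLabel) &&
                    nzchar(row[[schema@sourceLabel]])) {
      row[[schema@sourceLabel]]
    } else unname(srcIds[1L])
    tgtLabel <- if (length(schema@targetLabel) &&
                    nzchar(row[[schema@targetLabel]])) {
      row[[schema@targetLabel]]
    } else unname(tgtIds[1L])
    sKey <- registerNode(srcIds, srcLabel, schema@sourceBiotype)
    tKey <- registerNode(tgtIds, tgtLabel, schema@targetBiotype)
    ev <- list()
    for (col in schema@edgeAttrs) {
      vals <- .splitCell(row[[col]], delim)
      if (length(vals)) ev[[col]] <- vals
    }
    iaKey[length(iaKey) + 1L] <- paste(sKey, tKey, sep = "\r")
    iaRows[[length(iaRows) + 1L]] <-
      list(sourceId = sKey, targetId = tKey, evidence = ev)
  }

  iaDf <- data.frame(
    sourceId = vapply(iaRows, `[[`, "", "sourceId"),
    targetId = vapply(iaRows, `[[`, "", "targetId"),
    interactionType = rep(schema@interactionType, length(iaRows)),
    stringsAsFactors = FALSE)
  iaDf$evidence <- I(lapply(iaRows, `[[`, "evidence"))
  dd <- .dedupInteractions(iaDf)

  nodeDf <- data.frame(
    nodeId = nodeOrder,
    label = vapply(nodeOrder, function(k) nodes[[k]]$label, ""),
    biotype = vapply(nodeOrder, function(k) nodes[[k]]$biotype, ""),
    stringsAsFactors = FALSE)
  nodeDf$identifiers <- I(lapply(nodeOrder, function(k) {
    nodes[[k]]$identifiers
  }))
  nodeDf$extra <- I(rep(list(character()), length(nodeOrder)))
  regin <- regIN(name, nodeDf, dd$interactions,
                 database = schema@database, version = schema@version,
                 organism = schema@organism,
                 interactionType = schema@interactionType)
  list(regin = regin,
       report = list(rows = nrow(tab), rowsSkipped = rowsSkipped,
                     duplicatesMerged = dd$nDuplicates,
                     collisions = collisions))
}

#' Validate a RegIN
#'
#' Quality gate before linking: reports nodes without identifiers,
#' dangling edge references, duplicate (source, target) pairs, missing
#' metadata fields, and (info-level) self-loops. An empty \code{warnings}
#' and \code{errors} report means the RegIN satisfies all invariants.
#'
#' @param regin A [RegIN-class] (slots inspected directly, so objects that
#'   would fail validity can still be diagnosed).
#' @return A list with character vectors \code{errors}, \code{warnings}
#'   and \code{info}, plus logical \code{ok} (no errors and no warnings).
#' @export
validateRegin <- function(regin) {
  stopifnot(is(regin, "RegIN"))
  errors <- character(); warn <- character(); info <- character()
  nd <- regin@nodes
  ia <- regin@interactions
  dup <- nd$nodeId[duplicated(nd$nodeId)]
  if (length(dup)) {
    errors <- c(errors, paste("duplicate node id(s):",
                              paste(unique(dup), collapse = ", ")))
  }
  noIds <- nd$nodeId[lengths(nd$identifiers) == 0L]
  for (n in noIds) {
    warn <- c(warn, sprintf("node '%s' has no identifiers and can never match", n))
  }
  dangling <- setdiff(unique(c(ia$sourceId, ia$targetId)), nd$nodeId)
  for (n in dangling) {
    errors <- c(errors, sprintf("interaction references undeclared node '%s'", n))
  }
  key <- paste(ia$sourceId, ia$targetId, sep = "\r")
  if (anyDuplicated(key)) {
    dupPairs <- unique(key[duplicated(key)])
    warn <- c(warn, sprintf("%d duplicate (source, target) pair(s)",
                            length(dupPairs)))
  }
  for (f in c("database", "version", "organism", "interactionType")) {
    if (identical(slot(regin, f), "unknown") || !nzchar(slot(regin, f))) {
      warn <- c(warn, sprintf("metadata field '%s' is missing", f))
    }
  }
  loops <- sum(ia$sourceId == ia$targetId)
  if (loops) info <- c(info, sprintf("%d self-loop(s)", loops))
  list(errors = errors, warnings = warn, info = info,
       ok = !length(errors) && !length(warn))
}
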