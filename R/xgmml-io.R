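## XGMML dialect used for RegINs, seed networks and extended networks:
##  - one <graph> element per file, optional XGMML namespace accepted on
##    read, none emitted on write
##  - attributes are <att name=".." value=".." type="string|integer|real"/>
##    or <att name=".." type="list"> with nested <att type="string"
##    value=".."/> members (order preserved)
##  - RegIN nodes carry their identifiers in a single list attribute
##    "identifiers" with entries "system:value"; a bare value means system
##    "unknown"
##  - <graphics> subelements are skipped on read and never written

.XGMML_TYPES <- c("string", "integer", "real", "list")

#' Typed XGMML attribute value
#'
#' Wraps an R value as a typed attribute for [xgmmlDocument()]. The type is
#' inferred when not given: single character = "string", integer =
#' "integer", double = "real", character vector of length != 1 = "list".
#'
#' @param value The value (character/integer/double; character vector for
#'   lists).
#' @param type One of "string", "integer", "real", "list", or NULL to infer.
#' @return \code{list(type=, value=)}.
#' @export
xgmmlAtt <- function(value, type = NULL) {
  if (is.null(type)) {
    type <- if (is.integer(value)) "integer"
    else if (is.double(value)) "real"
    else if (is.character(value) && length(value) == 1L) "string"
    else "list"
  }
  type <- match.arg(type, .XGMML_TYPES)
  value <- switch(type,
    string = as.character(value)[1L],
    integer = as.integer(value)[1L],
    real = as.double(value)[1L],
    list = as.character(value))
  list(type = type, value = value)
}

# Coerce a named list of plain R values into typed attributes.
.asAtts <- function(x) {
  if (is.null(x)) return(list())
  lapply(x, function(v) {
    if (is.list(v) && identical(sort(names(v)), c("type", "value"))) v
    else xgmmlAtt(v)
  })
}

#' Construct an XGMML document
#'
#' @param label Graph label.
#' @param directed Directedness flag written on the graph element.
#' @param graphAttrs Named list of attribute values (plain R values or
#'   [xgmmlAtt()] wrappers).
#' @param nodes List of \code{list(id=, label=, attrs=)}; \code{label}
#'   defaults to the id, \code{attrs} to none.
#' @param edges List of \code{list(source=, target=, attrs=)}.
#' @return An [XgmmlDocument-class].
#' @export
xgmmlDocument <- function(label = "", directed = FALSE,
                          graphAttrs = list(), nodes = list(),
                          edges = list()) {
  nodes <- lapply(nodes, function(n) {
    list(id = as.character(n$id),
         label = as.character(if (is.null(n$label)) n$id else n$label),
         attrs = .asAtts(n$attrs))
  })
  edges <- lapply(edges, function(e) {
    list(source = as.character(e$source), target = as.character(e$target),
         attrs = .asAtts(e$attrs))
  })
  new("XgmmlDocument", label = label, directed = directed,
      graphAttrs = .asAtts(graphAttrs), nodes = nodes, edges = edges)
}

.parseAtt <- function(el) {
  type <- xml2::xml_attr(el, "type")
  if (is.na(type)) type <- "string"
  if (!type %in% .XGMML_TYPES) {
    stop(sprintf("unsupported attribute type '%s'", type))
  }
  if (type == "list") {
    members <- xml2::xml_find_all(el, "./att")
    xgmmlAtt(vapply(members, xml2::xml_attr, "", "value"), "list")
  } else {
    xgmmlAtt(xml2::xml_attr(el, "value"), type)
  }
}

.parseAtts <- function(el) {
  atts <- xml2::xml_find_all(el, "./att")
  out <- list()
  for (a in atts) {
    nm <- xml2::xml_attr(a, "name")
    if (is.na(nm)) next
    out[[nm]] <- .parseAtt(a)
  }
  out
}

#' Read an XGMML network file
#'
#' Accepts documents with or without the XGMML XML namespace; exactly one
#' \code{<graph>} element per file. Node ids must be unique and every edge
#' must reference declared nodes. \code{<graphics>} subelements are
#' ignored.
#'
#' @param path Path to an XGMML file.
#' @return An [XgmmlDocument-class] with all attributes preserved;
#'   \code{directed} is read from the graph element (FALSE when absent).
#' @seealso [writeXgmml()], [reginFromXgmml()]
#' @export
readXgmml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "graph") {
    stop("not an XGMML file: root element must be <graph>")
  }
  if (length(xml2::xml_find_all(root, ".//graph"))) {
    stop("multiple <graph> elements in one file; one network per file")
  }
  label <- xml2::xml_attr(root, "label")
  if (is.na(label)) label <- ""
  dflag <- xml2::xml_attr(root, "directed")
  directed <- !is.na(dflag) && dflag %in% c("1", "true", "TRUE", "yes")
  nodes <- lapply(xml2::xml_find_all(root, "./node"), function(n) {
    id <- xml2::xml_attr(n, "id")
    if (is.na(id)) stop("node without id attribute")
    lab <- xml2::xml_attr(n, "label")
    list(id = id, label = if (is.na(lab)) id else lab, attrs = .parseAtts(n))
  })
  ids <- vapply(nodes, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate node id '%s'", ids[duplicated(ids)][1L]))
  }
  edges <- lapply(xml2::xml_find_all(root, "./edge"), function(e) {
    src <- xml2::xml_attr(e, "source")
    tgt <- xml2::xml_attr(e, "target")
    if (is.na(src) || is.na(tgt)) stop("edge without source/target")
    list(source = src, target = tgt, attrs = .parseAtts(e))
  })
  for (e in edges) {
    for (endp in c(e$source, e$target)) {
      if (!endp %in% ids) {
        stop(sprintf("edge %s -> %s references undeclared node '%s'",
                     e$source, e$target, endp))
      }
    }
  }
  new("XgmmlDocument", label = label, directed = directed,
      graphAttrs = .parseAtts(root), nodes = nodes, edges = edges)
}

.writeAtt <- function(parent, name, att) {
  if (att$type == "list") {
    el <- xml2::xml_add_child(parent, "att", name = name, type = "list")
    for (v in att$value) {
      xml2::xml_add_child(el, "att", type = "string", value = v)
    }
  } else {
    # %.17g keeps doubles bit-exact across the write/read round trip
    value <- if (att$type == "real") sprintf("%.17g", att$value) else
      as.character(att$value)
    xml2::xml_add_child(parent, "att", name = name, value = value,
                        type = att$type)
  }
  invisible(NULL)
}

#' Write an XGMML network file
#'
#' Emits UTF-8 XML with nodes before edges, both in insertion order, so the
#' same document always produces byte-identical files.
#'
#' @param doc An [XgmmlDocument-class].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @seealso [readXgmml()]
#' @export
writeXgmml <- function(doc, path) {
  stopifnot(is(doc, "XgmmlDocument"))
  validObject(doc)
  root <- xml2::xml_new_root("graph", label = doc@label,
                             directed = if (doc@directed) "1" else "0")
  for (nm in names(doc@graphAttrs)) .writeAtt(root, nm, doc@graphAttrs[[nm]])
  for (n in doc@nodes) {
    el <- xml2::xml_add_child(root, "node", id = n$id, label = n$label)
    for (nm in names(n$attrs)) .writeAtt(el, nm, n$attrs[[nm]])
  }
  for (e in doc@edges) {
    el <- xml2::xml_add_child(root, "edge", source = e$source,
                              target = e$target)
    for (nm in names(e$attrs)) .writeAtt(el, nm, e$attrs[[nm]])
  }
  xml2::write_xml(root, path)
  invisible(path)
}

.attChr <- function(atts, name, default = NA_character_) {
  a <- atts[[name]]
  if (is.null(a)) default else as.character(a$value)
}

.splitIdentifier <- function(entry) {
  pos <- regexpr(":", entry, fixed = TRUE)
  if (pos > 0L) {
    sys <- substr(entry, 1L, pos - 1L)
    val <- substr(entry, pos + 1L, nchar(entry))
    if (!nzchar(sys)) sys <- "unknown"
  } else {
    sys <- "unknown"
    val <- entry
  }
  stats::setNames(val, sys)
}

#' Interpret an XGMML document as a RegIN
#'
#' The document must be directed. Each node's identifiers come from its
#' "identifiers" list attribute with "system:value" entries (a bare value
#' gets system "unknown"). Graph attributes database/version/organism/type
#' default to "unknown" when absent. Duplicate (source, target)
#' interactions are collapsed with evidence merged; nodes without
#' identifiers load but can never match — both conditions raise warnings,
#' not errors.
#'
#' @param doc An [XgmmlDocument-class], or a file path which is read first.
#' @param name RegIN name; defaults to the graph label (or the file name).
#' @return A [RegIN-class].
#' @seealso [reginToXgmml()], [validateRegin()]
#' @export
reginFromXgmml <- function(doc, name = NULL) {
  if (is.character(doc)) {
    if (is.null(name)) {
      name <- tools::file_path_sans_ext(basename(doc))
    }
    doc <- readXgmml(doc)
  }
  if (!doc@directed) stop("RegIN must be directed")
  if (is.null(name)) name <- if (nzchar(doc@label)) doc@label else "regin"
  ga <- doc@graphAttrs
  itype <- .attChr(ga, "type", "unknown")
  nodes <- lapply(doc@nodes, function(n) {
    ids <- n$attrs[["identifiers"]]
    idv <- if (is.null(ids)) character() else {
      entries <- as.character(ids$value)
      entries <- entries[nzchar(entries)]
      if (length(entries)) {
        out <- unlist(lapply(entries, .splitIdentifier))
        out
      } else character()
    }
    extra <- character()
    for (nm in setdiff(names(n$attrs), c("identifiers", "biotype"))) {
      a <- n$attrs[[nm]]
      if (a$type != "list") extra[nm] <- as.character(a$value)
    }
    list(nodeId = n$id, label = n$label,
         biotype = .attChr(n$attrs, "biotype", "other"),
         identifiers = idv, extra = extra)
  })
  noId <- vapply(nodes, function(n) length(n$identifiers) == 0L, NA)
  if (any(noId)) {
    warning(sprintf(
      "RegIN '%s': %d node(s) without identifiers cannot match (e.g. '%s')",
      name, sum(noId), nodes[[which(noId)[1L]]]$nodeId))
  }
  nodeDf <- data.frame(
    nodeId = vapply(nodes, `[[`, "", "nodeId"),
    label = vapply(nodes, `[[`, "", "label"),
    biotype = vapply(nodes, `[[`, "", "biotype"),
    stringsAsFactors = FALSE)
  nodeDf$identifiers <- I(lapply(nodes, `[[`, "identifiers"))
  nodeDf$extra <- I(lapply(nodes, `[[`, "extra"))
  ia <- lapply(doc@edges, function(e) {
    ev <- list()
    for (nm in setdiff(names(e$attrs), "interaction")) {
      ev[[nm]] <- as.character(e$attrs[[nm]]$value)
    }
    list(sourceId = e$source, targetId = e$target,
         interactionType = .attChr(e$attrs, "interaction", itype),
         evidence = ev)
  })
  iaDf <- data.frame(
    sourceId = vapply(ia, `[[`, "", "sourceId"),
    targetId = vapply(ia, `[[`, "", "targetId"),
    interactionType = vapply(ia, `[[`, "", "interactionType"),
    stringsAsFactors = FALSE)
  iaDf$evidence <- I(lapply(ia, `[[`, "evidence"))
  dd <- .dedupInteractions(iaDf)
  if (dd$nDuplicates > 0L) {
    warning(sprintf(
      "RegIN '%s': collapsed %d duplicate interaction(s), evidence merged",
      name, dd$nDuplicates))
  }
  regIN(name = name, nodes = nodeDf, interactions = dd$interactions,
        database = .attChr(ga, "database", "unknown"),
        version = .attChr(ga, "version", "unknown"),
        organism = .attChr(ga, "organism", "unknown"),
        interactionType = itype)
}

#' Serialise a RegIN as an XGMML document
#'
#' Inverse of [reginFromXgmml()]: node identifiers become the
#' "identifiers" list attribute ("system:value" entries), metadata becomes
#' graph attributes, evidence values become edge attributes.
#'
#' @param regin A [RegIN-class].
#' @param path Optional file path; when given the document is also written.
#' @return The [XgmmlDocument-class], invisibly when \code{path} is given.
#' @export
reginToXgmml <- function(regin, path = NULL) {
  stopifnot(is(regin, "RegIN"))
  nd <- regin@nodes
  nodes <- lapply(seq_len(nrow(nd)), function(i) {
    ids <- nd$identifiers[[i]]
    attrs <- list(
      identifiers = xgmmlAtt(
        if (length(ids)) paste(names(ids), ids, sep = ":") else character(),
        "list"),
      biotype = xgmmlAtt(nd$biotype[i]))
    ex <- nd$extra[[i]]
    for (nm in names(ex)) attrs[[nm]] <- xgmmlAtt(unname(ex[[nm]]))
    list(id = nd$nodeId[i], label = nd$label[i], attrs = attrs)
  })
  ia <- regin@interactions
  edges <- lapply(seq_len(nrow(ia)), function(i) {
    attrs <- list(interaction = xgmmlAtt(ia$interactionType[i]))
    ev <- ia$evidence[[i]]
    for (nm in names(ev)) attrs[[nm]] <- xgmmlAtt(ev[[nm]], "list")
    list(source = ia$sourceId[i], target = ia$targetId[i], attrs = attrs)
  })
  doc <- xgmmlDocument(
    label = regin@name, directed = TRUE,
    graphAttrs = list(database = regin@database, version = regin@version,
                      organism = regin@organism,
                      type = regin@interactionType),
    nodes = nodes, edges = edges)
  if (!is.null(path)) {
    writeXgmml(doc, path)
    return(invisible(doc))
  }
  doc
}

.stripBom <- function(x) sub("^﻿", "", x)

.readLinesClean <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines)) lines[1L] <- .stripBom(lines[1L])
  sub("\r$", "", lines)
}

# Typed attribute -> plain character vector for seed attrs
.attToChr <- function(a) as.character(a$value)

#' Load a seed network from a file
#'
#' Supported formats: \describe{
#'   \item{xgmml}{as [readXgmml()]; node attributes are kept and
#'     \code{idAttribute} should name one of them.}
#'   \item{sif}{whitespace/tab-delimited \code{source interaction target}
#'     lines (extra trailing targets allowed, one-token lines give
#'     isolated nodes); the node id doubles as the id-attribute value.}
#'   \item{nodelist}{one node id per line, no edges; the id doubles as the
#'     id-attribute value.}
#' }
#' Readers tolerate Windows/Unix line endings and a UTF-8 BOM. An empty
#' file yields an empty network with a warning; an id attribute missing
#' from every node also warns (such a seed can never match a RegIN).
#'
#' @param path File path.
#' @param format One of "xgmml", "sif", "nodelist".
#' @param idAttribute Node attribute used for matching (default "id").
#' @return A [SeedNetwork-class].
#' @export
seedFromFile <- function(path, format = c("xgmml", "sif", "nodelist"),
                         idAttribute = "id") {
  format <- match.arg(format)
  seed <- switch(format,
    nodelist = {
      lines <- trimws(.readLinesClean(path))
      lines <- lines[nzchar(lines)]
      seedNetwork(lines, idAttribute = idAttribute)
    },
    sif = {
      lines <- trimws(.readLinesClean(path))
      lines <- lines[nzchar(lines)]
      nodes <- character()
      edges <- list()
      for (ln in lines) {
        tok <- strsplit(ln, "[ \t]+")[[1L]]
        nodes <- c(nodes, tok[1L])
        if (length(tok) >= 3L) {
          nodes <- c(nodes, tok[-(1:2)])
          for (tgt in tok[-(1:2)]) {
            edges[[length(edges) + 1L]] <-
              list(source = tok[1L], target = tgt, interaction = tok[2L])
          }
        }
      }
      nodes <- unique(nodes)
      ed <- data.frame(
        source = vapply(edges, `[[`, "", "source"),
        target = vapply(edges, `[[`, "", "target"),
        stringsAsFactors = FALSE)
      ed$attrs <- I(lapply(edges, function(e) {
        list(interaction = e$interaction)
      }))
      seedNetwork(nodes, edges = ed, idAttribute = idAttribute)
    },
    xgmml = {
      doc <- readXgmml(path)
      nd <- data.frame(
        nodeId = vapply(doc@nodes, `[[`, "", "id"),
        stringsAsFactors = FALSE)
      nd$attrs <- I(lapply(doc@nodes, function(n) {
        out <- lapply(n$attrs, .attToChr)
        if (is.null(out[["label"]])) out$label <- n$label
        out
      }))
      ed <- data.frame(
        source = vapply(doc@edges, `[[`, "", "source"),
        target = vapply(doc@edges, `[[`, "", "target"),
        stringsAsFactors = FALSE)
      ed$attrs <- I(lapply(doc@edges, function(e) {
        lapply(e$attrs, .attToChr)
      }))
      seedNetwork(nd, edges = ed, idAttribute = idAttribute,
                  directed = doc@directed)
    })
  if (!nrow(seed@nodes)) {
    warning(sprintf("empty seed network read from '%s'", path))
  } else if (!any(vapply(seed@nodes$attrs, function(a) {
    !is.null(a[[idAttribute]])
  }, NA))) {
    warning(sprintf(
      "id attribute '%s' is missing from every seed node; extension will add nothing",
      idAttribute))
  }
  seed
}

# Seed network -> XGMML document nodes/edges (shared by extended writer)
.seedNodeAtts <- function(attrs) {
  out <- list()
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    out[[nm]] <- if (length(v) == 1L) xgmmlAtt(as.character(v), "string")
    else xgmmlAtt(as.character(v), "list")
  }
  out
}

.RESERVED_NODE_ATTS <- c("origin", "styleHint", "canonicalKey")
.RESERVED_EDGE_ATTS <- c("origin", "sourceRegin", "interaction", "colour")

#' Serialise an extended network as XGMML
#'
#' Writes the full multigraph: seed nodes/edges with their original
#' attributes plus \code{origin="initial"}, added nodes with
#' \code{origin="added"}, style hints and canonical keys, and added edges
#' with \code{sourceRegin}, \code{interaction}, \code{colour} and evidence
#' attributes. Visibility state is written as graph attributes
#' (\code{hiddenRegins}, \code{threshold}, \code{supportOver}) so
#' [extendedFromXgmml()] restores it.
#'
#' @param extended An [ExtendedNetwork-class].
#' @param path Optional output path.
#' @param visibleOnly When TRUE only currently visible nodes/edges are
#'   written (materialising the filtered graph); the seed subgraph is
#'   always included.
#' @return The [XgmmlDocument-class]; invisibly when \code{path} is given.
#' @export
extendedToXgmml <- function(extended, path = NULL, visibleOnly = FALSE) {
  stopifnot(is(extended, "ExtendedNetwork"))
  nd <- extended@nodes
  ed <- extended@edges
  if (visibleOnly) {
    nd <- nd[nd$visible | nd$origin == "initial", , drop = FALSE]
    ed <- ed[ed$visible | ed$origin == "initial", , drop = FALSE]
  }
  nodes <- lapply(seq_len(nrow(nd)), function(i) {
    attrs <- .seedNodeAtts(nd$attrs[[i]])
    attrs$origin <- xgmmlAtt(nd$origin[i])
    attrs$styleHint <- xgmmlAtt(nd$styleHint[i])
    if (!is.na(nd$canonicalKey[i])) {
      attrs$canonicalKey <- xgmmlAtt(nd$canonicalKey[i])
    }
    list(id = nd$nodeId[i], label = nd$label[i], attrs = attrs)
  })
  edges <- lapply(seq_len(nrow(ed)), function(i) {
    attrs <- .seedNodeAtts(ed$attrs[[i]])
    attrs$origin <- xgmmlAtt(ed$origin[i])
    if (ed$origin[i] == "added") {
      attrs$sourceRegin <- xgmmlAtt(ed$regin[i])
      attrs$interaction <- xgmmlAtt(ed$interactionType[i])
      attrs$colour <- xgmmlAtt(ed$colour[i])
      ev <- ed$evidence[[i]]
      for (nm in names(ev)) attrs[[nm]] <- xgmmlAtt(ev[[nm]], "list")
    }
    list(source = ed$source[i], target = ed$target[i], attrs = attrs)
  })
  vis <- extended@visibility
  ga <- list(
    idAttribute = xgmmlAtt(extended@seed@idAttribute),
    seedDirected = xgmmlAtt(if (extended@seed@directed) "1" else "0"),
    regins = xgmmlAtt(names(vis), "list"),
    hiddenRegins = xgmmlAtt(names(vis)[!vis], "list"),
    threshold = xgmmlAtt(extended@threshold),
    supportOver = xgmmlAtt(extended@supportOver))
  doc <- xgmmlDocument(label = "extended network", directed = TRUE,
                       graphAttrs = ga, nodes = nodes, edges = edges)
  if (!is.null(path)) {
    writeXgmml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Rebuild an extended network from its XGMML serialisation
#'
#' Inverse of [extendedToXgmml()] (full, not visible-only, output):
#' reconstructs the seed subgraph from \code{origin="initial"} elements,
#' the added multigraph from the provenance attributes, and the visibility
#' state from the graph attributes, then recomputes visibility flags.
#'
#' @param doc An [XgmmlDocument-class] or a file path.
#' @return An [ExtendedNetwork-class].
#' @export
extendedFromXgmml <- function(doc) {
  if (is.character(doc)) doc <- readXgmml(doc)
  ga <- doc@graphAttrs
  idAttr <- .attChr(ga, "idAttribute", "id")
  origin <- vapply(doc@nodes, function(n) {
    .attChr(n$attrs, "origin", "initial")
  }, "")
  seedNodeIds <- vapply(doc@nodes, `[[`, "", "id")[origin == "initial"]
  plainAttrs <- function(n, reserved) {
    out <- lapply(n$attrs[setdiff(names(n$attrs), reserved)], .attToChr)
    out
  }
  sn <- data.frame(nodeId = seedNodeIds, stringsAsFactors = FALSE)
  sn$attrs <- I(lapply(doc@nodes[origin == "initial"], plainAttrs,
                       reserved = .RESERVED_NODE_ATTS))
  eorigin <- vapply(doc@edges, function(e) {
    .attChr(e$attrs, "origin", "initial")
  }, "")
  sed <- doc@edges[eorigin == "initial"]
  se <- data.frame(
    source = vapply(sed, `[[`, "", "source"),
    target = vapply(sed, `[[`, "", "target"),
    stringsAsFactors = FALSE)
  se$attrs <- I(lapply(sed, plainAttrs, reserved = .RESERVED_EDGE_ATTS))
  seed <- seedNetwork(sn, edges = se, idAttribute = idAttr,
                      directed = .attChr(ga, "seedDirected", "0") == "1")

  nd <- data.frame(
    nodeId = vapply(doc@nodes, `[[`, "", "id"),
    label = vapply(doc@nodes, `[[`, "", "label"),
    origin = origin,
    styleHint = vapply(doc@nodes, function(n) {
      .attChr(n$attrs, "styleHint", "grey circle")
    }, ""),
    canonicalKey = vapply(doc@nodes, function(n) {
      .attChr(n$attrs, "canonicalKey", NA_character_)
    }, ""),
    stringsAsFactors = FALSE)
  nd$attrs <- I(lapply(doc@nodes, plainAttrs,
                       reserved = .RESERVED_NODE_ATTS))
  nd$visible <- rep(TRUE, nrow(nd))
  ed <- data.frame(
    source = vapply(doc@edges, `[[`, "", "source"),
    target = vapply(doc@edges, `[[`, "", "target"),
    origin = eorigin,
    regin = vapply(doc@edges, function(e) {
      .attChr(e$attrs, "sourceRegin", NA_character_)
    }, ""),
    interactionType = vapply(doc@edges, function(e) {
      .attChr(e$attrs, "interaction", NA_character_)
    }, ""),
    colour = vapply(doc@edges, function(e) {
      .attChr(e$attrs, "colour", NA_character_)
    }, ""),
    stringsAsFactors = FALSE)
  ed$evidence <- I(lapply(doc@edges, function(e) {
    if (.attChr(e$attrs, "origin", "initial") != "added") return(list())
    keep <- setdiff(names(e$attrs), .RESERVED_EDGE_ATTS)
    lapply(e$attrs[keep], .attToChr)
  }))
  ed$attrs <- I(lapply(doc@edges, function(e) {
    if (.attChr(e$attrs, "origin", "initial") == "added") return(list())
    plainAttrs(e, .RESERVED_EDGE_ATTS)
  }))
  ed$visible <- rep(TRUE, nrow(ed))

  regins <- ga[["regins"]]
  reginNames <- if (is.null(regins)) {
    unique(stats::na.omit(ed$regin))
  } else as.character(regins$value)
  hidden <- ga[["hiddenRegins"]]
  hidden <- if (is.null(hidden)) character() else as.character(hidden$value)
  vis <- stats::setNames(!(reginNames %in% hidden), reginNames)
  thr <- ga[["threshold"]]
  thr <- if (is.null(thr)) 1L else as.integer(thr$value)
  ext <- new("ExtendedNetwork", seed = seed, nodes = nd, edges = ed,
             visibility = vis, threshold = thr,
             supportOver = .attChr(ga, "supportOver", "shown"),
             report = linkStatsFromEdges(nd, ed, vis))
  .recomputeVisibility(ext)
}

#' Serialise a seed network as XGMML
#'
#' Node/edge attributes become string attributes (list attributes when a
#' value has several elements, as after [expandSeedIds()]).
#'
#' @param seed A [SeedNetwork-class].
#' @param path Optional output path.
#' @return The [XgmmlDocument-class]; invisibly when \code{path} is given.
#' @export
seedToXgmml <- function(seed, path = NULL) {
  stopifnot(is(seed, "SeedNetwork"))
  nodes <- lapply(seq_len(nrow(seed@nodes)), function(i) {
    a <- seed@nodes$attrs[[i]]
    lab <- if (is.null(a$label)) seed@nodes$nodeId[i] else
      as.character(a$label)[1L]
    list(id = seed@nodes$nodeId[i], label = lab, attrs = .seedNodeAtts(a))
  })
  edges <- lapply(seq_len(nrow(seed@edges)), function(i) {
    list(source = seed@edges$source[i], target = seed@edges$target[i],
         attrs = .seedNodeAtts(seed@edges$attrs[[i]]))
  })
  doc <- xgmmlDocument(label = "seed network", directed = seed@directed,
                       graphAttrs = list(idAttribute = seed@idAttribute),
                       nodes = nodes, edges = edges)
  if (!is.null(path)) {
    writeXgmml(doc, path)
    return(invisible(doc))
  }
  doc
}
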