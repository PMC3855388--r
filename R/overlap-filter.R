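## Post-extension filtering: per-RegIN show/hide and the overlap (support)
## threshold. Both are non-destructive visibility flags on the
## ExtendedNetwork and can be applied and reverted freely; visibility is
## always recomputed from scratch from (visibility map, threshold), so
## hide+threshold compose predictably.

#' Support index of an extended network
#'
#' Groups the added parallel edges by their endpoint pair and records which
#' RegINs support each pair. Endpoints are already canonical: seed node ids
#' for matched endpoints, canonical-key node ids for added endpoints, so
#' the support of a pair equals its number of parallel edges.
#'
#' @param extended An [ExtendedNetwork-class].
#' @param visibleOnly When TRUE, edges of hidden RegINs are excluded from
#'   the support sets.
#' @return data.frame with columns \code{source}, \code{target},
#'   list-column \code{regins} (supporting RegIN names) and integer
#'   \code{support}.
#' @export
buildSupportIndex <- function(extended, visibleOnly = FALSE) {
  stopifnot(is(extended, "ExtendedNetwork"))
  ed <- extended@edges
  added <- ed[ed$origin == "added", , drop = FALSE]
  if (visibleOnly && nrow(added)) {
    shown <- names(extended@visibility)[extended@visibility]
    added <- added[added$regin %in% shown, , drop = FALSE]
  }
  if (!nrow(added)) {
    out <- data.frame(source = character(), target = character(),
                      stringsAsFactors = FALSE)
    out$regins <- I(list())
    out$support <- integer()
    return(out)
  }
  key <- paste(added$source, added$target, sep = "\r")
  first <- !duplicated(key)
  regins <- lapply(key[first], function(k) {
    sort(unique(added$regin[key == k]))
  })
  out <- data.frame(source = added$source[first],
                    target = added$target[first],
                    stringsAsFactors = FALSE)
  out$regins <- I(regins)
  out$support <- lengths(regins)
  rownames(out) <- NULL
  out
}

# Recompute edge/node visibility from the stored visibility map, threshold
# and support-counting mode; single source of truth for all filters.
.recomputeVisibility <- function(extended) {
  ed <- extended@edges
  nd <- extended@nodes
  vis <- extended@visibility
  added <- ed$origin == "added"
  if (any(added)) {
    idx <- buildSupportIndex(extended,
                             visibleOnly = extended@supportOver == "shown")
    support <- stats::setNames(idx$support,
                               paste(idx$source, idx$target, sep = "\r"))
    key <- paste(ed$source, ed$target, sep = "\r")
    sup <- support[key]
    sup[is.na(sup)] <- 0L
    shown <- rep(TRUE, nrow(ed))
    shown[added] <- unname(vis[ed$regin[added]])
    ed$visible <- ifelse(added,
                         shown & sup >= extended@threshold,
                         TRUE)
  } else {
    ed$visible <- rep(TRUE, nrow(ed))
  }
  addedN <- nd$origin == "added"
  if (any(addedN)) {
    visAdded <- ed[added & ed$visible, , drop = FALSE]
    touched <- unique(c(visAdded$source, visAdded$target))
    nd$visible <- ifelse(addedN, nd$nodeId %in% touched, TRUE)
  } else {
    nd$visible <- rep(TRUE, nrow(nd))
  }
  extended@edges <- ed
  extended@nodes <- nd
  extended
}

#' Show or hide one RegIN
#'
#' Temporarily removes (or restores) all edges of one RegIN from the
#' visible network. Added nodes left without any visible incident added
#' edge are hidden too; seed nodes and edges are never hidden. The
#' operation only flips a flag and is fully reversible.
#'
#' @param extended An [ExtendedNetwork-class].
#' @param reginName Name of a loaded RegIN.
#' @param visible TRUE to show, FALSE to hide.
#' @return The updated [ExtendedNetwork-class].
#' @seealso [applyThreshold()], [buildSupportIndex()]
#' @export
setVisibility <- function(extended, reginName, visible) {
  stopifnot(is(extended, "ExtendedNetwork"))
  if (!reginName %in% names(extended@visibility)) {
    stop(sprintf("unknown RegIN '%s'; loaded RegINs: %s", reginName,
                 paste(names(extended@visibility), collapse = ", ")))
  }
  extended@visibility[reginName] <- isTRUE(visible)
  .recomputeVisibility(extended)
}

#' Apply the overlap (support) threshold
#'
#' Shows only the added interactions supported by at least \code{k} RegINs.
#' An added edge is visible iff its RegIN is shown and its endpoint pair's
#' support is at least \code{k}; with the default counting mode
#' (\code{supportOver = "shown"}) support is counted over currently shown
#' RegINs only, so hiding a RegIN and thresholding compose the same way as
#' recomputing from scratch. \code{k = 1} restores every edge of a shown
#' RegIN; \code{k} above the number of loaded RegINs leaves only the seed
#' visible.
#'
#' @param extended An [ExtendedNetwork-class].
#' @param k Integer threshold, >= 1.
#' @return The updated [ExtendedNetwork-class].
#' @seealso [setVisibility()], [setSupportMode()]
#' @export
applyThreshold <- function(extended, k) {
  stopifnot(is(extended, "ExtendedNetwork"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("threshold must be an integer >= 1")
  extended@threshold <- k
  .recomputeVisibility(extended)
}

#' Choose how support is counted
#'
#' @param extended An [ExtendedNetwork-class].
#' @param mode "shown": support counts only edges of currently shown RegINs
#'   (default); "loaded": support counts edges of all loaded RegINs even
#'   when hidden.
#' @return The updated [ExtendedNetwork-class].
#' @export
setSupportMode <- function(extended, mode = c("shown", "loaded")) {
  stopifnot(is(extended, "ExtendedNetwork"))
  extended@supportOver <- match.arg(mode)
  .recomputeVisibility(extended)
}

#' Visible part of an extended network
#'
#' @param extended An [ExtendedNetwork-class].
#' @return A list with the \code{nodes} and \code{edges} data.frames
#'   restricted to currently visible elements.
#' @export
visibleSubgraph <- function(extended) {
  stopifnot(is(extended, "ExtendedNetwork"))
  list(nodes = extended@nodes[extended@nodes$visible, , drop = FALSE],
       edges = extended@edges[extended@edges$visible, , drop = FALSE])
}

#' Materialise the visible network as an XGMML file
#'
#' @param extended An [ExtendedNetwork-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
exportVisible <- function(extended, path) {
  extendedToXgmml(extended, path, visibleOnly = TRUE)
  invisible(path)
}
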