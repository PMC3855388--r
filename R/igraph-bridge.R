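#' Convert a network to an igraph object
#'
#' Bridge for downstream analysis (centrality, motifs, layouts) with the
#' igraph package. Parallel added edges are kept, with their RegIN
#' provenance as the \code{regin} edge attribute.
#'
#' @param x A [SeedNetwork-class], [RegIN-class] or
#'   [ExtendedNetwork-class].
#' @param visibleOnly For extended networks: keep only visible elements.
#' @return An \code{igraph} graph.
#' @export
asIgraph <- function(x, visibleOnly = FALSE) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for asIgraph()")
  }
  if (is(x, "SeedNetwork")) {
    return(igraph::graph_from_data_frame(
      x@edges[, c("source", "target"), drop = FALSE],
      directed = x@directed,
      vertices = data.frame(name = x@nodes$nodeId,
                            stringsAsFactors = FALSE)))
  }
  if (is(x, "RegIN")) {
    ia <- x@interactions
    return(igraph::graph_from_data_frame(
      data.frame(from = ia$sourceId, to = ia$targetId,
                 interaction = ia$interactionType,
                 stringsAsFactors = FALSE),
      directed = TRUE,
      vertices = data.frame(name = x@nodes$nodeId, label = x@nodes$label,
                            biotype = x@nodes$biotype,
                            stringsAsFactors = FALSE)))
  }
  if (is(x, "ExtendedNetwork")) {
    nd <- x@nodes
    ed <- x@edges
    if (visibleOnly) {
      nd <- nd[nd$visible, , drop = FALSE]
      ed <- ed[ed$visible, , drop = FALSE]
    }
    return(igraph::graph_from_data_frame(
      data.frame(from = ed$source, to = ed$target, origin = ed$origin,
                 regin = ed$regin, stringsAsFactors = FALSE),
      directed = TRUE,
      vertices = data.frame(name = nd$nodeId, origin = nd$origin,
                            label = nd$label, stringsAsFactors = FALSE)))
  }
  stop("cannot convert object of class ", class(x)[1L])
}
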