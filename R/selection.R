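# Search, first-neighbor expansion and visibility filtering.

#' @keywords internal
new_selection <- function(selected = character(0), highlighted = character(0),
                          mode = "search", components = character(0)) {
  stopifnot(all(selected %in% highlighted) || length(highlighted) == 0)
  structure(list(selected = selected,
                 highlighted = union(selected, highlighted),
                 mode = mode,
                 components = components),
            class = "cell_selection")
}

#' @export
print.cell_selection <- function(x, ...) {
  cat("<cell_selection> mode=", x$mode, ": ", length(x$selected),
      " selected, ", length(x$highlighted), " highlighted\n", sep = "")
  invisible(x)
}

#' Search nodes by label
#'
#' Case-insensitive exact label matching; multiple query terms union their
#' matches. Gene-symbol lists (one symbol per query term) therefore select
#' precisely the named nodes, with no substring over-selection.
#'
#' @param network a `cell_network`.
#' @param queries character vector of label queries.
#' @return A `cell_selection` with matching node ids selected and
#'   highlighted (empty when nothing matches).
#' @export
search_nodes <- function(network, queries) {
  q <- tolower(trimws(as.character(queries)))
  q <- q[nzchar(q)]
  hit <- network$nodes$id[tolower(trimws(network$nodes$label)) %in% q]
  new_selection(selected = hit, highlighted = hit, mode = "search")
}

#' First neighbors of a node
#'
#' Selects a node and highlights it together with all its adjacent nodes.
#' Also reports the node's multivalued cellular-component annotation, so
#' every compartment the molecule is known to occupy can be highlighted in
#' the diagram alongside the placement compartment.
#'
#' @param network a `cell_network`.
#' @param id node id.
#' @return A `cell_selection` (mode `"neighbors"`) whose `components` field
#'   carries the node's cellular-component list.
#' @export
first_neighbors <- function(network, id) {
  if (!id %in% network$nodes$id) stop("unknown node id: ", id)
  e <- network$edges[!network$edges$is_loop, , drop = FALSE]
  nb <- c(e$target[e$source == id], e$source[e$target == id])
  comp <- network$nodes$cellular_components[[match(id, network$nodes$id)]]
  new_selection(selected = id, highlighted = unique(c(id, nb)),
                mode = "neighbors", components = comp)
}

#' Hide nodes outside a selection
#'
#' Sets `visible = FALSE` on every node outside the selection's highlighted
#' set; an edge is visible only when both endpoints are. No records are
#' deleted, so the filter is fully reversible with [clear_filter()]. The
#' previous visibility flags are stashed on the network so clearing
#' restores them exactly.
#'
#' @param network a `cell_network`.
#' @param selection a `cell_selection`.
#' @return The network with visibility flags updated.
#' @export
apply_filter <- function(network, selection) {
  if (is.null(attr(network, "prev_visible"))) {
    attr(network, "prev_visible") <- network$nodes$visible
  }
  network$nodes$visible <- network$nodes$id %in% selection$highlighted
  refresh_edge_visibility(network)
}

#' @rdname apply_filter
#' @export
clear_filter <- function(network) {
  prev <- attr(network, "prev_visible")
  network$nodes$visible <- if (is.null(prev)) rep(TRUE, nrow(network$nodes)) else prev
  attr(network, "prev_visible") <- NULL
  refresh_edge_visibility(network)
}

# Edge visibility is always the conjunction of its endpoint visibilities.
#' @keywords internal
refresh_edge_visibility <- function(network) {
  vis <- stats::setNames(network$nodes$visible, network$nodes$id)
  network$edges$visible <- vis[network$edges$source] & vis[network$edges$target]
  network
}
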