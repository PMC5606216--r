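# Topology measures (degree, betweenness, clustering coefficient) and
# per-compartment node counts. All measures are computed over the visible
# subgraph, matching the filter semantics: when nodes are hidden the layout
# and the measures consider only visible nodes.

# Visible-subgraph adjacency list, self-loops dropped.
#' @keywords internal
visible_adjacency <- function(network) {
  ids <- network$nodes$id[network$nodes$visible]
  e <- network$edges
  e <- e[e$visible & !e$is_loop & e$source %in% ids & e$target %in% ids, ,
         drop = FALSE]
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) adj[[id]] <- character(0)
  if (nrow(e) > 0) {
    sp <- split(c(e$target, e$source), c(e$source, e$target))
    adj[names(sp)] <- sp
  }
  adj
}

#' Node degree
#'
#' Undirected degree over the visible subgraph. Self-loops contribute 0.
#'
#' @param network a `cell_network`.
#' @return Named numeric vector, one entry per visible node.
#' @export
node_degree <- function(network) {
  adj <- visible_adjacency(network)
  vapply(adj, length, numeric(1))
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness over unordered distinct pairs of
#' the unweighted visible subgraph, computed with Brandes' dependency
#' accumulation (one BFS per source). Disconnected graphs are handled
#' naturally: unreachable pairs contribute nothing.
#'
#' @param network a `cell_network`.
#' @return Named numeric vector (>= 0), one entry per visible node.
#' @export
node_betweenness <- function(network) {
  adj <- visible_adjacency(network)
  ids <- names(adj)
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  nbr <- lapply(adj, function(v) unname(idx[v]))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- c(s); head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      order_visited <- c(order_visited, v)
      for (w in nbr[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc / 2, ids) # each unordered pair was counted from both ends
}

#' Local clustering coefficient
#'
#' `2 * (edges among neighbors) / (k * (k - 1))` for a node of degree `k`;
#' nodes with fewer than two neighbors get 0. Computed over the visible
#' subgraph.
#'
#' @param network a `cell_network`.
#' @return Named numeric vector in [0, 1], one entry per visible node.
#' @export
node_clustering <- function(network) {
  adj <- visible_adjacency(network)
  ids <- names(adj)
  ekey <- character(0)
  for (id in ids) {
    if (length(adj[[id]]) > 0) {
      ekey <- c(ekey, paste(pmin(id, adj[[id]]), pmax(id, adj[[id]]), sep = "\r"))
    }
  }
  ekey <- unique(ekey)
  out <- stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    nb <- unique(adj[[id]])
    k <- length(nb)
    if (k < 2) next
    pairs <- utils::combn(sort(nb), 2)
    key <- paste(pairs[1, ], pairs[2, ], sep = "\r")
    out[id] <- 2 * sum(key %in% ekey) / (k * (k - 1))
  }
  out
}

#' Attach topology measures as node attributes
#'
#' Computes degree, betweenness, and clustering coefficient over the visible
#' subgraph and stores them as `[degree]`, `[betweenness]`, `[clustering
#' coefficient]` attributes on each visible node, so they can drive node
#' coloring like any other attribute.
#'
#' @param network a `cell_network`.
#' @return The network with measure attributes added.
#' @export
add_topology_measures <- function(network) {
  deg <- node_degree(network)
  btw <- node_betweenness(network)
  clu <- node_clustering(network)
  for (i in seq_len(nrow(network$nodes))) {
    id <- network$nodes$id[i]
    if (!id %in% names(deg)) next
    a <- network$nodes$atts[[i]]
    a[["[degree]"]] <- list(value = unname(deg[id]), type = "real")
    a[["[betweenness]"]] <- list(value = unname(btw[id]), type = "real")
    a[["[clustering coefficient]"]] <- list(value = unname(clu[id]), type = "real")
    network$nodes$atts[[i]] <- a
  }
  network
}

#' Per-compartment node counts
#'
#' Counts visible nodes per assigned compartment (unannotated and
#' unrecognized labels fall back to the cytosol) together with percentages
#' of the visible total; this is the data behind the donut chart.
#'
#' @param network a `cell_network`.
#' @return A data.frame of class `compartment_counts` with columns `label`,
#'   `count`, `percentage`, sorted by decreasing count then label. Empty
#'   networks yield zero rows.
#' @export
compartment_counts <- function(network) {
  vis <- network$nodes[network$nodes$visible, , drop = FALSE]
  if (nrow(vis) == 0) {
    out <- data.frame(label = character(0), count = integer(0),
                      percentage = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("compartment_counts", "data.frame")
    return(out)
  }
  lab <- assign_compartment(vis$selected_cc)
  tab <- table(lab)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percentage <- 100 * out$count / sum(out$count)
  out <- out[order(-out$count, out$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("compartment_counts", "data.frame")
  out
}

#' Write compartment counts as CSV
#'
#' Columns `label,count,percentage` (percentages with two decimals).
#'
#' @param counts a `compartment_counts` data.frame.
#' @param path output file path.
#' @export
write_counts_csv <- function(counts, path) {
  lines <- c("label,count,percentage",
             sprintf("%s,%d,%.2f", counts$label, counts$count, counts$percentage))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write topology measures as TSV
#'
#' @param network a `cell_network` (measures are computed here).
#' @param path output file path.
#' @export
write_metrics_tsv <- function(network, path) {
  deg <- node_degree(network)
  btw <- node_betweenness(network)
  clu <- node_clustering(network)
  ids <- names(deg)
  lines <- c("id\tdegree\tbetweenness\tclustering_coefficient",
             sprintf("%s\t%d\t%.6f\t%.6f", ids, as.integer(deg), btw[ids], clu[ids]))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
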