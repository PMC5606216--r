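# Shared fixtures and independent oracles, built in code.

# Build an XGMML document string from node/edge descriptions.
# nodes: list of lists with id, label (opt), atts (named chr vector),
#        list_atts (named list of chr vectors), x/y (opt)
# edges: 2-column matrix/data.frame of source, target
xgmml_doc <- function(nodes, edges = NULL, name = "fixture") {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  out <- c('<?xml version="1.0"?>',
           sprintf('<graph label="%s" xmlns="http://www.cs.rpi.edu/XGMML">', name))
  for (nd in nodes) {
    lab <- if (is.null(nd$label)) nd$id else nd$label
    out <- c(out, sprintf('<node id="%s" label="%s">', esc(nd$id), esc(lab)))
    for (an in names(nd$atts)) {
      out <- c(out, sprintf('<att name="%s" value="%s" type="string"/>',
                            an, esc(nd$atts[[an]])))
    }
    for (an in names(nd$list_atts)) {
      out <- c(out, sprintf('<att name="%s" type="list">', an),
               sprintf('<att name="%s" value="%s" type="string"/>',
                       an, esc(nd$list_atts[[an]])),
               '</att>')
    }
    if (!is.null(nd$x)) {
      out <- c(out, sprintf('<graphics x="%s" y="%s"/>', nd$x, nd$y))
    }
    out <- c(out, "</node>")
  }
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    for (k in seq_len(nrow(edges))) {
      out <- c(out, sprintf('<edge source="%s" target="%s"/>',
                            esc(edges[k, 1]), esc(edges[k, 2])))
    }
  }
  paste(c(out, "</graph>"), collapse = "\n")
}

# In-code cell_network builder for graph-measure tests.
make_net <- function(edges = NULL, ids = NULL, cc = NULL, labels = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(edges)))
  n <- length(ids)
  if (is.null(cc)) cc <- rep("cytosol", n)
  if (is.null(labels)) labels <- ids
  nodes <- data.frame(id = ids, label = labels, selected_cc = cc,
                      x = rep(NA_real_, n), y = rep(NA_real_, n),
                      visible = rep(TRUE, n),
                      fixed = rep(FALSE, n), stringsAsFactors = FALSE)
  nodes$cellular_components <- I(rep(list(character(0)), n))
  nodes$atts <- I(rep(list(list()), n))
  if (is.null(edges) || nrow(as.matrix(edges)) == 0) {
    ed <- data.frame(source = character(0), target = character(0),
                     is_loop = logical(0), visible = logical(0),
                     stringsAsFactors = FALSE)
    ed$atts <- I(list())
  } else {
    edges <- as.matrix(edges)
    ed <- data.frame(source = edges[, 1], target = edges[, 2],
                     is_loop = edges[, 1] == edges[, 2],
                     visible = rep(TRUE, nrow(edges)),
                     stringsAsFactors = FALSE)
    ed$atts <- I(rep(list(list()), nrow(edges)))
  }
  structure(list(name = "test", nodes = nodes, edges = ed),
            class = "cell_network")
}

# Semantic network equality (order-independent).
net_equal <- function(a, b) {
  na <- a$nodes[order(a$nodes$id), ]
  nb <- b$nodes[order(b$nodes$id), ]
  if (!identical(na$id, nb$id)) return(FALSE)
  if (!identical(na$label, nb$label)) return(FALSE)
  if (!identical(na$selected_cc, nb$selected_cc)) return(FALSE)
  if (!identical(lapply(na$cellular_components, sort),
                 lapply(nb$cellular_components, sort))) return(FALSE)
  ek <- function(n) sort(paste(pmin(n$edges$source, n$edges$target),
                               pmax(n$edges$source, n$edges$target)))
  identical(ek(a), ek(b))
}

# Brute-force betweenness: enumerate every simple path per pair, keep the
# shortest, and split credit over interior vertices. Independent of Brandes.
bf_betweenness <- function(ids, edges) {
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (!is.null(edges) && nrow(as.matrix(edges)) > 0) {
    edges <- as.matrix(edges)
    for (k in seq_len(nrow(edges))) {
      a <- idx[[edges[k, 1]]]; b <- idx[[edges[k, 2]]]
      if (a == b) next
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  bc <- numeric(n)
  if (n < 3) return(setNames(bc, ids))
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- list()
    dfs <- function(v, visited) {
      if (v == t) { paths[[length(paths) + 1]] <<- visited; return(invisible()) }
      for (w in adj[[v]]) if (!(w %in% visited)) dfs(w, c(visited, w))
    }
    dfs(s, s)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1))
    short <- paths[lens == min(lens)]
    for (p in short) {
      inner <- setdiff(p, c(s, t))
      bc[inner] <- bc[inner] + 1 / length(short)
    }
  }
  setNames(bc, ids)
}

# All labelled graphs on `n` nodes as edge lists (n small!).
all_graphs <- function(n, ids = letters[1:n]) {
  pairs <- t(combn(ids, 2))
  m <- nrow(pairs)
  lapply(0:(2^m - 1), function(mask) {
    sel <- bitwAnd(mask, 2^(0:(m - 1))) > 0
    pairs[sel, , drop = FALSE]
  })
}

# Membership audit across a whole simulation run.
audit_run <- function(net, diagram, params, n_ticks) {
  st <- init_layout(net, diagram, params)
  ok <- all(subcellnet:::membership_ok(diagram, st$labels, st$pos,
                                       params$node_r))
  for (i in seq_len(n_ticks)) {
    st <- tick(st, net, diagram, params)
    ok <- ok && all(subcellnet:::membership_ok(diagram, st$labels, st$pos,
                                               params$node_r))
  }
  list(ok = ok, state = st)
}
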