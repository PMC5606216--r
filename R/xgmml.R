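# XGMML (Cytoscape dialect) input and output.
#
# The only contract imposed on input networks is that nodes may carry a
# single-valued compartment attribute named "Selected CC" (IIS convention)
# or "Localization" (InnateDB convention), and optionally a multivalued
# "Cellular Component" attribute. Duplicate nodes (same id) and duplicate
# unordered edges are collapsed on load, keeping the first occurrence.

#' Parse an XGMML network
#'
#' Reads a Cytoscape-dialect XGMML document into a `cell_network`. The
#' single-valued compartment annotation is taken from the "Selected CC"
#' attribute if present, else from "Localization", else left empty (such
#' nodes fall back to the cytosol at layout time). A multivalued
#' "Cellular Component" attribute -- either an XGMML list att or a single
#' comma-separated string -- populates `cellular_components`; its values are
#' trimmed and lower-cased. Attribute-name matching is case-insensitive.
#'
#' Duplicate nodes and duplicate unordered edges are collapsed keeping the
#' first occurrence's attributes; edges are undirected, so `(a,b)` and
#' `(b,a)` are the same edge. Self-loops are retained but flagged (they
#' exert no link force in the simulation).
#'
#' @param x path to an XGMML file, or a single string containing XGMML.
#' @return A `cell_network`: list with `name`, `nodes` (data.frame with
#'   columns `id`, `label`, `selected_cc`, `x`, `y`, `visible`, `fixed` and
#'   list-columns `cellular_components`, `atts`) and `edges` (data.frame
#'   with `source`, `target`, `is_loop`, `visible` and list-column `atts`).
#' @export
parse_xgmml <- function(x) {
  doc <- xml2::read_xml(x)
  xml2::xml_ns_strip(doc)
  root <- if (xml2::xml_name(doc) == "graph") doc else
    xml2::xml_find_first(doc, ".//graph")
  if (inherits(root, "xml_missing")) stop("no <graph> element found in XGMML input")
  name <- xml2::xml_attr(root, "label")
  if (is.na(name)) name <- xml2::xml_attr(root, "id")
  if (is.na(name)) name <- "network"

  node_els <- xml2::xml_find_all(root, "./node")
  ids <- xml2::xml_attr(node_els, "id")
  labels <- xml2::xml_attr(node_els, "label")
  labels[is.na(labels)] <- ids[is.na(labels)]
  if (any(is.na(ids) | !nzchar(ids))) stop("node without an id attribute")

  n <- length(node_els)
  selected_cc <- character(n)
  ccs <- vector("list", n)
  atts <- vector("list", n)
  xs <- rep(NA_real_, n); ys <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- parse_atts(node_els[[i]])
    atts[[i]] <- a
    selected_cc[i] <- find_single_cc(a)
    ccs[[i]] <- find_multi_cc(a)
    g <- xml2::xml_find_first(node_els[[i]], "./graphics")
    if (!inherits(g, "xml_missing")) {
      xs[i] <- suppressWarnings(as.numeric(xml2::xml_attr(g, "x")))
      ys[i] <- suppressWarnings(as.numeric(xml2::xml_attr(g, "y")))
    }
  }
  keep <- !duplicated(ids)
  nk <- sum(keep)
  nodes <- data.frame(id = ids[keep], label = labels[keep],
                      selected_cc = selected_cc[keep],
                      x = xs[keep], y = ys[keep],
                      visible = rep(TRUE, nk), fixed = rep(FALSE, nk),
                      stringsAsFactors = FALSE)
  nodes$cellular_components <- I(ccs[keep])
  nodes$atts <- I(atts[keep])

  edge_els <- xml2::xml_find_all(root, "./edge")
  src <- xml2::xml_attr(edge_els, "source")
  tgt <- xml2::xml_attr(edge_els, "target")
  unknown <- setdiff(c(src, tgt), nodes$id)
  if (length(unknown) > 0) {
    stop("edge(s) reference unknown node id(s): ",
         paste(sort(unique(unknown)), collapse = ", "))
  }
  eatts <- lapply(edge_els, parse_atts)
  key <- paste(pmin(src, tgt), pmax(src, tgt), sep = "\r")
  ekeep <- !duplicated(key)
  edges <- data.frame(source = src[ekeep], target = tgt[ekeep],
                      is_loop = src[ekeep] == tgt[ekeep],
                      visible = rep(TRUE, sum(ekeep)), stringsAsFactors = FALSE)
  edges$atts <- I(eatts[ekeep])

  structure(list(name = name, nodes = nodes, edges = edges),
            class = "cell_network")
}

#' @export
print.cell_network <- function(x, ...) {
  cat("<cell_network> '", x$name, "': ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (", sum(x$edges$is_loop), " self-loops)\n", sep = "")
  cc <- table(assign_compartment(x$nodes$selected_cc))
  cat("  compartments:", paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Parse nested <att> elements into a named list of list(value=, type=).
# List atts recurse one level: value is a character vector of child values.
#' @keywords internal
parse_atts <- function(el) {
  att_els <- xml2::xml_find_all(el, "./att")
  out <- list()
  for (a in att_els) {
    nm <- xml2::xml_attr(a, "name")
    if (is.na(nm)) next
    ty <- xml2::xml_attr(a, "type")
    if (is.na(ty)) ty <- "string"
    if (identical(ty, "list")) {
      kids <- xml2::xml_find_all(a, "./att")
      val <- xml2::xml_attr(kids, "value")
      out[[nm]] <- list(value = val[!is.na(val)], type = "list")
    } else {
      raw <- xml2::xml_attr(a, "value")
      val <- switch(ty,
        integer = suppressWarnings(as.integer(raw)),
        real = suppressWarnings(as.numeric(raw)),
        raw)
      out[[nm]] <- list(value = val, type = ty)
    }
  }
  out
}

#' @keywords internal
att_by_name <- function(atts, name) {
  hit <- which(tolower(names(atts)) == tolower(name))
  if (length(hit) == 0) NULL else atts[[hit[1]]]
}

#' @keywords internal
find_single_cc <- function(atts) {
  for (nm in c("Selected CC", "Localization")) {
    a <- att_by_name(atts, nm)
    if (!is.null(a) && length(a$value) >= 1 && !is.na(a$value[1])) {
      return(as.character(a$value[1]))
    }
  }
  ""
}

#' @keywords internal
find_multi_cc <- function(atts) {
  a <- att_by_name(atts, "Cellular Component")
  if (is.null(a)) return(character(0))
  vals <- as.character(a$value)
  if (!identical(a$type, "list") && length(vals) == 1) {
    vals <- strsplit(vals, ",", fixed = TRUE)[[1]]
  }
  vals <- tolower(trimws(vals))
  vals[nzchar(vals)]
}

#' @keywords internal
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' @keywords internal
format_att_value <- function(v, type) {
  if (type == "integer") return(as.character(as.integer(v)))
  if (type == "real") return(format(as.numeric(v), digits = 15, scientific = FALSE))
  as.character(v)
}

#' @keywords internal
serialize_atts <- function(atts, indent) {
  out <- character(0)
  for (nm in names(atts)) {
    a <- atts[[nm]]
    if (identical(a$type, "list")) {
      kid <- sprintf('%s  <att name="%s" value="%s" type="string"/>',
                     indent, xml_escape(nm), xml_escape(as.character(a$value)))
      out <- c(out, sprintf('%s<att name="%s" type="list">', indent, xml_escape(nm)),
               kid, sprintf('%s</att>', indent))
    } else {
      out <- c(out, sprintf('%s<att name="%s" value="%s" type="%s"/>',
                            indent, xml_escape(nm),
                            xml_escape(format_att_value(a$value, a$type)), a$type))
    }
  }
  out
}

#' Write a network (optionally with layout coordinates) as XGMML
#'
#' Serializes a `cell_network` to XGMML. When a layout is supplied every node
#' gets a `<graphics x= y=/>` element with its coordinates; a node without a
#' position is an error. Re-parsing the emitted file recovers a semantically
#' identical network.
#'
#' @param network a `cell_network`.
#' @param path output file path.
#' @param layout optional layout state (see [init_layout()]); positions may
#'   also come from the network's own `x`/`y` columns when `layout` is NULL.
#' @return `path`, invisibly.
#' @export
write_xgmml <- function(network, path, layout = NULL) {
  nodes <- network$nodes
  pos <- NULL
  if (!is.null(layout)) {
    missing <- setdiff(nodes$id, rownames(layout$pos))
    if (length(missing) > 0) {
      stop("layout holds no position for node(s): ", paste(missing, collapse = ", "))
    }
    pos <- layout$pos[nodes$id, , drop = FALSE]
  } else if (!all(is.na(nodes$x))) {
    pos <- cbind(nodes$x, nodes$y)
  }
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf('<graph label="%s" directed="0" xmlns="http://www.cs.rpi.edu/XGMML">',
                     xml_escape(network$name)))
  for (i in seq_len(nrow(nodes))) {
    lines <- c(lines, sprintf('  <node id="%s" label="%s">',
                              xml_escape(nodes$id[i]), xml_escape(nodes$label[i])))
    atts <- nodes$atts[[i]]
    if (nzchar(nodes$selected_cc[i]) && is.null(att_by_name(atts, "Selected CC")) &&
        is.null(att_by_name(atts, "Localization"))) {
      atts[["Selected CC"]] <- list(value = nodes$selected_cc[i], type = "string")
    }
    ccs <- nodes$cellular_components[[i]]
    if (length(ccs) > 0 && is.null(att_by_name(atts, "Cellular Component"))) {
      atts[["Cellular Component"]] <- list(value = ccs, type = "list")
    }
    lines <- c(lines, serialize_atts(atts, "    "))
    if (!is.null(pos)) {
      if (any(is.na(pos[i, ]))) stop("node '", nodes$id[i], "' has no position")
      lines <- c(lines, sprintf('    <graphics type="ELLIPSE" x="%.6f" y="%.6f"/>',
                                pos[i, 1], pos[i, 2]))
    }
    lines <- c(lines, "  </node>")
  }
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    ea <- network$edges$atts[[i]]
    if (length(ea) == 0) {
      lines <- c(lines, sprintf('  <edge source="%s" target="%s"/>',
                                xml_escape(e$source), xml_escape(e$target)))
    } else {
      lines <- c(lines, sprintf('  <edge source="%s" target="%s">',
                                xml_escape(e$source), xml_escape(e$target)),
                 serialize_atts(ea, "    "), "  </edge>")
    }
  }
  lines <- c(lines, "</graph>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a plain-text coordinates table
#'
#' One row per node: `id`, `x`, `y`, `compartment` (tab-separated, positions
#' printed with six decimals so identical layouts yield byte-identical
#' tables).
#'
#' @inheritParams write_xgmml
#' @param layout layout state holding a position for every node.
#' @export
write_coords <- function(network, layout, path) {
  nodes <- network$nodes
  missing <- setdiff(nodes$id, rownames(layout$pos))
  if (length(missing) > 0) {
    stop("layout holds no position for node(s): ", paste(missing, collapse = ", "))
  }
  pos <- layout$pos[nodes$id, , drop = FALSE]
  comp <- assign_compartment(nodes$selected_cc)
  lines <- c("id\tx\ty\tcompartment",
             sprintf("%s\t%.6f\t%.6f\t%s", nodes$id, pos[, 1], pos[, 2], comp))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
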