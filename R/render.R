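# Deterministic SVG/PNG rendering of the cell diagram, network, bundles and
# donut chart. The SVG is assembled as text with fixed number formatting, so
# identical inputs give byte-identical documents; the PNG is drawn from the
# same scene with the png device.

.QUALITATIVE_PALETTE <- c(
  "#1B9E77", "#D95F02", "#7570B3", "#E7298A", "#66A61E", "#E6AB02",
  "#A6761D", "#666666", "#1F78B4", "#B2DF8A", "#FB9A99", "#CAB2D6")

#' Map attribute values to node colors
#'
#' Categorical values get a cycled qualitative palette with stable
#' assignment by first appearance; numeric values get a light-to-dark
#' sequential ramp over `[min, max]`, so the node with the darkest color
#' carries the highest value. Mixed or non-numeric input is treated as
#' categorical; a numeric column with a single distinct value maps to the
#' ramp midpoint (no degenerate division).
#'
#' @param values vector of attribute values (one per node).
#' @param kind `"auto"`, `"categorical"` or `"numeric"`.
#' @return A named character vector mapping each distinct value (as a
#'   string) to a 6-digit hex color, with attribute `kind`.
#' @export
node_color_mapping <- function(values, kind = c("auto", "categorical", "numeric")) {
  kind <- match.arg(kind)
  stopifnot(length(values) > 0)
  if (kind == "auto") {
    num <- suppressWarnings(as.numeric(values))
    kind <- if (all(!is.na(num[!is.na(values)])) && any(!is.na(values)))
      "numeric" else "categorical"
  }
  if (kind == "numeric") {
    v <- suppressWarnings(as.numeric(values))
    if (any(is.na(v))) kind <- "categorical"
  }
  if (kind == "numeric") {
    uv <- sort(unique(v))
    ramp <- grDevices::colorRampPalette(c("#FEE8C8", "#E34A33", "#7F0000"))
    if (length(uv) == 1) {
      cols <- stats::setNames(toupper(ramp(3)[2]), format_value(uv))
    } else {
      t <- (uv - min(uv)) / (max(uv) - min(uv))
      pal <- toupper(ramp(256))
      cols <- stats::setNames(pal[1 + round(t * 255)], format_value(uv))
    }
  } else {
    uv <- unique(as.character(values)) # first-appearance order, stable
    cols <- stats::setNames(
      .QUALITATIVE_PALETTE[((seq_along(uv) - 1) %% length(.QUALITATIVE_PALETTE)) + 1],
      uv)
  }
  attr(cols, "kind") <- kind
  cols
}

#' @keywords internal
format_value <- function(v) {
  if (is.numeric(v)) {
    out <- as.character(v)
  } else out <- as.character(v)
  out
}

# Extract a per-node attribute column: special names, then the att map.
#' @keywords internal
node_attribute_values <- function(network, name) {
  if (tolower(name) %in% c("selected cc", "localization", "compartment")) {
    return(assign_compartment(network$nodes$selected_cc))
  }
  if (tolower(name) == "label") return(network$nodes$label)
  vapply(network$nodes$atts, function(a) {
    at <- att_by_name(a, name)
    if (is.null(at) || length(at$value) == 0) NA_character_
    else as.character(at$value[1])
  }, character(1))
}

#' @keywords internal
fmt6 <- function(x) sprintf("%.6f", x)

#' @keywords internal
fmt2 <- function(x) sprintf("%.2f", x)

# One donut segment as an SVG path (angles in radians, clockwise from 12
# o'clock); a full-circle segment is split into two half arcs.
#' @keywords internal
donut_segment_path <- function(cx, cy, r0, r1, a0, a1) {
  pt <- function(r, a) c(cx + r * sin(a), cy - r * cos(a))
  if (a1 - a0 >= 2 * pi - 1e-9) {
    mid <- a0 + pi
    return(paste(donut_segment_path(cx, cy, r0, r1, a0, mid),
                 donut_segment_path(cx, cy, r0, r1, mid, a0 + 2 * pi)))
  }
  large <- if (a1 - a0 > pi) 1 else 0
  p1 <- pt(r1, a0); p2 <- pt(r1, a1); p3 <- pt(r0, a1); p4 <- pt(r0, a0)
  sprintf("M %s %s A %s %s 0 %d 1 %s %s L %s %s A %s %s 0 %d 0 %s %s Z",
          fmt2(p1[1]), fmt2(p1[2]), fmt2(r1), fmt2(r1), large,
          fmt2(p2[1]), fmt2(p2[2]), fmt2(p3[1]), fmt2(p3[2]),
          fmt2(r0), fmt2(r0), large, fmt2(p4[1]), fmt2(p4[2]))
}

#' Render the donut chart as an SVG fragment
#'
#' Arc angles are proportional to the per-compartment counts (they sum to a
#' full turn); each segment uses the compartment's diagram fill.
#'
#' @param counts a `compartment_counts` data.frame.
#' @param style a `cell_style`.
#' @param cx,cy donut center.
#' @param r_outer,r_inner outer and inner radii, px.
#' @return A character vector of SVG lines (empty for empty counts).
#' @export
render_donut <- function(counts, style = default_style(), cx = 80, cy = 80,
                         r_outer = 55, r_inner = 30) {
  if (nrow(counts) == 0) return(character(0))
  total <- sum(counts$count)
  ang <- 2 * pi * counts$count / total
  a1 <- cumsum(ang)
  a0 <- c(0, a1[-length(a1)])
  out <- sprintf('<g class="donut">')
  for (i in seq_len(nrow(counts))) {
    out <- c(out, sprintf('  <path class="donut-seg" d="%s" fill="%s" stroke="#FFFFFF" stroke-width="1"><title>%s: %d (%s%%)</title></path>',
                          donut_segment_path(cx, cy, r_inner, r_outer, a0[i], a1[i]),
                          style$fills[[counts$label[i]]],
                          xml_escape(counts$label[i]), counts$count[i],
                          fmt2(counts$percentage[i])))
  }
  c(out, "</g>")
}

#' Render the cell diagram and network as SVG
#'
#' Draws, back to front: the extracellular background, cell wall and plasma
#' membrane rings, the cytoplasm disc, nucleus and organelle circles (with
#' reduced-contrast contours), edges (straight lines, or bundle polylines
#' when supplied), node discs with dark contours, labels for selected
#' nodes, and the donut chart in the bottom-left corner when counts are
#' supplied. When a selection exists, unselected nodes are drawn with
#' reduced opacity. Output is byte-identical across runs for identical
#' inputs.
#'
#' @param network a `cell_network`.
#' @param diagram a `cell_diagram`.
#' @param layout a `layout_state` positioning every visible node.
#' @param bundles optional list of `bundle_polyline`s (from
#'   [bundle_edges()]).
#' @param counts optional `compartment_counts` for the donut chart.
#' @param selection optional `cell_selection`.
#' @param style a `cell_style`.
#' @param color_by optional attribute or measure name driving node fill.
#' @return A single SVG string.
#' @export
render_svg <- function(network, diagram, layout, bundles = NULL, counts = NULL,
                       selection = NULL, style = default_style(),
                       color_by = NULL) {
  w <- diagram$canvas_w; h <- diagram$canvas_h
  ctr <- diagram$cell_center
  fills <- style$fills
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            round(w), round(h), round(w), round(h)),
    sprintf('<rect class="extracellular" x="0" y="0" width="%d" height="%d" fill="%s"/>',
            round(w), round(h), fills[["extracellular"]]))

  circle <- function(class, cx, cy, r, fill, stroke, sw = 1, extra = "") {
    sprintf('<circle class="%s" cx="%s" cy="%s" r="%s" fill="%s" stroke="%s" stroke-width="%s"%s/>',
            class, fmt2(cx), fmt2(cy), fmt2(r), fill, stroke, fmt2(sw), extra)
  }
  if (diagram$has_wall) {
    out <- c(out, circle("cell-wall", ctr["x"], ctr["y"],
                         diagram$ring_radii["wall_outer"],
                         fills[["cell wall"]], style$cell_contour))
  }
  out <- c(out,
    circle("plasma-membrane", ctr["x"], ctr["y"],
           diagram$ring_radii["membrane_outer"],
           fills[["plasma membrane"]], style$cell_contour),
    circle("cytoplasm", ctr["x"], ctr["y"], diagram$ring_radii["cytoplasm"],
           fills[["cytosol"]], style$cell_contour))
  if (diagram$has_nucleus) {
    out <- c(out, circle("nucleus organelle", ctr["x"], ctr["y"],
                         diagram$ring_radii["nucleus"],
                         fills[["nucleus"]], style$organelle_contour))
  }
  for (lab in names(diagram$organelles)) {
    circ <- diagram$organelles[[lab]]
    out <- c(out, circle(paste0("organelle"), circ[1], circ[2], circ[3],
                         fills[[lab]], style$organelle_contour))
  }

  nodes <- network$nodes[network$nodes$visible, , drop = FALSE]
  pos <- layout$pos
  missing <- setdiff(nodes$id, rownames(pos))
  if (length(missing) > 0 || any(is.na(pos[nodes$id, ]))) {
    stop("layout holds no position for some visible node(s)")
  }

  if (is.null(bundles)) {
    e <- network$edges[network$edges$visible & !network$edges$is_loop, ,
                       drop = FALSE]
    for (i in seq_len(nrow(e))) {
      out <- c(out, sprintf('<line class="edge" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s" stroke-opacity="%s"/>',
                            fmt6(pos[e$source[i], 1]), fmt6(pos[e$source[i], 2]),
                            fmt6(pos[e$target[i], 1]), fmt6(pos[e$target[i], 2]),
                            style$edge_stroke, fmt2(style$edge_width),
                            fmt2(style$edge_opacity)))
    }
  } else {
    for (b in bundles) {
      d <- paste0("M ", fmt2(b$points[1, 1]), " ", fmt2(b$points[1, 2]), " L ",
                  paste(fmt2(b$points[-1, 1]), fmt2(b$points[-1, 2]),
                        collapse = " L "))
      out <- c(out, sprintf('<path class="bundle" d="%s" fill="none" stroke="%s" stroke-width="%s" stroke-opacity="%s"/>',
                            d, style$bundle_stroke, fmt2(style$edge_width),
                            fmt2(style$bundle_opacity)))
    }
  }

  node_fill <- rep(style$node_fill, nrow(nodes))
  if (!is.null(color_by)) {
    vals <- node_attribute_values(network, color_by)[network$nodes$visible]
    map <- node_color_mapping(vals[!is.na(vals)])
    key <- as.character(vals)
    mapped <- map[key]
    node_fill[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  highlighted <- if (is.null(selection)) NULL else selection$highlighted
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$id[i]
    op <- if (!is.null(highlighted) && !(id %in% highlighted))
      style$unselected_opacity else 1
    out <- c(out, sprintf('<circle class="node" data-id="%s" cx="%s" cy="%s" r="%s" fill="%s" stroke="%s" stroke-width="1.00" opacity="%s"/>',
                          xml_escape(id), fmt6(pos[id, 1]), fmt6(pos[id, 2]),
                          fmt2(layout$node_r), node_fill[i],
                          style$node_contour, fmt2(op)))
  }

  sel_ids <- if (is.null(selection)) character(0) else selection$selected
  for (id in intersect(sel_ids, nodes$id)) {
    lab <- nodes$label[match(id, nodes$id)]
    out <- c(out, sprintf('<text class="node-label" x="%s" y="%s" font-family="%s" font-size="%d">%s</text>',
                          fmt6(pos[id, 1] + layout$node_r + 2),
                          fmt6(pos[id, 2] - layout$node_r - 2),
                          style$font_family, as.integer(style$label_size),
                          xml_escape(lab)))
  }

  if (!is.null(counts) && nrow(counts) > 0) {
    r_out <- 55
    out <- c(out, render_donut(counts, style,
                               cx = 15 + r_out, cy = h - 15 - r_out,
                               r_outer = r_out, r_inner = 30))
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

#' Write an SVG string to a file
#' @param svg SVG string from [render_svg()].
#' @param path output path.
#' @export
write_svg <- function(svg, path) {
  writeLines(svg, path, useBytes = TRUE)
  invisible(path)
}

#' Render the scene as a PNG
#'
#' Draws the same scene as [render_svg()] with the `png` graphics device at
#' a configurable resolution. The SVG remains the source of truth for exact
#' coordinates; the PNG is a raster convenience export.
#'
#' @inheritParams render_svg
#' @param path output PNG path.
#' @param dpi raster resolution (96 reproduces the SVG pixel size).
#' @export
render_png <- function(network, diagram, layout, path, bundles = NULL,
                       counts = NULL, selection = NULL,
                       style = default_style(), color_by = NULL, dpi = 96) {
  w <- diagram$canvas_w; h <- diagram$canvas_h
  grDevices::png(path, width = w * dpi / 96, height = h * dpi / 96, res = dpi)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot(NA, xlim = c(0, w), ylim = c(h, 0), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::rect(0, h, w, 0, col = style$fills[["extracellular"]], border = NA)
  ctr <- diagram$cell_center
  disc <- function(cx, cy, r, fill, border) {
    th <- seq(0, 2 * pi, length.out = 181)
    graphics::polygon(cx + r * cos(th), cy + r * sin(th), col = fill,
                      border = border)
  }
  if (diagram$has_wall) {
    disc(ctr["x"], ctr["y"], diagram$ring_radii["wall_outer"],
         style$fills[["cell wall"]], style$cell_contour)
  }
  disc(ctr["x"], ctr["y"], diagram$ring_radii["membrane_outer"],
       style$fills[["plasma membrane"]], style$cell_contour)
  disc(ctr["x"], ctr["y"], diagram$ring_radii["cytoplasm"],
       style$fills[["cytosol"]], style$cell_contour)
  if (diagram$has_nucleus) {
    disc(ctr["x"], ctr["y"], diagram$ring_radii["nucleus"],
         style$fills[["nucleus"]], style$organelle_contour)
  }
  for (lab in names(diagram$organelles)) {
    circ <- diagram$organelles[[lab]]
    disc(circ[1], circ[2], circ[3], style$fills[[lab]],
         style$organelle_contour)
  }
  pos <- layout$pos
  if (is.null(bundles)) {
    e <- network$edges[network$edges$visible & !network$edges$is_loop, ,
                       drop = FALSE]
    if (nrow(e) > 0) {
      graphics::segments(pos[e$source, 1], pos[e$source, 2],
                         pos[e$target, 1], pos[e$target, 2],
                         col = grDevices::adjustcolor(style$edge_stroke,
                                                      style$edge_opacity),
                         lwd = style$edge_width)
    }
  } else {
    for (b in bundles) {
      graphics::lines(b$points[, 1], b$points[, 2],
                      col = grDevices::adjustcolor(style$bundle_stroke,
                                                   style$bundle_opacity),
                      lwd = style$edge_width)
    }
  }
  nodes <- network$nodes[network$nodes$visible, , drop = FALSE]
  node_fill <- rep(style$node_fill, nrow(nodes))
  if (!is.null(color_by)) {
    vals <- node_attribute_values(network, color_by)[network$nodes$visible]
    map <- node_color_mapping(vals[!is.na(vals)])
    mapped <- map[as.character(vals)]
    node_fill[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  op <- rep(1, nrow(nodes))
  if (!is.null(selection)) {
    op[!(nodes$id %in% selection$highlighted)] <- style$unselected_opacity
  }
  rgbm <- grDevices::col2rgb(node_fill) / 255
  bg <- grDevices::rgb(rgbm[1, ], rgbm[2, ], rgbm[3, ], alpha = op)
  graphics::symbols(pos[nodes$id, 1], pos[nodes$id, 2],
                    circles = rep(layout$node_r, nrow(nodes)), inches = FALSE,
                    add = TRUE, bg = bg, fg = style$node_contour)
  invisible(path)
}
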