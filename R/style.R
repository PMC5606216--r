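# Style sheet: diagram proportions, compartment fills, contour contrast.

# Fixed compartment -> fill assignment from a "BrBG" diverging ramp over the
# canonical label order, so the same compartment always gets the same color
# regardless of which network is loaded.
#' @keywords internal
default_fills <- function() {
  cols <- grDevices::hcl.colors(length(.IIS_LABELS), "BrBG")
  stats::setNames(toupper(cols), .IIS_LABELS)
}

#' Default style sheet
#'
#' Styling follows the contrast rules of the cell-diagram view: cell contour
#' lines are light (they are only a reference), organelle contours have
#' reduced contrast (those regions are dense with edge crossings), node
#' contours are dark, and when a selection exists the unselected nodes are
#' drawn with reduced opacity. Compartment fills come from a fixed
#' ColorBrewer-style "BrBG" diverging assignment.
#'
#' @param ... overrides for any style key.
#' @return A named list of class `cell_style`.
#' @export
default_style <- function(...) {
  s <- list(
    margin = 10,                 # canvas margin around the outermost ring, px
    wall_frac = 0.05,            # cell wall thickness as a fraction of R
    membrane_frac = 0.05,        # plasma membrane thickness as a fraction of R
    nucleus_frac = 0.22,         # nucleus radius as a fraction of R
    organelle_ring_frac = 0.55,  # radius of the organelle placement ring
    organelle_frac = 0.12,       # default organelle radius as a fraction of R
    fills = default_fills(),
    canvas_fill = "#FFFFFF",
    cell_contour = "#BBBBBB",    # light: reference only
    organelle_contour = "#AAAAAA", # reduced contrast in dense regions
    node_contour = "#333333",    # dark by default
    node_fill = "#888888",
    node_r = 5,
    unselected_opacity = 0.25,
    edge_stroke = "#666666",
    edge_opacity = 0.5,
    edge_width = 0.7,
    bundle_stroke = "#555555",
    bundle_opacity = 0.35,
    label_selected_only = TRUE,
    label_size = 11,
    font_family = "sans-serif"
  )
  ovr <- list(...)
  s[names(ovr)] <- ovr
  validate_style(s)
  structure(s, class = "cell_style")
}

#' @keywords internal
validate_style <- function(s) {
  hexes <- c(s$fills, s$canvas_fill, s$cell_contour, s$organelle_contour,
             s$node_contour, s$node_fill, s$edge_stroke, s$bundle_stroke)
  bad <- !grepl("^#[0-9A-Fa-f]{6}$", hexes)
  if (any(bad)) stop("invalid 6-digit hex color(s): ", paste(hexes[bad], collapse = ", "))
  for (op in c(s$unselected_opacity, s$edge_opacity, s$bundle_opacity)) {
    if (!is.numeric(op) || op < 0 || op > 1) stop("opacity values must be in [0, 1]")
  }
  invisible(s)
}

#' Read a key-value style configuration file
#'
#' Plain-text `key = value` lines (comments with `#`); numeric values are
#' converted, `fills.<label>` keys override individual compartment fills.
#' Unspecified keys keep their defaults.
#'
#' @param path file path.
#' @return A `cell_style` list.
#' @export
read_style <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  s <- default_style()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed style line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    if (startsWith(key, "fills.")) {
      lab <- canonical_label(sub("^fills\\.", "", key))
      if (is.na(lab)) stop("unknown compartment in style key: ", key)
      s$fills[[lab]] <- val
    } else if (key %in% names(s)) {
      s[[key]] <- if (!is.na(num)) num else val
    } else {
      stop("unknown style key: ", key)
    }
  }
  validate_style(s)
  s
}
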