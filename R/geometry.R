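# Circle-only cell diagram: construction, region membership, organelle moves.
#
# All compartments are circles or rings, which keeps both the membership test
# and the constraint projection a matter of one distance computation per
# circle.

#' Build the cell diagram for a set of annotated compartments
#'
#' Constructs the canvas-space geometry of the cell: concentric rings for
#' cell wall, plasma membrane and cytoplasm, a central nucleus disc, and one
#' circle per free-floating organelle. Only compartments actually annotated
#' in the network are drawn; in particular the cell wall ring is omitted when
#' no node is annotated to it (the plasma membrane then becomes the outermost
#' ring), and unused organelles are pruned.
#'
#' Proportions relative to `R = min(canvas_w, canvas_h)/2 - margin`:
#' wall and membrane thickness 0.05 R each, nucleus radius 0.22 R, organelles
#' on a ring of radius 0.55 R with default radius 0.12 R (shrunk as needed so
#' all organelle circles fit on the ring without overlap).
#'
#' @param present_labels character vector of canonical compartment labels
#'   present in the network (see [assign_compartment()]).
#' @param canvas_w,canvas_h canvas size in px.
#' @param style style list, see [default_style()]; only the geometric keys
#'   (`margin`, `wall_frac`, `membrane_frac`, `nucleus_frac`,
#'   `organelle_ring_frac`, `organelle_frac`) are used here.
#' @return An object of class `cell_diagram`: a list with `canvas_w`,
#'   `canvas_h`, `cell_center`, `ring_radii` (named, strictly increasing),
#'   `has_wall`, `has_nucleus`, `organelles` (named list of `c(cx, cy, r)`),
#'   and `present_labels`.
#' @export
build_cell_diagram <- function(present_labels, canvas_w = 800, canvas_h = 600,
                               style = default_style()) {
  stopifnot(canvas_w > 0, canvas_h > 0)
  labs <- sort(unique(canonical_label(present_labels)))
  labs <- labs[!is.na(labs)]
  cx <- canvas_w / 2
  cy <- canvas_h / 2
  R <- min(canvas_w, canvas_h) / 2 - style$margin
  if (R <= 0) stop("canvas too small for the configured margin")

  has_wall <- "cell wall" %in% labs
  has_nucleus <- "nucleus" %in% labs

  wall_outer <- R
  pm_outer <- if (has_wall) R * (1 - style$wall_frac) else R
  pm_inner <- pm_outer - R * style$membrane_frac
  nuc_r <- R * style$nucleus_frac

  ring_radii <- c(cytoplasm = pm_inner, membrane_outer = pm_outer)
  if (has_nucleus) ring_radii <- c(nucleus = nuc_r, ring_radii)
  if (has_wall) ring_radii <- c(ring_radii, wall_outer = wall_outer)
  if (any(diff(ring_radii) <= 0)) {
    stop("ring radii are not strictly increasing; check style fractions")
  }

  reg <- compartment_registry()
  org_labels <- sort(labs[labs %in%
    reg$label[reg$region_kind == "organelle_disc"] & labs != "nucleus"])
  organelles <- list()
  if (length(org_labels) > 0) {
    n <- length(org_labels)
    a <- R * style$organelle_ring_frac
    r_org <- R * style$organelle_frac
    if (n > 1) {
      # largest radius for n non-overlapping circles centered on the ring
      r_org <- min(r_org, 0.98 * a * sin(pi / n))
    }
    r_org <- min(r_org, 0.98 * (pm_inner - a))            # inside cytoplasm
    if (has_nucleus) r_org <- min(r_org, 0.98 * (a - nuc_r)) # outside nucleus
    if (r_org <= 0) {
      stop("cannot pack ", n, " organelle circles; reduce organelle_frac ",
           "or enlarge the canvas")
    }
    ang <- 2 * pi * (seq_len(n) - 1) / n - pi / 2
    for (i in seq_len(n)) {
      organelles[[org_labels[i]]] <-
        c(cx = cx + a * cos(ang[i]), cy = cy + a * sin(ang[i]), r = r_org)
    }
    # construction invariant: pairwise non-overlap
    if (n > 1) {
      cen <- do.call(rbind, organelles)
      d <- as.matrix(stats::dist(cen[, 1:2]))
      diag(d) <- Inf
      if (any(d < 2 * r_org - 1e-9)) {
        stop("organelle circles overlap at construction; reduce organelle_frac")
      }
    }
  }

  structure(list(
    canvas_w = canvas_w, canvas_h = canvas_h,
    cell_center = c(x = cx, y = cy),
    ring_radii = ring_radii,
    has_wall = has_wall, has_nucleus = has_nucleus,
    organelles = organelles,
    present_labels = labs
  ), class = "cell_diagram")
}

#' @export
print.cell_diagram <- function(x, ...) {
  cat("<cell_diagram> canvas", x$canvas_w, "x", x$canvas_h, "px\n")
  cat("  rings:", paste(sprintf("%s=%.1f", names(x$ring_radii), x$ring_radii),
                        collapse = ", "), "\n")
  cat("  organelles:", if (length(x$organelles) == 0) "(none)" else
    paste(names(x$organelles), collapse = ", "), "\n")
  invisible(x)
}

# Governing circle of an organelle-disc label: c(cx, cy, r).
#' @keywords internal
diagram_circle <- function(diagram, label) {
  if (label == "nucleus") {
    if (!diagram$has_nucleus) stop("nucleus is not present in this diagram")
    return(c(cx = unname(diagram$cell_center["x"]),
             cy = unname(diagram$cell_center["y"]),
             r = unname(diagram$ring_radii["nucleus"])))
  }
  circ <- diagram$organelles[[label]]
  if (is.null(circ)) stop("compartment '", label, "' has no circle in this diagram")
  circ
}

# Circles excluded from the cytosol free region: nucleus + all organelles.
# Returns a matrix with columns cx, cy, r (0 rows if none).
#' @keywords internal
excluded_circles <- function(diagram) {
  rows <- diagram$organelles
  if (diagram$has_nucleus) {
    rows <- c(list(nucleus = diagram_circle(diagram, "nucleus")), rows)
  }
  if (length(rows) == 0) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("cx", "cy", "r"))))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("cx", "cy", "r")
  m
}

# Inner radius of the innermost annulus = cytoplasm disc radius.
#' @keywords internal
cytoplasm_radius <- function(diagram) unname(diagram$ring_radii["cytoplasm"])

# Outer radius of the outermost ring (wall if present, else membrane).
#' @keywords internal
outermost_radius <- function(diagram) unname(diagram$ring_radii[length(diagram$ring_radii)])

# Annulus bounds [inner, outer] for "plasma membrane" / "cell wall".
#' @keywords internal
annulus_bounds <- function(diagram, label) {
  rr <- diagram$ring_radii
  if (label == "plasma membrane") {
    c(inner = unname(rr["cytoplasm"]), outer = unname(rr["membrane_outer"]))
  } else if (label == "cell wall") {
    if (!diagram$has_wall) stop("cell wall is not present in this diagram")
    c(inner = unname(rr["membrane_outer"]), outer = unname(rr["wall_outer"]))
  } else {
    stop("'", label, "' is not an annulus compartment")
  }
}

#' Test whether a node disc lies inside its compartment region
#'
#' Returns `TRUE` iff the disc of radius `node_r` centered at `p` lies wholly
#' inside the region of `label`: inside the organelle circle for disc
#' compartments, between the two bounding circles for the cell wall and
#' plasma membrane, inside the cytoplasm disc but outside nucleus and every
#' organelle for the cytosol, and outside the outermost ring but inside the
#' canvas for the extracellular region. Comparisons are closed on the
#' region's own boundary, with tolerance `tol`.
#'
#' @param diagram a `cell_diagram`.
#' @param label canonical compartment label.
#' @param p numeric `c(x, y)`.
#' @param node_r node disc radius in px.
#' @param tol boundary tolerance in px.
#' @export
region_contains <- function(diagram, label, p, node_r = 0, tol = 1e-6) {
  membership_ok(diagram, label, matrix(p[1:2], ncol = 2), node_r, tol)[1]
}

# Vectorized membership over a position matrix (n x 2) with per-node labels.
#' @keywords internal
membership_ok <- function(diagram, labels, pos, node_r = 0, tol = 1e-6) {
  n <- nrow(pos)
  labels <- rep_len(labels, n)
  node_r <- rep_len(node_r, n)
  ok <- logical(n)
  ctr <- diagram$cell_center
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    x <- pos[idx, 1]; y <- pos[idx, 2]; nr <- node_r[idx]
    kind <- region_kind_of(lab)
    if (kind == "organelle_disc") {
      circ <- diagram_circle(diagram, lab)
      d <- sqrt((x - circ[1])^2 + (y - circ[2])^2)
      ok[idx] <- d + nr <= circ[3] + tol
    } else if (kind == "annulus") {
      b <- annulus_bounds(diagram, lab)
      d <- sqrt((x - ctr["x"])^2 + (y - ctr["y"])^2)
      ok[idx] <- (d - nr >= b["inner"] - tol) & (d + nr <= b["outer"] + tol)
    } else if (kind == "cytosol_free_region") {
      d <- sqrt((x - ctr["x"])^2 + (y - ctr["y"])^2)
      good <- d + nr <= cytoplasm_radius(diagram) + tol
      exc <- excluded_circles(diagram)
      if (nrow(exc) > 0) {
        for (k in seq_len(nrow(exc))) {
          dk <- sqrt((x - exc[k, 1])^2 + (y - exc[k, 2])^2)
          good <- good & (dk - nr >= exc[k, 3] - tol)
        }
      }
      ok[idx] <- good
    } else { # extracellular_region
      d <- sqrt((x - ctr["x"])^2 + (y - ctr["y"])^2)
      ok[idx] <- (d - nr >= outermost_radius(diagram) - tol) &
        (x - nr >= -tol) & (y - nr >= -tol) &
        (x + nr <= diagram$canvas_w + tol) & (y + nr <= diagram$canvas_h + tol)
    }
  }
  ok
}

#' Move an organelle, carrying its content
#'
#' Translates an organelle circle to a new center and rigidly translates
#' every node assigned to that compartment by the same displacement, so
#' relative positions within the organelle are preserved exactly. No
#' consistency check is applied to the destination: the organelle may be
#' dragged anywhere on the canvas, including the extracellular region.
#'
#' @param diagram a `cell_diagram`.
#' @param label organelle label (must have a circle in the diagram).
#' @param new_center numeric `c(x, y)`.
#' @param network optional `cell_network` whose node assignments identify the
#'   carried nodes.
#' @param layout optional layout state holding node positions.
#' @return If `layout` is `NULL` the updated diagram, else
#'   `list(diagram=, layout=)`.
#' @export
move_organelle <- function(diagram, label, new_center, network = NULL,
                           layout = NULL) {
  circ <- diagram_circle(diagram, label)
  delta <- c(new_center[1] - circ[1], new_center[2] - circ[2])
  if (label == "nucleus") {
    stop("the nucleus is part of the concentric ring structure and cannot be moved")
  }
  diagram$organelles[[label]][1:2] <- c(new_center[1], new_center[2])
  if (is.null(layout)) return(diagram)
  if (!is.null(network)) {
    lab <- assign_compartment(network$nodes$selected_cc)
    idx <- which(lab == label)
    if (length(idx) > 0) {
      ids <- network$nodes$id[idx]
      layout$pos[ids, 1] <- layout$pos[ids, 1] + delta[1]
      layout$pos[ids, 2] <- layout$pos[ids, 2] + delta[2]
      layout$prev_pos[ids, 1] <- layout$prev_pos[ids, 1] + delta[1]
      layout$prev_pos[ids, 2] <- layout$prev_pos[ids, 2] + delta[2]
    }
  }
  list(diagram = diagram, layout = layout)
}

# Draw n positions uniformly at random in a region (uses the current RNG
# stream). Rejection sampling for the cytosol free region and extracellular.
#' @keywords internal
sample_region <- function(diagram, label, n, node_r = 0) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  ctr <- diagram$cell_center
  kind <- region_kind_of(label)
  runif_disc <- function(n, cx, cy, rmin, rmax) {
    if (rmax <= rmin) stop("region '", label, "' has no admissible area for node radius ", node_r)
    r <- sqrt(stats::runif(n, rmin^2, rmax^2))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(cx + r * cos(th), cy + r * sin(th))
  }
  if (kind == "organelle_disc") {
    circ <- diagram_circle(diagram, label)
    return(runif_disc(n, circ[1], circ[2], 0, max(circ[3] - node_r, 0)))
  }
  if (kind == "annulus") {
    b <- annulus_bounds(diagram, label)
    return(runif_disc(n, ctr["x"], ctr["y"], b["inner"] + node_r, b["outer"] - node_r))
  }
  if (kind == "cytosol_free_region") {
    out <- matrix(NA_real_, n, 2)
    need <- seq_len(n)
    for (tries in 1:200) {
      cand <- runif_disc(length(need), ctr["x"], ctr["y"], 0,
                         cytoplasm_radius(diagram) - node_r)
      ok <- membership_ok(diagram, label, cand, node_r)
      out[need[ok], ] <- cand[ok, , drop = FALSE]
      need <- need[!ok]
      if (length(need) == 0) return(out)
    }
    stop("could not sample the cytosol free region; it may have no admissible area")
  }
  # extracellular_region
  out <- matrix(NA_real_, n, 2)
  need <- seq_len(n)
  for (tries in 1:200) {
    cand <- cbind(stats::runif(length(need), node_r, diagram$canvas_w - node_r),
                  stats::runif(length(need), node_r, diagram$canvas_h - node_r))
    ok <- membership_ok(diagram, label, cand, node_r)
    out[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
    if (length(need) == 0) return(out)
  }
  stop("could not sample the extracellular region; it may have no admissible area")
}
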