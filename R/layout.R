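# Compartment-constrained force-directed layout.
#
# The simulation follows the D3 v3 force layout mechanics: link springs,
# Barnes-Hut many-body charge, weak gravity, position-Verlet integration
# with friction, and a multiplicatively cooling temperature alpha. After the
# integration step of every tick each unpinned node is projected back into
# its assigned compartment region (radial projection onto the region
# border), and an optional quad-tree collision pass separates overlapping
# node discs.

#' Simulation parameters
#'
#' Defaults follow the D3 v3 force layout: `charge = -30` (negative repels;
#' more negative separates nodes further), `link_distance = 20` px,
#' `link_strength = 1`, `friction = 0.9`, Barnes-Hut opening angle
#' `theta = 0.8`, cooling from `alpha0 = 0.1` by a factor `alpha_decay =
#' 0.99` per tick until `alpha_min = 0.005`, `gravity = 0.1` (toward the
#' assigned region's centroid). `repulsive` scales the post-tick overlap
#' separation: 0 disables it, larger values separate overlapping nodes
#' faster at the cost of layout stability. The collision pass is enabled by
#' default and auto-disabled for networks larger than
#' `large_network_threshold` nodes.
#'
#' @param charge many-body force strength; negative repels.
#' @param link_distance spring rest length, px.
#' @param link_strength spring strength.
#' @param friction velocity retention per tick, in (0, 1].
#' @param theta Barnes-Hut opening angle.
#' @param alpha0,alpha_decay,alpha_min cooling schedule.
#' @param repulsive overlap-resolution strength, >= 0.
#' @param gravity pull toward the assigned region centroid.
#' @param collision_enabled logical or `NULL` (auto by network size).
#' @param large_network_threshold node count above which collisions default
#'   to off.
#' @param node_r node disc radius, px.
#' @param collision_padding extra separation between node discs, px.
#' @param seed integer seed for the initial placement.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(charge = -30, link_distance = 20, link_strength = 1,
                       friction = 0.9, theta = 0.8,
                       alpha0 = 0.1, alpha_decay = 0.99, alpha_min = 0.005,
                       repulsive = 1, gravity = 0.1,
                       collision_enabled = NULL,
                       large_network_threshold = 1000,
                       node_r = 5, collision_padding = 0, seed = 1L) {
  stopifnot(friction > 0, friction <= 1,
            alpha_decay > 0, alpha_decay < 1,
            repulsive >= 0, theta >= 0, node_r >= 0)
  structure(list(charge = charge, link_distance = link_distance,
                 link_strength = link_strength, friction = friction,
                 theta = theta, alpha0 = alpha0, alpha_decay = alpha_decay,
                 alpha_min = alpha_min, repulsive = repulsive,
                 gravity = gravity, collision_enabled = collision_enabled,
                 large_network_threshold = large_network_threshold,
                 node_r = node_r, collision_padding = collision_padding,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' @keywords internal
collisions_on <- function(params, n_nodes) {
  if (!is.null(params$collision_enabled)) return(isTRUE(params$collision_enabled))
  n_nodes <= params$large_network_threshold
}

#' Project a point into its compartment region
#'
#' Radial constraint projection. For an organelle disc, a node outside the
#' circle is moved radially onto the inner border: with `R` the distance
#' from the compartment center and `r_eff = r - node_r` the effective
#' radius, the new position is `center + (r_eff / R) (p - center)`. For the
#' cytosol free region the same projection runs in the opposite direction,
#' pushing a node out of the nucleus or an organelle onto its outer border
#' and clamping it inside the cytoplasm disc. Cell wall and plasma membrane
#' check two constraints, clamping the radial distance into
#' `[r_inner + node_r, r_outer - node_r]`. The extracellular region clamps
#' outside the outermost ring and inside the canvas. A point already
#' satisfying its region is returned unchanged; a point exactly at the
#' center of an excluding circle is displaced by `node_r` along +x before
#' projecting, keeping the operation total and deterministic.
#'
#' @param p numeric `c(x, y)`.
#' @param label canonical compartment label.
#' @param diagram a `cell_diagram`.
#' @param node_r node disc radius, px.
#' @return The projected point `c(x, y)`.
#' @export
constrain_to_region <- function(p, label, diagram, node_r = 0) {
  out <- constrain_positions(matrix(p[1:2], ncol = 2), label, diagram, node_r)
  c(out[1, 1], out[1, 2])
}

# Radial projection of rows of `pos` (k x 2) onto a circle border.
# outward = FALSE: points with R > r move onto the circle (inner border);
# outward = TRUE: points with R < r move onto the circle (outer border).
#' @keywords internal
project_radial <- function(pos, cx, cy, r, outward = FALSE) {
  dx <- pos[, 1] - cx
  dy <- pos[, 2] - cy
  R <- sqrt(dx^2 + dy^2)
  viol <- if (outward) R < r else R > r
  if (!any(viol)) return(pos)
  deg <- viol & R < 1e-12
  if (any(deg)) { # degenerate center hit: deterministic +x displacement
    dx[deg] <- 1e-9
    R[deg] <- 1e-9
  }
  s <- r / R[viol]
  pos[viol, 1] <- cx + s * dx[viol]
  pos[viol, 2] <- cy + s * dy[viol]
  pos
}

# Vectorized constraint projection; `labels` recycled over rows of pos.
#' @keywords internal
constrain_positions <- function(pos, labels, diagram, node_r = 0) {
  n <- nrow(pos)
  labels <- rep_len(labels, n)
  ctr <- diagram$cell_center
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    sub <- pos[idx, , drop = FALSE]
    kind <- region_kind_of(lab)
    if (kind == "organelle_disc") {
      circ <- diagram_circle(diagram, lab)
      sub <- project_radial(sub, circ[1], circ[2], max(circ[3] - node_r, 0))
    } else if (kind == "annulus") {
      b <- annulus_bounds(diagram, lab)
      lo <- b["inner"] + node_r
      hi <- b["outer"] - node_r
      if (lo > hi) stop("annulus '", lab, "' too thin for node radius ", node_r)
      sub <- project_radial(sub, ctr["x"], ctr["y"], hi, outward = FALSE)
      sub <- project_radial(sub, ctr["x"], ctr["y"], lo, outward = TRUE)
    } else if (kind == "cytosol_free_region") {
      exc <- excluded_circles(diagram)
      r_cyto <- cytoplasm_radius(diagram) - node_r
      for (pass in 1:25) {
        sub <- project_radial(sub, ctr["x"], ctr["y"], r_cyto, outward = FALSE)
        if (nrow(exc) > 0) {
          for (k in seq_len(nrow(exc))) {
            sub <- project_radial(sub, exc[k, 1], exc[k, 2], exc[k, 3] + node_r,
                                  outward = TRUE)
          }
        }
        if (all(membership_ok(diagram, lab, sub, node_r, tol = 1e-9))) break
      }
    } else { # extracellular_region
      r_out <- outermost_radius(diagram) + node_r
      for (pass in 1:25) {
        sub[, 1] <- pmin(pmax(sub[, 1], node_r), diagram$canvas_w - node_r)
        sub[, 2] <- pmin(pmax(sub[, 2], node_r), diagram$canvas_h - node_r)
        sub <- project_radial(sub, ctr["x"], ctr["y"], r_out, outward = TRUE)
        if (all(membership_ok(diagram, lab, sub, node_r, tol = 1e-9))) break
      }
      # final canvas clamp cannot re-enter the ring: corners are admissible
      sub[, 1] <- pmin(pmax(sub[, 1], node_r), diagram$canvas_w - node_r)
      sub[, 2] <- pmin(pmax(sub[, 2], node_r), diagram$canvas_h - node_r)
    }
    pos[idx, ] <- sub
  }
  pos
}

#' Initialize the layout state
#'
#' Places every node uniformly at random inside its assigned compartment
#' region using `params$seed` (identical seeds give identical placements).
#' Nodes whose XGMML carried coordinates start there instead, projected into
#' their region; explicitly supplied `start` positions override both, and
#' ids listed in `pinned` are held exactly where given, even outside their
#' region (user override).
#'
#' @param network a `cell_network`.
#' @param diagram a `cell_diagram` built from the network's labels.
#' @param params a `sim_params` list.
#' @param start optional data.frame with columns `id`, `x`, `y`.
#' @param pinned character vector of node ids to pin.
#' @return A `layout_state`: list with `pos` and `prev_pos` (matrices with
#'   node-id rownames), `alpha`, `tick_count`, `pinned`, `node_r`, and the
#'   per-node compartment assignment `labels`.
#' @export
init_layout <- function(network, diagram, params = sim_params(),
                        start = NULL, pinned = character()) {
  nodes <- network$nodes
  labels <- stats::setNames(assign_compartment(nodes$selected_cc), nodes$id)
  pos <- matrix(NA_real_, nrow(nodes), 2,
                dimnames = list(nodes$id, c("x", "y")))
  set.seed(params$seed)
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    pos[idx, ] <- sample_region(diagram, lab, length(idx), params$node_r)
  }
  has_xy <- !is.na(nodes$x) & !is.na(nodes$y)
  if (any(has_xy)) pos[has_xy, ] <- cbind(nodes$x[has_xy], nodes$y[has_xy])
  if (!is.null(start)) {
    sid <- as.character(start$id)
    unknown <- setdiff(sid, nodes$id)
    if (length(unknown) > 0) stop("start positions for unknown node(s): ",
                                  paste(unknown, collapse = ", "))
    pos[sid, ] <- cbind(start$x, start$y)
  }
  pinned <- unique(c(as.character(pinned), nodes$id[nodes$fixed]))
  unknown <- setdiff(pinned, nodes$id)
  if (length(unknown) > 0) stop("pinned unknown node(s): ",
                                paste(unknown, collapse = ", "))
  free <- setdiff(nodes$id, pinned)
  if (length(free) > 0) {
    pos[free, ] <- constrain_positions(pos[free, , drop = FALSE],
                                       labels[free], diagram, params$node_r)
  }
  structure(list(pos = pos, prev_pos = pos, alpha = params$alpha0,
                 tick_count = 0L, pinned = pinned, node_r = params$node_r,
                 labels = labels),
            class = "layout_state")
}

#' @export
print.layout_state <- function(x, ...) {
  cat("<layout_state>", nrow(x$pos), "nodes, tick", x$tick_count,
      sprintf("alpha=%.4f", x$alpha),
      if (length(x$pinned)) paste0("(", length(x$pinned), " pinned)") else "", "\n")
  invisible(x)
}

#' Advance the simulation by one tick
#'
#' Applies, in order: link spring forces toward `link_distance`; Barnes-Hut
#' many-body charge forces; weak gravity toward each node's region centroid;
#' position-Verlet integration with friction, forces scaled by the current
#' alpha; constraint projection of every unpinned node back into its
#' compartment; and, when enabled, the quad-tree collision pass. Alpha is
#' then multiplied by `alpha_decay`. Only visible nodes participate; pinned
#' nodes never move.
#'
#' @param state a `layout_state`.
#' @inheritParams init_layout
#' @return The updated `layout_state`.
#' @export
tick <- function(state, network, diagram, params = sim_params()) {
  nodes <- network$nodes
  vis_ids <- nodes$id[nodes$visible]
  nv <- length(vis_ids)
  if (nv == 0) {
    state$alpha <- state$alpha * params$alpha_decay
    state$tick_count <- state$tick_count + 1L
    return(state)
  }
  pos <- state$pos[vis_ids, , drop = FALSE]
  prev <- state$prev_pos[vis_ids, , drop = FALSE]
  labels <- state$labels[vis_ids]
  idx_of <- stats::setNames(seq_len(nv), vis_ids)

  F <- matrix(0, nv, 2)

  # (1) link springs, visible non-loop edges only
  e <- network$edges
  ev <- e[e$visible & !e$is_loop & e$source %in% vis_ids & e$target %in% vis_ids, ,
          drop = FALSE]
  if (nrow(ev) > 0) {
    si <- idx_of[ev$source]
    ti <- idx_of[ev$target]
    dx <- pos[ti, 1] - pos[si, 1]
    dy <- pos[ti, 2] - pos[si, 2]
    d <- sqrt(dx^2 + dy^2)
    ok <- d > 1e-9
    f <- numeric(nrow(ev))
    f[ok] <- params$link_strength * (d[ok] - params$link_distance) / d[ok]
    fx <- 0.5 * f * dx
    fy <- 0.5 * f * dy
    acc <- function(v, i) { out <- numeric(nv); s <- tapply(v, i, sum); out[as.integer(names(s))] <- s; out }
    F[, 1] <- F[, 1] + acc(fx, si) - acc(fx, ti)
    F[, 2] <- F[, 2] + acc(fy, si) - acc(fy, ti)
  }

  # (2) many-body charge via Barnes-Hut (k > 0 repels for negative charge)
  if (params$charge != 0 && nv > 1) {
    F <- F + .bh_repulsion(pos[, 1], pos[, 2], -params$charge, params$theta)
  }

  # (3) weak gravity toward the assigned region's centroid
  if (params$gravity > 0) {
    cen <- region_centroids(diagram, labels)
    F <- F + params$gravity * (cen - pos)
  }

  # (4) position-Verlet with friction; forces scaled by alpha
  vel <- (pos - prev) * params$friction
  newpos <- pos + vel + state$alpha * F
  free <- !(vis_ids %in% state$pinned)
  pos2 <- pos
  pos2[free, ] <- newpos[free, , drop = FALSE]

  # (5) constraint projection for every unpinned visible node
  if (any(free)) {
    pos2[free, ] <- constrain_positions(pos2[free, , drop = FALSE],
                                        labels[free], diagram, state$node_r)
  }

  state$prev_pos[vis_ids, ] <- pos
  state$pos[vis_ids, ] <- pos2

  # (6) collision resolution
  if (collisions_on(params, nv) && params$repulsive > 0) {
    state <- resolve_collisions(state, params, network = network,
                                diagram = diagram)
  }

  state$alpha <- state$alpha * params$alpha_decay
  state$tick_count <- state$tick_count + 1L
  state
}

# Per-node gravity centroid: organelle discs pull toward their own center,
# every other region toward the cell center (projection keeps ring nodes on
# their annulus, so the tangential distribution is unaffected).
#' @keywords internal
region_centroids <- function(diagram, labels) {
  n <- length(labels)
  cen <- matrix(rep(diagram$cell_center, each = n), n, 2)
  for (lab in unique(labels)) {
    if (region_kind_of(lab) == "organelle_disc") {
      circ <- diagram_circle(diagram, lab)
      idx <- labels == lab
      cen[idx, 1] <- circ[1]
      cen[idx, 2] <- circ[2]
    }
  }
  cen
}

#' Resolve node-disc overlaps with a quad-tree pass
#'
#' Enumerates overlapping node pairs (center distance below the sum of the
#' two disc radii plus padding) through a quad-tree neighbor query -- never
#' all pairs -- and pushes each pair apart along its center line, each node
#' by `repulsive * overlap / 2`. A pinned node absorbs no displacement; its
#' partner takes the full share. Displaced nodes are then re-projected into
#' their compartment when a diagram is supplied. With `repulsive = 0` the
#' operation is the identity.
#'
#' @inheritParams tick
#' @param network optional; restricts the pass to visible nodes.
#' @param diagram optional; when given, membership is restored afterwards.
#' @return The updated `layout_state`.
#' @export
resolve_collisions <- function(state, params, network = NULL, diagram = NULL) {
  ids <- rownames(state$pos)
  if (!is.null(network)) ids <- network$nodes$id[network$nodes$visible]
  if (length(ids) < 2 || params$repulsive <= 0) return(state)
  pos <- state$pos[ids, , drop = FALSE]
  pinned <- ids %in% state$pinned
  res <- .resolve_collisions_cpp(pos[, 1], pos[, 2],
                                 rep(state$node_r, length(ids)),
                                 params$collision_padding, params$repulsive,
                                 pinned)
  newpos <- cbind(res$x, res$y)
  moved <- res$moved
  if (any(moved) && !is.null(diagram)) {
    newpos[moved, ] <- constrain_positions(newpos[moved, , drop = FALSE],
                                           state$labels[ids][moved], diagram,
                                           state$node_r)
  }
  state$pos[ids, ] <- newpos
  state
}

#' Run the simulation until it cools down
#'
#' Ticks until `alpha < alpha_min` or `max_ticks` is reached. The returned
#' state satisfies the compartment-membership invariant for every unpinned
#' visible node.
#'
#' @inheritParams tick
#' @param max_ticks maximum number of ticks.
#' @return The final `layout_state`.
#' @export
run_until_stable <- function(state, network, diagram, params = sim_params(),
                             max_ticks = 1000L) {
  stopifnot(max_ticks > 0)
  while (state$alpha >= params$alpha_min && state$tick_count < max_ticks) {
    state <- tick(state, network, diagram, params)
  }
  state
}

#' Pin or unpin a node
#'
#' A pinned node holds its coordinate across ticks (the headless equivalent
#' of dragging and holding). Pinning at an explicit point places the node
#' there as given, even outside its assigned region: consistency of a
#' user-forced position is left to the user.
#'
#' @param state a `layout_state`.
#' @param id node id.
#' @param point optional `c(x, y)` to move the node to while pinning.
#' @return The updated `layout_state`.
#' @export
pin_node <- function(state, id, point = NULL) {
  if (!id %in% rownames(state$pos)) stop("unknown node id: ", id)
  if (!is.null(point)) {
    state$pos[id, ] <- point[1:2]
    state$prev_pos[id, ] <- point[1:2]
  }
  state$pinned <- union(state$pinned, id)
  state
}

#' @rdname pin_node
#' @export
unpin_node <- function(state, id) {
  if (!id %in% rownames(state$pos)) stop("unknown node id: ", id)
  state$pinned <- setdiff(state$pinned, id)
  # restart the implicit velocity so motion resumes cleanly
  state$prev_pos[id, ] <- state$pos[id, ]
  state
}
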