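# Force-directed edge bundling (FDEB).
#
# Edges are subdivided into control points; compatible edge pairs attract
# each other's corresponding points while internal springs keep each
# polyline smooth. Cycles double the subdivision level, halve the step size
# and shrink the iteration count, producing progressively finer bundles.
# The effect is to group and smooth edges that flow along the same region
# of the display.

#' Edge-bundling parameters
#'
#' Defaults follow the published FDEB parameterization: stiffness
#' `K = 0.1`, `cycles = 6`, `I0 = 90` initial iterations decaying by 2/3
#' per cycle, `P0 = 1` initial subdivision point doubling per cycle, step
#' size `S0 = 0.1` halving per cycle, and a pairwise compatibility
#' threshold of 0.6.
#'
#' @param K bundle stiffness (spring constant numerator).
#' @param cycles number of subdivision cycles, >= 1.
#' @param I0 iterations in the first cycle.
#' @param iter_decay multiplicative iteration decay per cycle.
#' @param P0 initial number of interior subdivision points.
#' @param subdiv_mult subdivision multiplier per cycle.
#' @param S0 initial step size, px.
#' @param step_decay multiplicative step decay per cycle.
#' @param threshold compatibility threshold in [0, 1]; only pairs at or
#'   above it interact.
#' @return A list of class `bundle_params`.
#' @export
bundle_params <- function(K = 0.1, cycles = 6, I0 = 90, iter_decay = 2 / 3,
                          P0 = 1, subdiv_mult = 2, S0 = 0.1,
                          step_decay = 0.5, threshold = 0.6) {
  stopifnot(cycles >= 1, threshold >= 0, threshold <= 1, P0 >= 1)
  structure(list(K = K, cycles = as.integer(cycles), I0 = I0,
                 iter_decay = iter_decay, P0 = as.integer(P0),
                 subdiv_mult = subdiv_mult, S0 = S0,
                 step_decay = step_decay, threshold = threshold),
            class = "bundle_params")
}

#' FDEB compatibility score of two edges
#'
#' Product of the four FDEB compatibility measures computed on the straight
#' segments between the edges' endpoints: angle (|cos| of the angle between
#' the segments), scale (penalizing length mismatch relative to the average
#' length), position (distance between midpoints relative to the average
#' length), and visibility (mutual projection overlap). The score is
#' symmetric in its arguments and lies in [0, 1]; a zero-length edge scores
#' 0 against anything.
#'
#' @param p1,p2 endpoints `c(x, y)` of the first edge.
#' @param q1,q2 endpoints `c(x, y)` of the second edge.
#' @return A scalar in [0, 1].
#' @export
edge_compatibility <- function(p1, p2, q1, q2) {
  compat_vec(matrix(c(p1, p2, q1, q2), nrow = 1))[1]
}

# Vectorized compatibility over rows of an (n x 8) matrix
# [p1x p1y p2x p2y q1x q1y q2x q2y].
#' @keywords internal
compat_vec <- function(m) {
  px <- m[, 3] - m[, 1]; py <- m[, 4] - m[, 2]
  qx <- m[, 7] - m[, 5]; qy <- m[, 8] - m[, 6]
  lp <- sqrt(px^2 + py^2)
  lq <- sqrt(qx^2 + qy^2)
  ok <- lp > 1e-12 & lq > 1e-12
  lavg <- (lp + lq) / 2
  c_angle <- abs(px * qx + py * qy) / (lp * lq)
  c_scale <- 2 / (lavg / pmin(lp, lq) + pmax(lp, lq) / lavg)
  pmx <- (m[, 1] + m[, 3]) / 2; pmy <- (m[, 2] + m[, 4]) / 2
  qmx <- (m[, 5] + m[, 7]) / 2; qmy <- (m[, 6] + m[, 8]) / 2
  dmid <- sqrt((pmx - qmx)^2 + (pmy - qmy)^2)
  c_pos <- lavg / (lavg + dmid)

  # visibility: project the other edge's endpoints onto this edge's line
  vis <- function(ax, ay, bx, by, c1x, c1y, c2x, c2y) {
    ux <- bx - ax; uy <- by - ay
    L2 <- ux^2 + uy^2
    t1 <- ((c1x - ax) * ux + (c1y - ay) * uy) / L2
    t2 <- ((c2x - ax) * ux + (c2y - ay) * uy) / L2
    i1x <- ax + t1 * ux; i1y <- ay + t1 * uy
    i2x <- ax + t2 * ux; i2y <- ay + t2 * uy
    imx <- (i1x + i2x) / 2; imy <- (i1y + i2y) / 2
    pmx <- (ax + bx) / 2; pmy <- (ay + by) / 2
    ilen <- sqrt((i1x - i2x)^2 + (i1y - i2y)^2)
    v <- 1 - 2 * sqrt((pmx - imx)^2 + (pmy - imy)^2) / ilen
    v[!is.finite(v)] <- 0
    pmax(v, 0)
  }
  c_vis <- pmin(
    vis(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6], m[, 7], m[, 8]),
    vis(m[, 5], m[, 6], m[, 7], m[, 8], m[, 1], m[, 2], m[, 3], m[, 4]))

  score <- c_angle * c_scale * c_pos * c_vis
  score[!ok] <- 0
  pmin(pmax(score, 0), 1)
}

# Uniform arc-length resampling of a polyline to n_interior interior points.
#' @keywords internal
resample_polyline <- function(pts, n_interior) {
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  tt <- seq(0, total, length.out = n_interior + 2)
  if (total < 1e-12) {
    return(cbind(rep(pts[1, 1], n_interior + 2), rep(pts[1, 2], n_interior + 2)))
  }
  x <- stats::approx(cum, pts[, 1], xout = tt, ties = "ordered")$y
  y <- stats::approx(cum, pts[, 2], xout = tt, ties = "ordered")$y
  cbind(x, y)
}

#' Bundle the edges of a laid-out network
#'
#' Runs the FDEB cycles over all visible non-loop edges. Endpoints never
#' move; only interior subdivision points are attracted between edge pairs
#' whose compatibility reaches `params$threshold`. Networks with fewer than
#' two bundleable edges (or a threshold no pair reaches) return straight
#' polylines.
#'
#' @param network a `cell_network`.
#' @param layout a `layout_state` positioning every node.
#' @param params a `bundle_params` list.
#' @return A list of `bundle_polyline` objects: each a list with `source`,
#'   `target` and `points`, an ordered (P+2) x 2 coordinate matrix whose
#'   first and last rows equal the endpoint node positions exactly.
#' @export
bundle_edges <- function(network, layout, params = bundle_params()) {
  e <- network$edges
  keep <- e$visible & !e$is_loop
  e <- e[keep, , drop = FALSE]
  ne <- nrow(e)
  final_P <- params$P0 * params$subdiv_mult^(params$cycles - 1)
  straight <- function(i) {
    pts <- resample_polyline(rbind(layout$pos[e$source[i], ],
                                   layout$pos[e$target[i], ]), final_P)
    structure(list(source = e$source[i], target = e$target[i], points = pts),
              class = "bundle_polyline")
  }
  if (ne == 0) return(list())
  if (ne == 1) return(list(straight(1)))

  ex1 <- layout$pos[e$source, 1]; ey1 <- layout$pos[e$source, 2]
  ex2 <- layout$pos[e$target, 1]; ey2 <- layout$pos[e$target, 2]
  elen <- sqrt((ex2 - ex1)^2 + (ey2 - ey1)^2)

  pr <- utils::combn(ne, 2)
  cm <- compat_vec(cbind(ex1[pr[1, ]], ey1[pr[1, ]], ex2[pr[1, ]], ey2[pr[1, ]],
                         ex1[pr[2, ]], ey1[pr[2, ]], ex2[pr[2, ]], ey2[pr[2, ]]))
  sel <- cm >= params$threshold & elen[pr[1, ]] > 1e-12 & elen[pr[2, ]] > 1e-12
  ia <- pr[1, sel]
  ib <- pr[2, sel]

  P <- params$P0
  S <- params$S0
  I <- params$I0
  # coordinate matrices: one row per edge, one column per polyline point
  X <- cbind(ex1, matrix(0, ne, P), ex2)
  Y <- cbind(ey1, matrix(0, ne, P), ey2)
  for (i in seq_len(ne)) {
    res <- resample_polyline(rbind(c(ex1[i], ey1[i]), c(ex2[i], ey2[i])), P)
    X[i, ] <- res[, 1]; Y[i, ] <- res[, 2]
  }

  for (cyc in seq_len(params$cycles)) {
    if (cyc > 1) {
      P <- P * params$subdiv_mult
      S <- S * params$step_decay
      I <- ceiling(I * params$iter_decay)
      Xn <- matrix(0, ne, P + 2); Yn <- matrix(0, ne, P + 2)
      for (i in seq_len(ne)) {
        res <- resample_polyline(cbind(X[i, ], Y[i, ]), P)
        Xn[i, ] <- res[, 1]; Yn[i, ] <- res[, 2]
      }
      X <- Xn; Y <- Yn
    }
    if (length(ia) == 0) next
    cols <- 2:(P + 1)
    kP <- params$K / (pmax(elen, 1e-12) * (P + 1))
    for (it in seq_len(I)) {
      # spring forces along each polyline
      FX <- kP * (X[, cols - 1, drop = FALSE] + X[, cols + 1, drop = FALSE] -
                    2 * X[, cols, drop = FALSE])
      FY <- kP * (Y[, cols - 1, drop = FALSE] + Y[, cols + 1, drop = FALSE] -
                    2 * Y[, cols, drop = FALSE])
      # electrostatic attraction between corresponding points of
      # compatible pairs: the raw coordinate difference, which decays as
      # points merge and so converges without oscillation
      DX <- X[ib, cols, drop = FALSE] - X[ia, cols, drop = FALSE]
      DY <- Y[ib, cols, drop = FALSE] - Y[ia, cols, drop = FALSE]
      D <- sqrt(DX^2 + DY^2)
      keepf <- D > 1e-6
      UX <- DX * keepf; UY <- DY * keepf
      ga <- rowsum(UX, ia); gb <- rowsum(UX, ib)
      FX[as.integer(rownames(ga)), ] <- FX[as.integer(rownames(ga)), ] + ga
      FX[as.integer(rownames(gb)), ] <- FX[as.integer(rownames(gb)), ] - gb
      ga <- rowsum(UY, ia); gb <- rowsum(UY, ib)
      FY[as.integer(rownames(ga)), ] <- FY[as.integer(rownames(ga)), ] + ga
      FY[as.integer(rownames(gb)), ] <- FY[as.integer(rownames(gb)), ] - gb
      X[, cols] <- X[, cols] + S * FX
      Y[, cols] <- Y[, cols] + S * FY
    }
  }

  lapply(seq_len(ne), function(i) {
    structure(list(source = e$source[i], target = e$target[i],
                   points = cbind(x = X[i, ], y = Y[i, ])),
              class = "bundle_polyline")
  })
}
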