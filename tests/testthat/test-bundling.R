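# FDEB compatibility measures and bundling contract.

# Independent recoding of the four compatibility formulas (oracle).
ref_compat <- function(p1, p2, q1, q2) {
  P <- p2 - p1; Q <- q2 - q1
  lp <- sqrt(sum(P^2)); lq <- sqrt(sum(Q^2))
  if (lp < 1e-12 || lq < 1e-12) return(0)
  lavg <- (lp + lq) / 2
  Ca <- abs(sum(P * Q)) / (lp * lq)
  Cs <- 2 / (lavg / min(lp, lq) + max(lp, lq) / lavg)
  pm <- (p1 + p2) / 2; qm <- (q1 + q2) / 2
  Cp <- lavg / (lavg + sqrt(sum((pm - qm)^2)))
  vis <- function(a, b, c1, c2) {
    u <- b - a; L2 <- sum(u^2)
    i1 <- a + sum((c1 - a) * u) / L2 * u
    i2 <- a + sum((c2 - a) * u) / L2 * u
    im <- (i1 + i2) / 2
    den <- sqrt(sum((i1 - i2)^2))
    if (den < 1e-12) return(0)
    max(0, 1 - 2 * sqrt(sum(((a + b) / 2 - im)^2)) / den)
  }
  Cv <- min(vis(p1, p2, q1, q2), vis(q1, q2, p1, p2))
  Ca * Cs * Cp * Cv
}

test_that("compatibility matches the reference formulas and is symmetric", {
  expect_equal(edge_compatibility(c(0, 0), c(1, 0), c(0, 0), c(1, 0)), 1)
  # perpendicular equal-length edges crossing at midpoints: angle term 0
  expect_equal(edge_compatibility(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)), 0)
  # zero-length edge scores 0
  expect_equal(edge_compatibility(c(0, 0), c(0, 0), c(0, 0), c(1, 0)), 0)
  # parallel equal-length laterally offset pair against the oracle
  expect_equal(edge_compatibility(c(0, 0), c(10, 0), c(0, 3), c(10, 3)),
               ref_compat(c(0, 0), c(10, 0), c(0, 3), c(10, 3)))
  set.seed(14)
  for (k in 1:50) {
    e <- matrix(runif(8, -20, 20), 4, 2)
    got <- edge_compatibility(e[1, ], e[2, ], e[3, ], e[4, ])
    expect_equal(got, ref_compat(e[1, ], e[2, ], e[3, ], e[4, ]),
                 tolerance = 1e-12)
    expect_equal(got, edge_compatibility(e[3, ], e[4, ], e[1, ], e[2, ]))
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

mk_layout <- function(net, coords) {
  pos <- matrix(coords, ncol = 2, byrow = TRUE,
                dimnames = list(net$nodes$id, c("x", "y")))
  structure(list(pos = pos, node_r = 5,
                 labels = setNames(rep("cytosol", nrow(pos)), net$nodes$id)),
            class = "layout_state")
}

test_that("a single edge stays a straight collinear polyline", {
  net <- make_net(rbind(c("a", "b")))
  lay <- mk_layout(net, c(0, 0, 30, 40))
  bp <- bundle_params(cycles = 4)
  b <- bundle_edges(net, lay, bp)
  expect_length(b, 1)
  pts <- b[[1]]$points
  expect_equal(nrow(pts), bp$P0 * bp$subdiv_mult^(bp$cycles - 1) + 2)
  expect_equal(unname(pts[1, ]), c(0, 0))
  expect_equal(unname(pts[nrow(pts), ]), c(30, 40))
  # collinearity: cross products vanish
  cr <- (pts[, 1] - 0) * 40 - (pts[, 2] - 0) * 30
  expect_equal(max(abs(cr)), 0, tolerance = 1e-9)
})

test_that("identical parallel edges converge onto each other; endpoints never move", {
  net <- make_net(rbind(c("a", "b"), c("c", "d")))
  # two edges drawn between coincident endpoint pairs: symmetric attraction
  # keeps their polylines identical at every cycle
  same <- mk_layout(net, c(0, 0, 100, 0, 0, 0, 100, 0))
  bs <- bundle_edges(net, same, bundle_params())
  expect_identical(bs[[1]]$points, bs[[2]]$points)
  # laterally offset parallel pair: the bundle closes in the middle while
  # the anchored endpoints stay put
  lay <- mk_layout(net, c(0, 0, 100, 0, 0, 4, 100, 4))
  b <- bundle_edges(net, lay, bundle_params())
  p1 <- b[[1]]$points; p2 <- b[[2]]$points
  expect_equal(unname(p1[1, ]), c(0, 0))
  expect_equal(unname(p1[nrow(p1), ]), c(100, 0))
  expect_equal(unname(p2[1, ]), c(0, 4))
  expect_equal(unname(p2[nrow(p2), ]), c(100, 4))
  mid <- ceiling(nrow(p1) / 2)
  expect_lt(sqrt(sum((p1[mid, ] - p2[mid, ])^2)), 0.05)
  # both polylines meet on the symmetry mid-line y = 2
  expect_equal(unname(p1[mid, 2]), 2, tolerance = 0.01)
  expect_equal(unname(p2[mid, 2]), 2, tolerance = 0.01)
})

test_that("threshold 1 with incompatible directions keeps every polyline straight", {
  net <- make_net(rbind(c("a", "b"), c("c", "d")))
  lay <- mk_layout(net, c(0, 0, 50, 0, 20, -30, 25, 60))
  b <- bundle_edges(net, lay, bundle_params(threshold = 1))
  for (bl in b) {
    p <- bl$points
    v <- p[nrow(p), ] - p[1, ]
    cr <- (p[, 1] - p[1, 1]) * v[2] - (p[, 2] - p[1, 2]) * v[1]
    expect_equal(max(abs(cr)), 0, tolerance = 1e-9)
  }
})

test_that("subdivision count follows P0 * m^(cycles-1) + 2 and endpoints hold", {
  net <- generate_network(gen_spec(20, 30, seed = 13))
  d <- build_cell_diagram(assign_compartment(net$nodes$selected_cc))
  p <- sim_params(seed = 2)
  st <- run_until_stable(init_layout(net, d, p), net, d, p, max_ticks = 60)
  for (cyc in c(1, 3, 5)) {
    bp <- bundle_params(cycles = cyc)
    b <- bundle_edges(net, st, bp)
    expect_length(b, sum(!net$edges$is_loop))
    for (i in seq_along(b)) {
      pts <- b[[i]]$points
      expect_equal(nrow(pts), bp$P0 * bp$subdiv_mult^(cyc - 1) + 2)
      expect_equal(unname(pts[1, ]), unname(st$pos[b[[i]]$source, ]))
      expect_equal(unname(pts[nrow(pts), ]), unname(st$pos[b[[i]]$target, ]))
    }
  }
})
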