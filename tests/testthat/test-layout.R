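# The constraint projection and the simulation around it.

test_that("radial projection reproduces the worked example and its algebra", {
  # organelle centered at c, effective radius 5, point at offset (6,8):
  # R = 10, scale 5/10, so the projected offset is (3,4)
  d <- build_cell_diagram(c("nucleus", "cytosol"), 200, 200)
  circ <- subcellnet:::diagram_circle(d, "nucleus")
  node_r <- circ[3] - 5 # leaves r_eff = 5
  p <- c(circ[1] + 6, circ[2] + 8)
  got <- constrain_to_region(p, "nucleus", d, node_r = node_r)
  expect_equal(unname(got - circ[1:2]), c(3, 4))
  # a point already inside is returned unchanged
  inside <- c(circ[1] + 1, circ[2] + 1)
  expect_identical(constrain_to_region(inside, "nucleus", d, node_r = node_r),
                   unname(inside))
})

test_that("projection is idempotent and angle-preserving", {
  set.seed(31)
  n <- 2000
  cx <- runif(n, -50, 50); cy <- runif(n, -50, 50); r <- runif(n, 1, 40)
  px <- runif(n, -100, 100); py <- runif(n, -100, 100)
  for (outward in c(FALSE, TRUE)) {
    for (i in sample(n, 250)) {
      p0 <- matrix(c(px[i], py[i]), 1)
      p1 <- subcellnet:::project_radial(p0, cx[i], cy[i], r[i], outward)
      p2 <- subcellnet:::project_radial(p1, cx[i], cy[i], r[i], outward)
      expect_equal(p2, p1, tolerance = 1e-12)
      a0 <- atan2(p0[2] - cy[i], p0[1] - cx[i])
      a1 <- atan2(p1[2] - cy[i], p1[1] - cx[i])
      if (sqrt((px[i] - cx[i])^2 + (py[i] - cy[i])^2) > 1e-9) {
        expect_equal(a1, a0, tolerance = 1e-9)
      }
    }
  }
})

test_that("annulus projection clamps both borders", {
  d <- build_cell_diagram(c("plasma membrane", "cytosol"))
  b <- subcellnet:::annulus_bounds(d, "plasma membrane")
  ctr <- d$cell_center
  out <- constrain_to_region(ctr + c(b[["outer"]] + 50, 0), "plasma membrane",
                             d, node_r = 0)
  expect_equal(unname(out), unname(c(ctr["x"] + b[["outer"]], ctr["y"])))
  inn <- constrain_to_region(ctr + c(b[["inner"]] - 30, 0), "plasma membrane",
                             d, node_r = 0)
  expect_equal(unname(inn), unname(c(ctr["x"] + b[["inner"]], ctr["y"])))
})

test_that("degenerate center points project deterministically along +x", {
  d <- build_cell_diagram(c("nucleus", "cytosol"))
  # a cytosol node exactly at the nucleus center must be expelled
  p <- constrain_to_region(unname(d$cell_center), "cytosol", d, node_r = 2)
  expect_true(region_contains(d, "cytosol", p, node_r = 2))
  expect_gt(p[1], d$cell_center["x"]) # pushed along +x
  expect_equal(p[2], unname(d$cell_center["y"]))
})

test_that("initial placement is seeded, in-region, and honors pins", {
  net <- generate_network(gen_spec(100, 150, seed = 3))
  d <- build_cell_diagram(assign_compartment(net$nodes$selected_cc))
  p <- sim_params(seed = 42)
  s1 <- init_layout(net, d, p)
  s2 <- init_layout(net, d, p)
  expect_identical(s1$pos, s2$pos)
  expect_true(all(subcellnet:::membership_ok(d, s1$labels, s1$pos, p$node_r)))
  id <- net$nodes$id[1]
  s3 <- init_layout(net, d, p, start = data.frame(id = id, x = 7, y = 9),
                    pinned = id)
  expect_equal(unname(s3$pos[id, ]), c(7, 9))
})

test_that("a tick leaves a zero-force equilibrium in place and cools alpha", {
  net <- make_net(rbind(c("a", "b")), cc = c("cytosol", "cytosol"))
  d <- build_cell_diagram(c("cytosol", "nucleus"))
  p <- sim_params(charge = 0, gravity = 0, repulsive = 0, seed = 1)
  st <- init_layout(net, d, p,
                    start = data.frame(id = c("a", "b"),
                                       x = d$cell_center["x"] + c(100, 100 + p$link_distance),
                                       y = d$cell_center["y"] + c(120, 120)))
  st1 <- tick(st, net, d, p)
  expect_equal(st1$pos, st$pos, tolerance = 1e-12)
  # alpha follows alpha0 * decay^k
  for (k in 2:5) st1 <- tick(st1, net, d, p)
  expect_equal(st1$alpha, p$alpha0 * p$alpha_decay^5, tolerance = 1e-12)
  expect_equal(st1$tick_count, 5L)
})

test_that("a node pushed outside its organelle returns to the inner border", {
  net <- make_net(ids = c("a"), cc = "endosome")
  d <- build_cell_diagram(c("endosome", "cytosol", "nucleus"))
  p <- sim_params(charge = 0, gravity = 0, repulsive = 0, seed = 1)
  circ <- d$organelles[["endosome"]]
  st <- init_layout(net, d, p)
  st$pos["a", ] <- circ[1:2] + c(circ[3] + 30, 0) # kicked outside
  st <- tick(st, net, d, p)
  expect_true(region_contains(d, "endosome", st$pos["a", ], node_r = p$node_r))
  expect_equal(sqrt(sum((st$pos["a", ] - circ[1:2])^2)),
               unname(circ[3]) - p$node_r, tolerance = 1e-9)
})

test_that("membership holds after every tick of a mixed-compartment run", {
  spec <- gen_spec(120, 240, unknown_prob = 0.1, seed = 21)
  net <- generate_network(spec)
  d <- build_cell_diagram(assign_compartment(net$nodes$selected_cc))
  res <- audit_run(net, d, sim_params(seed = 5), n_ticks = 80)
  expect_true(res$ok)
})

test_that("cooling terminates the run and results are reproducible", {
  net <- generate_network(gen_spec(50, 80, seed = 2))
  d <- build_cell_diagram(assign_compartment(net$nodes$selected_cc))
  cold <- sim_params(alpha0 = 0.0025, alpha_min = 0.005, seed = 1)
  st <- init_layout(net, d, cold)
  st <- run_until_stable(st, net, d, cold, max_ticks = 100)
  expect_equal(st$tick_count, 0L) # already colder than the stop threshold
  p <- sim_params(seed = 77)
  a <- run_until_stable(init_layout(net, d, p), net, d, p, max_ticks = 120)
  b <- run_until_stable(init_layout(net, d, p), net, d, p, max_ticks = 120)
  expect_identical(a$pos, b$pos)
  expect_true(all(subcellnet:::membership_ok(d, a$labels, a$pos, p$node_r)))
})

test_that("pinned nodes hold their position, even outside their region", {
  net <- make_net(rbind(c("a", "b"), c("b", "c")),
                  cc = c("nucleus", "cytosol", "cytosol"))
  d <- build_cell_diagram(c("nucleus", "cytosol"))
  p <- sim_params(seed = 6)
  st <- init_layout(net, d, p)
  st <- pin_node(st, "a", point = c(5, 5)) # extracellular corner: user override
  for (i in 1:30) st <- tick(st, net, d, p)
  expect_equal(unname(st$pos["a", ]), c(5, 5))
  # unpinning restores mobility under a net force
  st <- unpin_node(st, "a")
  st2 <- tick(st, net, d, p)
  expect_false(all(st2$pos["a", ] == st$pos["a", ]))
  expect_error(pin_node(st, "nope"), "unknown")
})

test_that("hidden nodes do not participate in the simulation", {
  net <- make_net(rbind(c("a", "b"), c("b", "c")),
                  cc = rep("cytosol", 3))
  net <- apply_filter(net, search_nodes(net, c("a", "b")))
  d <- build_cell_diagram(c("cytosol", "nucleus"))
  p <- sim_params(seed = 4)
  st <- init_layout(net, d, p)
  before_c <- st$pos["c", ]
  st <- tick(st, net, d, p)
  expect_equal(st$pos["c", ], before_c) # invisible: untouched
})
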