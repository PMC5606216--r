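test_that("minimal diagram: nucleus disc only, no free-floating organelles", {
  d <- build_cell_diagram(c("nucleus", "cytosol"))
  expect_s3_class(d, "cell_diagram")
  expect_true(d$has_nucleus)
  expect_false(d$has_wall)
  expect_length(d$organelles, 0)
  expect_true(all(diff(d$ring_radii) > 0))
})

test_that("all 16 organelle-disc labels pack without overlap inside the cytoplasm", {
  reg <- compartment_registry()
  orgs <- reg$label[reg$region_kind == "organelle_disc"] # includes nucleus
  expect_length(orgs, 16L)
  d <- build_cell_diagram(c(orgs, "cytosol", "plasma membrane", "cell wall",
                            "extracellular"))
  expect_length(d$organelles, 15L) # nucleus is the central disc
  circ <- do.call(rbind, d$organelles)
  nuc <- c(d$cell_center, d$ring_radii[["nucleus"]])
  all_c <- rbind(circ, nuc)
  for (i in seq_len(nrow(all_c) - 1)) for (j in (i + 1):nrow(all_c)) {
    dd <- sqrt(sum((all_c[i, 1:2] - all_c[j, 1:2])^2))
    expect_gte(dd, all_c[i, 3] + all_c[j, 3] - 1e-9)
  }
  # every organelle lies inside the cytoplasm disc
  dc <- sqrt((circ[, 1] - d$cell_center["x"])^2 +
               (circ[, 2] - d$cell_center["y"])^2)
  expect_true(all(dc + circ[, 3] <= d$ring_radii[["cytoplasm"]] + 1e-9))
})

test_that("absent compartments are pruned from the diagram", {
  d <- build_cell_diagram(c("nucleus", "cytosol", "mitochondrion"))
  expect_named(d$organelles, "mitochondrion")
  expect_false("wall_outer" %in% names(d$ring_radii))
  dw <- build_cell_diagram(c("nucleus", "cell wall"))
  expect_true("wall_outer" %in% names(dw$ring_radii))
  # no nucleus annotated -> no nucleus disc
  d2 <- build_cell_diagram("cytosol")
  expect_false(d2$has_nucleus)
})

test_that("diagram construction is deterministic", {
  labs <- c("nucleus", "cytosol", "endosome", "mitochondrion", "cell wall")
  d1 <- build_cell_diagram(labs)
  d2 <- build_cell_diagram(rev(labs))
  expect_identical(d1, d2)
})

test_that("region membership respects the node disc, not just its center", {
  d <- build_cell_diagram(c("nucleus", "cytosol", "mitochondrion",
                            "plasma membrane", "extracellular"))
  ctr <- d$cell_center
  rn <- d$ring_radii[["nucleus"]]
  expect_true(region_contains(d, "nucleus", ctr, node_r = 5))
  # disc crossing the boundary: 49 + 5 > 50 scaled to this nucleus radius
  p <- ctr + c(rn * 49 / 50, 0)
  expect_false(region_contains(d, "nucleus", p, node_r = rn * 5 / 50))
  expect_true(region_contains(d, "nucleus", p, node_r = rn * 1 / 50 * 0.9))
  # cytosol excludes organelle interiors
  mito <- d$organelles[["mitochondrion"]]
  expect_false(region_contains(d, "cytosol", mito[1:2], node_r = 0))
  expect_true(region_contains(d, "mitochondrion", mito[1:2], node_r = 0))
  # annulus needs both bounds
  b <- subcellnet:::annulus_bounds(d, "plasma membrane")
  mid <- (b[1] + b[2]) / 2
  expect_true(region_contains(d, "plasma membrane", ctr + c(mid, 0), node_r = 1))
  expect_false(region_contains(d, "plasma membrane", ctr + c(b[1], 0), node_r = 1))
  # extracellular is outside the outer ring but inside the canvas
  expect_true(region_contains(d, "extracellular", c(5, 5), node_r = 2))
  expect_false(region_contains(d, "extracellular", c(1, 5), node_r = 2))
  expect_false(region_contains(d, "extracellular", ctr, node_r = 2))
  expect_error(region_contains(d, "ribosome", c(0, 0), 0), "unknown")
})

test_that("the cytoplasm partitions into nucleus, organelles and free cytosol", {
  d <- build_cell_diagram(c("nucleus", "cytosol", "mitochondrion", "endosome"))
  set.seed(42)
  r_c <- subcellnet:::cytoplasm_radius(d)
  th <- runif(500, 0, 2 * pi)
  rr <- sqrt(runif(500)) * (r_c - 1e-6)
  pts <- cbind(d$cell_center["x"] + rr * cos(th),
               d$cell_center["y"] + rr * sin(th))
  in_regions <- sapply(c("nucleus", "mitochondrion", "endosome", "cytosol"),
                       function(lab) {
                         subcellnet:::membership_ok(d, lab, pts, node_r = 0,
                                                    tol = 0)
                       })
  expect_true(all(rowSums(in_regions) == 1))
})

test_that("moving an organelle rigidly carries its nodes", {
  net <- make_net(rbind(c("a", "b")), ids = c("a", "b", "c"),
                  cc = c("endosome", "endosome", "cytosol"))
  d <- build_cell_diagram(c("nucleus", "cytosol", "endosome"))
  p <- sim_params(seed = 8)
  st <- init_layout(net, d, p)
  before <- st$pos
  gap <- sqrt(sum((before["a", ] - before["b", ])^2))
  circ <- d$organelles[["endosome"]]
  newc <- c(circ[1] + 150, circ[2] - 40)
  res <- move_organelle(d, "endosome", newc, net, st)
  expect_equal(unname(res$diagram$organelles[["endosome"]][1:2]), unname(newc))
  expect_equal(unname(res$layout$pos["a", ] - before["a", ]), c(150, -40))
  expect_equal(sqrt(sum((res$layout$pos["a", ] - res$layout$pos["b", ])^2)),
               gap) # pairwise distance preserved exactly
  expect_equal(res$layout$pos["c", ], before["c", ]) # others untouched
  # organelle with no nodes: only the circle moves
  d2 <- move_organelle(d, "endosome", newc)
  expect_equal(unname(d2$organelles[["endosome"]][1:2]), unname(newc))
})
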