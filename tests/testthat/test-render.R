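# SVG/PNG/donut rendering and color mapping.

lay_for <- function(net, d, seed = 3) {
  p <- sim_params(seed = seed)
  run_until_stable(init_layout(net, d, p), net, d, p, max_ticks = 40)
}

test_that("an empty network renders a valid diagram-only SVG", {
  net <- make_net(ids = character(0))
  d <- build_cell_diagram(c("nucleus", "cytosol"))
  st <- structure(list(pos = matrix(numeric(0), 0, 2,
                                    dimnames = list(character(0), c("x", "y"))),
                       node_r = 5, labels = character(0)),
                  class = "layout_state")
  svg <- render_svg(net, d, st)
  doc <- xml2::read_xml(svg)
  expect_equal(xml2::xml_name(doc), "svg")
  xml2::xml_ns_strip(doc)
  expect_length(xml2::xml_find_all(doc, "//circle[@class='node']"), 0)
})

test_that("each visible node becomes exactly one node circle at its layout position", {
  net <- make_net(rbind(c("a", "b"), c("b", "c")),
                  cc = c("nucleus", "cytosol", "cytosol"))
  d <- build_cell_diagram(c("nucleus", "cytosol"))
  st <- lay_for(net, d)
  svg <- render_svg(net, d, st)
  doc <- xml2::read_xml(svg); xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, "//circle[@class='node']")
  expect_length(nodes, 3)
  cx <- as.numeric(xml2::xml_attr(nodes, "cx"))
  ids <- xml2::xml_attr(nodes, "data-id")
  # rendered coordinates equal the layout table values exactly (same format)
  expect_identical(sprintf("%.6f", st$pos[ids, 1]), xml2::xml_attr(nodes, "cx"))
  expect_identical(sprintf("%.6f", st$pos[ids, 2]), xml2::xml_attr(nodes, "cy"))
  expect_equal(cx, unname(st$pos[ids, 1]))
})

test_that("unselected nodes get the transparency treatment; selected get labels", {
  net <- make_net(rbind(c("a", "b"), c("b", "c")))
  d <- build_cell_diagram("cytosol")
  st <- lay_for(net, d)
  sel <- search_nodes(net, "a")
  svg <- render_svg(net, d, st, selection = sel)
  doc <- xml2::read_xml(svg); xml2::xml_ns_strip(doc)
  ops <- xml2::xml_attr(xml2::xml_find_all(doc, "//circle[@class='node']"),
                        "opacity")
  expect_equal(sum(ops == "0.25"), 2)
  expect_equal(sum(ops == "1.00"), 1)
  labels <- xml2::xml_find_all(doc, "//text[@class='node-label']")
  expect_length(labels, 1)
  expect_equal(xml2::xml_text(labels), "a")
})

test_that("rendering is byte-identical across runs and hides filtered nodes", {
  net <- generate_network(gen_spec(25, 40, seed = 15))
  d <- build_cell_diagram(assign_compartment(net$nodes$selected_cc))
  st <- lay_for(net, d)
  cnt <- compartment_counts(net)
  s1 <- render_svg(net, d, st, counts = cnt, color_by = "Selected CC")
  s2 <- render_svg(net, d, st, counts = cnt, color_by = "Selected CC")
  expect_identical(s1, s2)
  f <- apply_filter(net, search_nodes(net, net$nodes$label[1:10]))
  sf <- render_svg(f, d, st)
  doc <- xml2::read_xml(sf); xml2::xml_ns_strip(doc)
  expect_length(xml2::xml_find_all(doc, "//circle[@class='node']"), 10)
})

test_that("numeric color mapping ramps light-to-dark with the maximum darkest", {
  lum <- function(hex) {
    v <- grDevices::col2rgb(hex)
    0.2126 * v[1, ] + 0.7152 * v[2, ] + 0.0722 * v[3, ]
  }
  map <- node_color_mapping(c(1, 1, 5), kind = "numeric")
  expect_equal(attr(map, "kind"), "numeric")
  expect_lt(lum(map[["5"]]), lum(map[["1"]])) # highest value darkest
  # single distinct value: no min==max degeneracy
  one <- node_color_mapping(c(3, 3, 3), kind = "numeric")
  expect_length(one, 1)
  expect_match(unname(one), "^#[0-9A-F]{6}$")
  # categorical: k distinct colors for k values within the palette size
  cm <- node_color_mapping(c("x", "y", "x", "z"))
  expect_equal(attr(cm, "kind"), "categorical")
  expect_length(unique(cm), 3)
  # mixed types degrade to categorical
  expect_equal(attr(node_color_mapping(c("1", "two", "3")), "kind"),
               "categorical")
})

test_that("donut arcs are proportional to counts and the CSV normalizes", {
  cnt <- structure(data.frame(label = c("nucleus", "cytosol"),
                              count = c(3L, 1L),
                              percentage = c(75, 25),
                              stringsAsFactors = FALSE),
                   class = c("compartment_counts", "data.frame"))
  frag <- render_donut(cnt)
  expect_length(grep("donut-seg", frag), 2)
  # 3:1 counts: the first segment spans > half a turn (large-arc flag 1)
  expect_match(frag[2], "A 55.00 55.00 0 1 1")
  expect_match(frag[3], "A 55.00 55.00 0 0 1")
  # equal counts: two half-turn arcs, neither flagged large
  cnt2 <- cnt; cnt2$count <- c(1L, 1L); cnt2$percentage <- c(50, 50)
  frag2 <- render_donut(cnt2)
  expect_false(any(grepl(" 0 1 1 ", frag2[2:3])))
  f <- withr::local_tempfile(fileext = ".csv")
  net <- make_net(ids = letters[1:7],
                  cc = c("nucleus", "nucleus", "nucleus", "cytosol",
                         "cytosol", "endosome", ""))
  write_counts_csv(compartment_counts(net), f)
  tab <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(names(tab), c("label", "count", "percentage"))
  expect_equal(sum(tab$percentage), 100, tolerance = 0.01)
  # empty counts produce an empty fragment
  expect_length(render_donut(compartment_counts(make_net(ids = character(0)))), 0)
})

test_that("PNG export writes a raster of the same scene", {
  net <- make_net(rbind(c("a", "b")), cc = c("nucleus", "cytosol"))
  d <- build_cell_diagram(c("nucleus", "cytosol"))
  st <- lay_for(net, d)
  f <- withr::local_tempfile(fileext = ".png")
  render_png(net, d, st, f, counts = compartment_counts(net))
  expect_true(file.exists(f))
  expect_gt(file.size(f), 1000)
  expect_identical(readBin(f, "raw", 4), as.raw(c(0x89, 0x50, 0x4e, 0x47)))
})
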