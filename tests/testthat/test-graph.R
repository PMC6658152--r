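test_that("thinning reduces a rectangle to its centerline", {
  # blunt ends erode by about half the width on each side
  sk <- skeletonize(rect_mask(5, 100))
  expect_lte(abs(sum(sk) - 100), 5)
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_equal(sum(skeletonize(as_mask(one))), 1)
  expect_warning(skeletonize(as_mask(matrix(0L, 4, 4))), "empty")
})

test_that("thinning preserves the component count", {
  m <- matrix(0L, 60, 60)
  m[10:14, 5:50] <- 1L        # bar
  m[30:50, 20:24] <- 1L       # separate bar
  m[55, 55] <- 1L             # isolated pixel
  sk <- skeletonize(as_mask(m))
  expect_equal(max(fundusgraph:::cc_label_cpp(unclass(sk))),
               max(fundusgraph:::cc_label_cpp(m)))
})

test_that("a straight line extracts as two endpoints and one segment", {
  g <- extract_graph(line_skeleton(50))
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$segments), 1)
  expect_equal(basic_counts(g)$endpoints, 2)
  expect_equal(basic_counts(g)$bifurcations, 0)
  expect_equal(g$segments$length, 50)
})

test_that("a plus sign extracts as one junction, four endpoints, four segments", {
  g <- extract_graph(plus_skeleton(10))
  bc <- basic_counts(g)
  expect_equal(bc$nodes, 5)
  expect_equal(bc$links, 4)
  expect_equal(bc$endpoints, 4)
  expect_equal(bc$bifurcations, 1)
  expect_equal(sort(g$nodes$degree), c(1, 1, 1, 1, 4))
  # the junction cluster absorbs the first pixel of each arm
  expect_true(all(abs(g$segments$length - 11) <= 1))
})

test_that("extraction matches the degree-2-contracted pixel graph", {
  fixtures <- list(line_skeleton(20), plus_skeleton(6))
  # Y shape: one junction, three arms
  y <- matrix(0L, 24, 24)
  y[12, 3:12] <- 1L
  for (i in 1:8) { y[12 - i, 12 + i] <- 1L; y[12 + i, 12 + i] <- 1L }
  fixtures$y <- structure(y, class = "skeleton")
  # T shape: bar plus stem
  tt <- matrix(0L, 22, 22)
  tt[8, 4:18] <- 1L; tt[9:18, 11] <- 1L
  fixtures$t <- structure(tt, class = "skeleton")
  # diamond ring with a tail: one junction, one self-loop, one chain
  dia <- matrix(0L, 21, 21)
  dia[abs(row(dia) - 11) + abs(col(dia) - 11) == 6] <- 1L
  dia[2:4, 11] <- 1L
  fixtures$dia <- structure(dia, class = "skeleton")
  for (sk in fixtures) {
    g <- extract_graph(sk, min_spur = 0, junction_merge = 0)
    oracle <- pixel_graph_contraction(sk)
    expect_equal(nrow(g$nodes), oracle$n_nodes)
    expect_equal(nrow(g$segments), oracle$n_edges)
    deg <- tabulate(c(g$segments$from, g$segments$to), nrow(g$nodes))
    expect_equal(sort(deg), oracle$degrees)
  }
})

test_that("extraction is invariant under transposition", {
  img <- generate_vessel_tree(clean_tree_spec(2))
  sk <- skeletonize(as_mask(img$mask))
  g1 <- extract_graph(sk)
  g2 <- extract_graph(structure(t(unclass(sk)), class = "skeleton"))
  expect_equal(basic_counts(g1), basic_counts(g2))
  expect_equal(sort(g1$segments$length), sort(g2$segments$length))
})

test_that("cycle-free synthetic rasters extract as trees", {
  for (s in c(4, 12)) {
    img <- generate_vessel_tree(clean_tree_spec(s))
    g <- extract_graph(skeletonize(as_mask(img$mask)))
    expect_equal(nrow(g$segments), nrow(g$nodes) - 1)
  }
})

test_that("a pure cycle raises the named error", {
  dia <- matrix(0L, 21, 21)
  dia[abs(row(dia) - 11) + abs(col(dia) - 11) == 6] <- 1L
  expect_error(extract_graph(structure(dia, class = "skeleton")),
               "pure cycle")
})

test_that("widths follow N = L x W and pixel assignment conserves the mask", {
  mk <- rect_mask(5, 100)
  sk <- skeletonize(mk)
  g <- extract_graph(sk, mask = mk)
  expect_equal(nrow(g$segments), 1)
  expect_lte(abs(g$segments$width - 5), 0.5)
  expect_equal(sum(g$segments$n_pixels), sum(mk))

  ln <- as_mask(unclass(line_skeleton(30)))
  gl <- extract_graph(skeletonize(ln), mask = ln)
  expect_equal(gl$segments$width, 1)

  img <- generate_vessel_tree(clean_tree_spec(5))
  gm <- extract_graph(skeletonize(as_mask(img$mask)), mask = as_mask(img$mask))
  expect_equal(sum(gm$segments$n_pixels), sum(img$mask))
})

test_that("central node assignment picks the nearest node with id tie-break", {
  g <- toy_graph(from = c(1, 2), to = c(2, 3), weight = c(1, 1))
  g$nodes$row <- c(0, 10, 20); g$nodes$col <- 0
  disc <- structure(list(center = c(0, 0), radius = 5), class = "optic_disc")
  expect_equal(assign_central_node(g, disc)$central_id, 1L)
  # two equidistant nodes -> lower id
  disc2 <- structure(list(center = c(5, 0), radius = 5), class = "optic_disc")
  expect_equal(assign_central_node(g, disc2)$central_id, 1L)
  # farther than 3 radii -> failure
  disc3 <- structure(list(center = c(100, 100), radius = 5),
                     class = "optic_disc")
  expect_error(assign_central_node(g, disc3),
               class = "fundusgraph_central_failure")
  g0 <- g; g0$nodes <- g0$nodes[0, ]
  expect_error(assign_central_node(g0, disc), "empty")
})

test_that("weights follow w = L^l W^a", {
  g <- toy_graph(from = 1, to = 2, weight = NA_real_)
  g$segments$length <- 10; g$segments$width <- 2
  expect_equal(apply_weights(g, 1, -2)$segments$weight, 2.5)
  expect_equal(apply_weights(g, 0, 1)$segments$weight, 2)
  expect_equal(apply_weights(g, 0, 0)$segments$weight, 1)
  img <- generate_vessel_tree(clean_tree_spec(3, size = 384))
  gm <- extract_graph(skeletonize(as_mask(img$mask)), mask = as_mask(img$mask))
  gw <- apply_weights(gm, 0, 1)
  expect_equal(gw$segments$weight, gw$segments$width)
  expect_true(all(apply_weights(gm, 1, -2)$segments$weight > 0))
})
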