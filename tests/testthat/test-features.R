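test_that("central distances on a path and a star match hand values", {
  # path A-B-C with weights 1 then 2, central A
  g <- toy_graph(from = c(1, 2), to = c(2, 3), weight = c(1, 2))
  prof <- central_distances(g)
  expect_equal(prof$distance[prof$node_id == 2], 1)
  expect_equal(prof$hops[prof$node_id == 2], 1)
  expect_equal(prof$distance[prof$node_id == 3], 3)
  expect_equal(prof$hops[prof$node_id == 3], 2)
  expect_equal(cndd_samples(prof)$value[order(cndd_samples(prof)$value)],
               c(1, 3))
  expect_equal(sort(cmwd_samples(prof)$value), c(1, 1.5))

  # star with 5 leaves, all weights 0.7
  st <- toy_graph(from = rep(1, 5), to = 2:6, weight = rep(0.7, 5))
  ps <- central_distances(st)
  expect_equal(ps$distance, rep(0.7, 5))
  expect_equal(cmwd_samples(ps)$value, rep(0.7, 5))
  expect_equal(nrow(cndd_samples(ps)), 5)
})

test_that("unreachable nodes are flagged and excluded from C-NDD/CMWD", {
  g <- toy_graph(from = c(1, 3), to = c(2, 4), weight = c(1, 1))
  prof <- central_distances(g)
  expect_false(any(prof$reachable[prof$node_id %in% c(3, 4)]))
  expect_equal(nrow(cndd_samples(prof)), 1)
  s <- wdd_samples(g)
  expect_equal(nrow(s), 4)   # strengths are local: every node counted
})

test_that("distances equal exhaustive path enumeration on random graphs", {
  withr::local_seed(404)
  for (rep in 1:50) {
    n <- sample(5:12, 1)
    rg <- random_weighted_graph(n, extra = sample(0:3, 1))
    g <- toy_graph(rg$from, rg$to, rg$weight, n_nodes = n)
    prof <- central_distances(g)
    oracle <- brute_force_distance(rg$from, rg$to, rg$weight, n, source = 1)
    expect_equal(prof$distance, oracle[prof$node_id], tolerance = 1e-12)
  }
})

test_that("CMWD samples never exceed C-NDD samples when weights >= 1", {
  withr::local_seed(11)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    rg <- random_weighted_graph(n, extra = 2)
    g <- toy_graph(rg$from, rg$to, rg$weight + 1, n_nodes = n)
    prof <- central_distances(g)
    expect_true(all(cmwd_samples(prof)$value <=
                    cndd_samples(prof)$value + 1e-12))
  }
})

test_that("scaling all weights by c scales distance samples by exactly c", {
  withr::local_seed(12)
  rg <- random_weighted_graph(10, extra = 3)
  g1 <- toy_graph(rg$from, rg$to, rg$weight, n_nodes = 10)
  g2 <- toy_graph(rg$from, rg$to, 4 * rg$weight, n_nodes = 10)
  expect_equal(central_distances(g2)$distance,
               4 * central_distances(g1)$distance)
  expect_equal(cmwd_samples(central_distances(g2))$value,
               4 * cmwd_samples(central_distances(g1))$value)
})

test_that("unit weights reduce C-NDD to breadth-first hop counts", {
  withr::local_seed(13)
  rg <- random_weighted_graph(11, extra = 2)
  g <- toy_graph(rg$from, rg$to, rep(1, length(rg$from)), n_nodes = 11)
  prof <- central_distances(g)
  ig <- igraph::graph_from_data_frame(data.frame(rg$from, rg$to),
                                      directed = FALSE,
                                      vertices = data.frame(1:11))
  bfs_d <- as.numeric(igraph::distances(ig, v = "1", weights = NA))
  expect_equal(prof$distance, bfs_d[prof$node_id])
  expect_equal(prof$distance, as.numeric(prof$hops))
})

test_that("strengths follow the handshake identity", {
  tri <- toy_graph(from = c(1, 2, 3), to = c(2, 3, 1), weight = c(1, 1, 1))
  expect_equal(wdd_samples(tri)$value, c(2, 2, 2))
  st <- toy_graph(from = rep(1, 4), to = 2:5, weight = rep(3, 4))
  s <- wdd_samples(st)
  expect_equal(s$value[1], 12)
  expect_equal(s$value[-1], rep(3, 4))
  withr::local_seed(14)
  rg <- random_weighted_graph(9, extra = 3)
  g <- toy_graph(rg$from, rg$to, rg$weight, n_nodes = 9)
  expect_equal(sum(wdd_samples(g)$value), 2 * sum(rg$weight))
})

test_that("total strength is conserved under subdivision for additive weights", {
  # splitting a segment of equal width into two whose lengths sum to the
  # original conserves the total link weight when the weight is additive in
  # length (here w = L x W, the pixel count), hence conserves sum(s)
  g1 <- toy_graph(from = 1, to = 2, weight = NA_real_)
  g1$segments$length <- 10; g1$segments$width <- 3
  g2 <- toy_graph(from = c(1, 3), to = c(3, 2), weight = NA_real_)
  g2$segments$length <- c(4, 6); g2$segments$width <- 3
  s1 <- wdd_samples(apply_weights(g1, 1, 1))
  s2 <- wdd_samples(apply_weights(g2, 1, 1))
  expect_equal(sum(s1$value), sum(s2$value))
  # with w = W instead, each half carries the full width: sum(s) doubles
  w1 <- wdd_samples(apply_weights(g1, 0, 1))
  w2 <- wdd_samples(apply_weights(g2, 0, 1))
  expect_equal(2 * sum(w1$value), sum(w2$value))
})

test_that("basic counts use the quoted degree definitions", {
  expect_equal(basic_counts(extract_graph(line_skeleton(30))),
               tibble::tibble(nodes = 2, links = 1, endpoints = 2,
                              bifurcations = 0))
  bc <- basic_counts(extract_graph(plus_skeleton(8)))
  expect_equal(bc$nodes, 5); expect_equal(bc$links, 4)
  expect_equal(bc$endpoints, 4); expect_equal(bc$bifurcations, 1)
})
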