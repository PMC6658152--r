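test_that("common bin edges span the pooled percentile range", {
  withr::local_seed(9)
  sets <- list(runif(5000, 0, 10), runif(5000, 0, 10))
  edges <- common_bin_edges(sets, n_bins = 10)
  expect_length(edges, 11)
  expect_equal(edges, seq(edges[1], edges[11], length.out = 11))
  expect_lt(edges[1], 0.2); expect_gt(edges[11], 9.8)
  expect_error(common_bin_edges(list(rep(5, 10), rep(5, 3))), "zero range")
})

test_that("histograms normalize, clip, and localize correctly", {
  edges <- 0:4
  expect_equal(to_histogram(c(1.5, 1.2), edges), c(0, 1, 0, 0))
  expect_equal(to_histogram(c(0.5, 0.1, 2.2, 2.9), edges),
               c(0.5, 0, 0.5, 0))
  # out-of-range values fall into the end bins
  expect_equal(to_histogram(c(-5, 9), edges), c(0.5, 0, 0, 0.5))
  withr::local_seed(10)
  h <- to_histogram(rnorm(1000), seq(-3, 3, length.out = 65))
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_error(to_histogram(numeric(0), edges), "empty")
})

test_that("JS divergence matches closed forms and its bounds", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(js_divergence(p, p), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
  # direct evaluation of the defining formula for (0.5, 0.5) vs (1, 0)
  expect_equal(js_divergence(c(0.5, 0.5), c(1, 0)), 0.2157616,
               tolerance = 1e-6)
  expect_error(js_divergence(c(0.5, 0.2), c(0.5, 0.5)), "sum to 1")
  expect_error(js_divergence(c(1, 0, 0), c(1, 0)), "equal length")

  withr::local_seed(21)
  for (i in 1:50) {
    a <- runif(16); a <- a / sum(a)
    b <- runif(16); b <- b / sum(b)
    d <- js_divergence(a, b)
    expect_gte(d, 0); expect_lte(d, log(2) + 1e-12)
    expect_equal(d, js_divergence(b, a), tolerance = 1e-12)
  }
})

test_that("divergence matrices are symmetric with zero diagonal", {
  withr::local_seed(22)
  probs <- t(replicate(5, { x <- runif(8); x / sum(x) }))
  m <- divergence_matrix(probs)
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(diag(m), rep(0, 5))
  expect_equal(m[2, 4], js_divergence(probs[2, ], probs[4, ]))
  same <- matrix(rep(probs[1, ], 3), 3, byrow = TRUE)
  expect_equal(max(abs(divergence_matrix(same))), 0)
  expect_error(divergence_matrix(probs[1:2, ]), "at least 3")
})

test_that("IsoMap with a complete neighbourhood reduces to classical MDS", {
  withr::local_seed(23)
  x <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(x))
  emb <- isomap_2d(d, k = 9)
  mds <- cmdscale(d, k = 2)
  for (j in 1:2) {
    i_max <- which.max(abs(mds[, j]))
    if (mds[i_max, j] < 0) mds[, j] <- -mds[, j]
  }
  expect_lt(max(abs(as.matrix(emb[, c("iso1", "iso2")]) - mds)), 1e-8)
})

test_that("IsoMap reproduces collinear configurations up to isometry", {
  pos <- c(0, 1, 2.5, 3, 4.7, 6, 7.2, 8, 9.5, 11)
  d <- abs(outer(pos, pos, "-"))
  emb <- isomap_2d(d, k = 3)
  rec <- emb$iso1 - emb$iso1[1]
  truth <- pos - pos[1]
  if (rec[10] < 0) rec <- -rec
  expect_lt(max(abs(rec - truth)), 1e-6)
  expect_lt(max(abs(emb$iso2)), 1e-6)
})

test_that("IsoMap embeds symmetric and duplicated configurations faithfully", {
  d3 <- matrix(1, 3, 3) - diag(3)
  emb3 <- isomap_2d(d3, k = 2)
  pd <- dist(as.matrix(emb3[, c("iso1", "iso2")]))
  expect_lt(diff(range(pd)), 1e-6)

  # duplicated image: zero divergence twins embed at the same point
  withr::local_seed(24)
  x <- matrix(rnorm(12), 6, 2)
  x <- rbind(x, x[1, ])
  d <- as.matrix(dist(x))
  emb <- isomap_2d(d, k = 3)
  expect_lt(sqrt((emb$iso1[7] - emb$iso1[1])^2 +
                 (emb$iso2[7] - emb$iso2[1])^2), 1e-8)
  expect_error(isomap_2d(d3[1:2, 1:2], k = 2), "at least 3")
})

test_that("IsoMap agrees with the reference implementation", {
  skip_if_not_installed("vegan")
  withr::local_seed(25)
  x <- matrix(rnorm(40), 20, 2)
  d <- as.matrix(dist(x))
  emb <- isomap_2d(d, k = 6)
  ref <- vegan::isomap(as.dist(d), ndim = 2, k = 6)$points
  # same configuration up to reflection/sign per axis
  for (j in 1:2) {
    r <- ref[, j]
    agree <- min(max(abs(emb[[paste0("iso", j)]] - r)),
                 max(abs(emb[[paste0("iso", j)]] + r)))
    expect_lt(agree, 1e-6)
  }
})

test_that("ttest2 matches the pooled-variance formula and its symmetries", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  # hand-computed pooled t
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(abs(t_hand), df = 6, lower.tail = FALSE)
  tt <- ttest2(a, b)
  expect_equal(tt$statistic, t_hand, tolerance = 1e-12)
  expect_equal(tt$df, 6)
  expect_equal(tt$p_value, p_hand, tolerance = 1e-12)

  sw <- ttest2(b, a)
  expect_equal(sw$statistic, -tt$statistic)
  expect_equal(sw$p_value, tt$p_value)

  id <- ttest2(c(2, 2, 2), c(2, 2, 2))
  expect_equal(id$statistic, 0); expect_equal(id$p_value, 1)
  dg <- ttest2(c(1, 1), c(2, 2))
  expect_equal(dg$p_value, 0); expect_true(dg$degenerate)
})

test_that("group separation detects separated groups and respects rotation", {
  withr::local_seed(26)
  n <- 15
  x <- rbind(cbind(rnorm(n, 0, 1), rnorm(n, 0, 1)),
             cbind(rnorm(n, 3, 1), rnorm(n, 0, 1)))
  labels <- rep(c("h", "d"), each = n)
  gt <- group_separation(x, labels)
  expect_lt(gt$p_value, 0.05)

  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  gt2 <- group_separation(x %*% t(rot), labels)
  expect_equal(gt2$p_value, gt$p_value, tolerance = 1e-9)

  gt3 <- group_separation(x, labels, method = "first_coordinate")
  expect_equal(gt3$method, "first_coordinate")
  expect_lt(gt3$p_value, 0.05)
})

test_that("selection-corrected p equals the Hotelling F transform", {
  withr::local_seed(27)
  x <- matrix(rnorm(40), 20, 2)
  labels <- rep(c("a", "b"), each = 10)
  gt <- group_separation(x, labels, p_correction = "selection")
  t2 <- gt$statistic^2
  f <- t2 * (20 - 1 - 2) / ((20 - 2) * 2)
  expect_equal(gt$p_value, pf(f, 2, 17, lower.tail = FALSE))
  naive <- group_separation(x, labels, p_correction = "none")
  expect_gt(gt$p_value, naive$p_value)   # correction is less optimistic
})
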