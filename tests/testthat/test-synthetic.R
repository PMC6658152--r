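test_that("degenerate specs produce the smallest trees", {
  spec <- tree_spec(n_trunks = 1, branch_probability = 0, max_depth = 1,
                    seed = 4)
  img <- generate_vessel_tree(spec)
  expect_equal(nrow(img$tree$nodes), 2)
  expect_equal(nrow(img$tree$segments), 1)
  expect_gt(sum(img$mask), 0)

  spec0 <- tree_spec(n_trunks = 1, branch_probability = 0.9, max_depth = 0,
                     seed = 4)
  img0 <- generate_vessel_tree(spec0)
  expect_equal(nrow(img0$tree$segments), 1)
})

test_that("perfect binary tree bookkeeping matches brute-force traversal", {
  spec <- tree_spec(image_size = 1200, root_position = c(600, 600),
                    n_trunks = 1, branch_probability = 1,
                    max_depth = 4, initial_length = 130, root_width = 4,
                    branch_angle_spread = 0.5, avoid_overlap = FALSE,
                    length_jitter = 0, angle_jitter = 0,
                    render_image = FALSE, seed = 11)
  img <- generate_vessel_tree(spec)
  tr <- img$tree
  # traversal oracle: walk the emitted segment list from the root
  adj <- split(seq_len(nrow(tr$segments)),
               factor(tr$segments$from, levels = tr$nodes$id))
  n_leaves <- 0; n_internal <- 0
  walk <- function(v) {
    kids <- adj[[v]]
    if (is.null(kids) || length(kids) == 0) {
      n_leaves <<- n_leaves + 1
    } else {
      if (v != 1) n_internal <<- n_internal + 1
      for (s in kids) walk(tr$segments$to[s])
    }
  }
  walk(1L)
  # depth-4 perfect binary tree rooted at a single trunk
  expect_equal(n_leaves, 16)
  expect_equal(n_internal, 15)
  tc <- tree_counts(tr)
  expect_equal(tc$endpoints, n_leaves + 1)      # root of a single trunk
  expect_equal(tc$bifurcations, n_internal)
  expect_equal(tc$links, tc$nodes - 1)
})

test_that("generation is a pure function of the spec", {
  spec <- tree_spec(seed = 21, thin_branch_rate = 0.4)
  a <- generate_vessel_tree(spec)
  b <- generate_vessel_tree(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$tree, b$tree)
})

test_that("rasterized tree is one connected component", {
  for (s in c(2, 9)) {
    img <- generate_vessel_tree(tree_spec(seed = s, render_image = FALSE))
    comp <- fundusgraph:::cc_label_cpp(img$mask)
    expect_equal(max(comp), 1)
  }
})

test_that("cohorts derive per-image seeds deterministically and label groups", {
  h <- tree_spec(seed = 1, render_image = FALSE, image_size = 256,
                 max_depth = 2)
  expect_length(generate_cohort(h, h, 0), 0)
  co <- generate_cohort(h, h, 2, seed = 5, labels = c("a", "b"))
  co2 <- generate_cohort(h, h, 2, seed = 5, labels = c("a", "b"))
  expect_identical(lapply(co, `[[`, "mask"), lapply(co2, `[[`, "mask"))
  expect_equal(vapply(co, `[[`, "", "group_label"), c("a", "a", "b", "b"))
  expect_false(identical(co[[1]]$mask, co[[2]]$mask))
})

test_that("thin side branches raise width-sensitive strength means", {
  h <- tree_spec(seed = 1, render_image = FALSE)
  d <- tree_spec(seed = 1, render_image = FALSE, thin_branch_rate = 1.5)
  cfg <- run_config(use_ground_truth_mask = TRUE)
  co <- generate_cohort(h, d, 3, seed = 31)
  recs <- lapply(co, run_image, config = cfg)
  mean_links <- vapply(recs, function(r) r$counts$links, numeric(1))
  expect_gt(mean(mean_links[4:6]), mean(mean_links[1:3]))
})

test_that("DLA aggregates are deterministic, connected, and capacity-checked", {
  expect_equal(sum(generate_dla(1, 128)), 1)
  a <- generate_dla(400, 256, seed = 3)
  b <- generate_dla(400, 256, seed = 3)
  expect_identical(a, b)
  comp <- fundusgraph:::cc_label_cpp(a)
  expect_equal(max(comp), 1)              # flood fill reaches every particle
  expect_equal(sum(a), 400)
  expect_error(generate_dla(20000, 128), "lattice too small")
})

test_that("phantoms have their closed-form rasters", {
  expect_equal(sum(make_phantom("filled_square", 64)), 64^2)
  ln <- make_phantom("line", 64)
  expect_equal(sum(ln), 64)
  expect_equal(sum(rowSums(ln) > 0), 1)
  expect_equal(sum(make_phantom("sierpinski_carpet", 729)), 8^6)
  expect_error(make_phantom("sierpinski_carpet", 700), "power of 3")
})

test_that("synthetic images round-trip through disk and manifest", {
  dir <- withr::local_tempdir()
  img <- generate_vessel_tree(tree_spec(seed = 2, image_size = 256,
                                        max_depth = 2))
  img$group_label <- "healthy"
  paths <- write_synthetic(img, dir, "t")
  expect_true(all(file.exists(unlist(paths))))
  m <- load_mask(paths$mask)
  expect_true(all(unclass(m) == img$mask))
  expect_equal(dim(m), dim(img$mask))
  co <- generate_cohort(tree_spec(seed = 1, image_size = 256, max_depth = 2),
                        tree_spec(seed = 1, image_size = 256, max_depth = 2),
                        1, seed = 9)
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(man$path)))
})
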