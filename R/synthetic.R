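#' Specify a synthetic vascular tree
#'
#' A `tree_spec` collects every parameter of the synthetic fundus generator:
#' a bright optic disc at the tree root from which `n_trunks` dark vessels
#' fan out and branch dichotomously, with lengths and widths tapering per
#' generation. Two disease surrogates are available: `thin_branch_rate`
#' grafts extra short, thin side branches onto existing vessels
#' (a neovascularization proxy) and `width_scale` rescales every calibre
#' (an intraocular-pressure proxy).
#'
#' @param image_size side of the square image in pixels (>= 256).
#' @param root_position `(row, col)` of the optic-disc centre; default is
#'   mid-height at 16% of the width, as in a typical fundus photograph.
#' @param root_width trunk calibre in pixels at the disc.
#' @param n_trunks number of main vessels leaving the disc.
#' @param branch_probability probability that a vessel bifurcates at the end
#'   of each segment; either a scalar or a vector with one entry per
#'   generation.
#' @param max_depth maximum branching generation; `0` yields single root
#'   segments with no bifurcations.
#' @param initial_length trunk segment length in pixels.
#' @param length_decay,width_decay multiplicative decay of segment length and
#'   width per generation, in (0, 1].
#' @param branch_angle_spread half-angle between daughter branches, radians.
#' @param angle_jitter,length_jitter relative random jitter on direction and
#'   length.
#' @param thin_branch_rate expected number of extra short thin side branches
#'   per segment (Poisson).
#' @param thin_branch_width calibre of the grafted side branches, pixels.
#' @param width_scale global multiplier applied to all widths.
#' @param disc_radius optic-disc radius in pixels.
#' @param avoid_overlap if `TRUE`, candidate branches that would pass too
#'   close to an existing vessel are re-aimed or dropped, keeping the
#'   rasterized tree clean for graph-recovery validation.
#' @param margin border margin in pixels; segments are clipped there.
#' @param render_image compose the RGB pseudo-fundus raster; set `FALSE`
#'   when only the mask and ground truth are needed (the mask is identical
#'   either way).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return an object of class `tree_spec`.
#' @export
tree_spec <- function(image_size = 512,
                      root_position = NULL,
                      root_width = 8,
                      n_trunks = 4,
                      branch_probability = 0.85,
                      max_depth = 6,
                      initial_length = image_size / 5.5,
                      length_decay = 0.82,
                      width_decay = 0.8,
                      branch_angle_spread = 0.55,
                      angle_jitter = 0.1,
                      length_jitter = 0.12,
                      thin_branch_rate = 0,
                      thin_branch_width = 1.5,
                      width_scale = 1,
                      disc_radius = image_size / 16,
                      avoid_overlap = TRUE,
                      margin = 6,
                      render_image = TRUE,
                      seed = 1L) {
  if (image_size < 256) abort("image_size must be >= 256")
  if (root_width < 1) abort("root_width must be >= 1")
  if (thin_branch_rate < 0 || width_scale <= 0 || n_trunks < 1)
    abort("all rates must be >= 0 and width_scale, n_trunks positive")
  if (any(branch_probability < 0 | branch_probability > 1))
    abort("branch_probability must lie in [0, 1]")
  if (is.null(root_position)) root_position <- c(image_size / 2, 0.16 * image_size)
  structure(
    list(image_size = as.integer(image_size), root_position = root_position,
         root_width = root_width, n_trunks = as.integer(n_trunks),
         branch_probability = branch_probability,
         max_depth = as.integer(max_depth), initial_length = initial_length,
         length_decay = length_decay, width_decay = width_decay,
         branch_angle_spread = branch_angle_spread,
         angle_jitter = angle_jitter, length_jitter = length_jitter,
         thin_branch_rate = thin_branch_rate,
         thin_branch_width = thin_branch_width, width_scale = width_scale,
         disc_radius = disc_radius, avoid_overlap = avoid_overlap,
         margin = margin, render_image = render_image,
         seed = as.integer(seed)),
    class = "tree_spec")
}

# vectorized point-to-segment distance: points (pr, pc) against segments
# (ar, ac)-(br, bc); all arguments recycle
pt_seg_dist <- function(pr, pc, ar, ac, br, bc) {
  abr <- br - ar; abc <- bc - ac
  den <- pmax(abr^2 + abc^2, 1e-300)   # degenerate segments act as points
  t <- pmin(pmax(((pr - ar) * abr + (pc - ac) * abc) / den, 0), 1)
  sqrt((ar + t * abr - pr)^2 + (ac + t * abc - pc)^2)
}

#' Generate a ground-truthed synthetic fundus image
#'
#' Grows a branching vascular tree according to `spec`, rasterizes it as
#' anti-aliased thick strokes thresholded at 0.5 intensity, and composes a
#' pseudo-fundus RGB raster (orange background, vessels darker than the
#' background, bright disc at the root). The ground-truth graph bookkeeping
#' (nodes, segments with centerline length and width) matches the
#' rasterization: degree-2 construction nodes are contracted away so the
#' returned tree contains only the root, bifurcations and endpoints.
#'
#' @param spec a [tree_spec()].
#' @return an object of class `synthetic_fundus`: a list with elements
#'   `image` (H x W x 3 array in \[0,1\]), `mask` (integer matrix, 1 =
#'   vessel), `tree` (a `vessel_tree`: `nodes` and `segments` tibbles),
#'   `disc` (centre + radius), `group_label`, and `clipped` (flag set when
#'   any segment was clipped at the image border).
#' @export
generate_vessel_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  withr::with_seed(spec$seed, grow_tree_impl(spec))
}

grow_tree_impl <- function(spec) {
  size <- spec$image_size
  margin <- spec$margin
  bp <- spec$branch_probability
  bp_at <- function(g) bp[min(g, length(bp))]

  nodes <- list(list(row = spec$root_position[1], col = spec$root_position[2],
                     kind = "root"))
  segs <- list()   # from, to, width (straight strokes, drawn as-is)
  clipped <- FALSE

  seg_mat <- function() {
    if (!length(segs)) return(NULL)
    t(vapply(segs, function(s) {
      c(nodes[[s$from]]$row, nodes[[s$from]]$col,
        nodes[[s$to]]$row, nodes[[s$to]]$col, s$width, s$from, s$to)
    }, numeric(7)))
  }

  too_close <- function(p0, p1, w, start_node) {
    sm <- seg_mat()
    if (is.null(sm)) return(FALSE)
    keep <- sm[, 6] != start_node & sm[, 7] != start_node
    if (!any(keep)) return(FALSE)
    sm <- sm[keep, , drop = FALSE]
    q0r <- sm[, 1]; q0c <- sm[, 2]; q1r <- sm[, 3]; q1c <- sm[, 4]
    thr <- (w + sm[, 5]) / 2 + 3
    d <- pmin(pt_seg_dist(p0[1], p0[2], q0r, q0c, q1r, q1c),
              pt_seg_dist(p1[1], p1[2], q0r, q0c, q1r, q1c),
              pt_seg_dist(q0r, q0c, p0[1], p0[2], p1[1], p1[2]),
              pt_seg_dist(q1r, q1c, p0[1], p0[2], p1[1], p1[2]))
    o <- function(ar, ac, br, bc, cr, cc)
      (br - ar) * (cc - ac) - (bc - ac) * (cr - ar)
    d1 <- o(q0r, q0c, q1r, q1c, p0[1], p0[2])
    d2 <- o(q0r, q0c, q1r, q1c, p1[1], p1[2])
    d3 <- o(p0[1], p0[2], p1[1], p1[2], q0r, q0c)
    d4 <- o(p0[1], p0[2], p1[1], p1[2], q1r, q1c)
    any((d1 * d2 < 0 & d3 * d4 < 0) | d < thr)
  }

  add_node <- function(row, col, kind) {
    nodes[[length(nodes) + 1]] <<- list(row = row, col = col, kind = kind)
    length(nodes)
  }

  # committed outgoing directions per node: vessels leaving one node keep a
  # minimum angular separation or their strokes fuse into a single one
  angles_at <- list()
  register_angle <- function(node, a) {
    key <- as.character(node)
    angles_at[[key]] <<- c(angles_at[[key]], a)
  }
  angle_clash <- function(node, a, min_sep = 0.35) {
    key <- as.character(node)
    if (is.null(angles_at[[key]])) return(FALSE)
    diffs <- abs((angles_at[[key]] - a + pi) %% (2 * pi) - pi)
    any(diffs < min_sep)
  }

  # active tips: list of (node, angle, width, depth)
  trunk_angles <- seq(-0.95, 0.95, length.out = spec$n_trunks) +
    runif(spec$n_trunks, -0.5, 0.5) * spec$angle_jitter
  tips <- lapply(trunk_angles, function(a) {
    list(node = 1L, angle = a, width = spec$root_width, depth = 0L)
  })

  while (length(tips)) {
    tip <- tips[[1]]; tips <- tips[-1]
    len <- spec$initial_length * spec$length_decay^tip$depth *
      (1 + runif(1, -1, 1) * spec$length_jitter)
    placed <- FALSE
    p0 <- c(nodes[[tip$node]]$row, nodes[[tip$node]]$col)
    ang <- tip$angle
    for (try in 1:5) {
      a <- ang + (try - 1) * sample(c(-1, 1), 1) * 0.3
      p1 <- p0 + len * c(sin(a), cos(a))
      was_clipped <- FALSE
      if (any(p1 < margin) || any(p1 > size - margin)) {
        # clip along the direction to the border margin
        tt <- 1
        dir <- p1 - p0
        for (k in 1:2) {
          if (dir[k] > 0) tt <- min(tt, ((size - margin) - p0[k]) / dir[k])
          if (dir[k] < 0) tt <- min(tt, (margin - p0[k]) / dir[k])
        }
        p1 <- p0 + max(tt, 0) * dir
        was_clipped <- TRUE
      }
      # stubs shorter than ~2 widths erode away under thinning; reject them
      if (sqrt(sum((p1 - p0)^2)) < max(6, 1.8 * tip$width)) next
      if (spec$avoid_overlap &&
          (angle_clash(tip$node, a) || too_close(p0, p1, tip$width, tip$node)))
        next
      nid <- add_node(p1[1], p1[2], "endpoint")
      segs[[length(segs) + 1]] <- list(from = tip$node, to = nid,
                                       width = tip$width)
      register_angle(tip$node, a)
      register_angle(nid, a + pi)
      clipped <- clipped || was_clipped
      placed <- TRUE
      if (!was_clipped && tip$depth < spec$max_depth &&
          runif(1) < bp_at(tip$depth + 1)) {
        nodes[[nid]]$kind <- "bifurcation"
        spread <- spec$branch_angle_spread *
          (1 + runif(2, -0.5, 0.5) * spec$angle_jitter * 2)
        for (s in c(-1, 1)) {
          tips[[length(tips) + 1]] <- list(
            node = nid, angle = a + s * spread[(s + 3) / 2],
            width = max(1, tip$width * spec$width_decay),
            depth = tip$depth + 1L)
        }
      }
      break
    }
    if (!placed) next  # branch dropped; degree-2 parents contracted later
  }

  # graft thin side branches (neovascularization surrogate)
  if (spec$thin_branch_rate > 0 && length(segs)) {
    n_main <- length(segs)
    for (i in seq_len(n_main)) {
      k <- rpois(1, spec$thin_branch_rate)
      if (k == 0) next
      s <- segs[[i]]
      p0 <- c(nodes[[s$from]]$row, nodes[[s$from]]$col)
      p1 <- c(nodes[[s$to]]$row, nodes[[s$to]]$col)
      seg_len <- sqrt(sum((p1 - p0)^2))
      if (seg_len < 20) next
      base_ang <- atan2(p1[1] - p0[1], p1[2] - p0[2])
      ts <- sort(runif(k, 0.25, 0.75))
      prev_node <- s$from
      for (j in seq_len(k)) {
        at <- p0 + ts[j] * (p1 - p0)
        mid <- add_node(at[1], at[2], "bifurcation")
        segs[[length(segs) + 1]] <- list(from = prev_node, to = mid,
                                         width = s$width)
        side_ang <- base_ang + sample(c(-1, 1), 1) * runif(1, 0.6, 1.2)
        side_len <- max(10, 0.3 * seg_len)
        q <- at + side_len * c(sin(side_ang), cos(side_ang))
        q <- pmin(pmax(q, margin), size - margin)
        if (!(spec$avoid_overlap &&
              too_close(at, q, spec$thin_branch_width, mid))) {
          tipn <- add_node(q[1], q[2], "endpoint")
          segs[[length(segs) + 1]] <- list(from = mid, to = tipn,
                                           width = spec$thin_branch_width)
        }
        prev_node <- mid
      }
      segs[[i]] <- list(from = prev_node, to = s$to, width = s$width)
    }
  }

  # apply the global calibre scale, floor at 1 px
  for (i in seq_along(segs))
    segs[[i]]$width <- max(1, segs[[i]]$width * spec$width_scale)

  tree <- build_truth_tree(nodes, segs)
  raster <- rasterize_tree(nodes, segs, spec)
  structure(
    list(image = raster$image, mask = raster$mask, tree = tree,
         disc = list(center = spec$root_position, radius = spec$disc_radius),
         group_label = NA_character_, clipped = clipped, spec = spec),
    class = "synthetic_fundus")
}

# Contract degree-2 construction nodes (dropped twins, side-branch stubs)
# into polyline segments so the logical tree only keeps root/bifurcation/
# endpoint nodes; lengths add, widths average weighted by length.
build_truth_tree <- function(nodes, segs) {
  n <- length(nodes)
  if (!length(segs)) {
    nd <- tibble::tibble(id = 1L, row = nodes[[1]]$row, col = nodes[[1]]$col,
                         kind = "root")
    return(structure(list(nodes = nd,
                          segments = tibble::tibble(id = integer(), from = integer(),
                                                    to = integer(), length = numeric(),
                                                    width = numeric())),
                     class = "vessel_tree"))
  }
  from <- vapply(segs, `[[`, 0, "from")
  to <- vapply(segs, `[[`, 0, "to")
  wid <- vapply(segs, `[[`, 0, "width")
  pos <- t(vapply(nodes, function(x) c(x$row, x$col), numeric(2)))
  len <- sqrt((pos[from, 1] - pos[to, 1])^2 + (pos[from, 2] - pos[to, 2])^2)
  deg <- tabulate(c(from, to), nbins = n)

  adj <- vector("list", n)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- c(adj[[from[i]]], i)
    adj[[to[i]]] <- c(adj[[to[i]]], i)
  }
  keep <- which(deg != 2 | seq_len(n) == 1L)   # root always kept
  is_node <- logical(n); is_node[keep] <- TRUE

  seg_used <- logical(length(from))
  out_from <- integer(); out_to <- integer()
  out_len <- numeric(); out_wid <- numeric()
  for (v in keep) {
    for (e in adj[[v]]) {
      if (seg_used[e]) next
      # walk through degree-2 nodes
      total_len <- len[e]; wsum <- wid[e] * len[e]
      seg_used[e] <- TRUE
      cur <- if (from[e] == v) to[e] else from[e]
      prev_e <- e
      while (!is_node[cur]) {
        nxt <- setdiff(adj[[cur]], prev_e)[1]
        seg_used[nxt] <- TRUE
        total_len <- total_len + len[nxt]
        wsum <- wsum + wid[nxt] * len[nxt]
        cur <- if (from[nxt] == cur) to[nxt] else from[nxt]
        prev_e <- nxt
      }
      out_from <- c(out_from, v); out_to <- c(out_to, cur)
      out_len <- c(out_len, total_len)
      out_wid <- c(out_wid, wsum / total_len)
    }
  }
  remap <- match(seq_len(n), keep)
  nd <- tibble::tibble(
    id = seq_along(keep),
    row = pos[keep, 1], col = pos[keep, 2],
    kind = vapply(nodes[keep], `[[`, "", "kind"))
  st <- tibble::tibble(id = seq_along(out_from),
                       from = remap[out_from], to = remap[out_to],
                       length = out_len, width = out_wid)
  structure(list(nodes = nd, segments = st), class = "vessel_tree")
}

# Anti-aliased thick strokes into a float canvas, thresholded at 0.5 for the
# mask; pseudo-fundus composite for the RGB raster.
rasterize_tree <- function(nodes, segs, spec) {
  size <- spec$image_size
  canvas <- matrix(0, size, size)
  for (s in segs) {
    p0 <- c(nodes[[s$from]]$row, nodes[[s$from]]$col)
    p1 <- c(nodes[[s$to]]$row, nodes[[s$to]]$col)
    hw <- s$width / 2
    r0 <- max(1, floor(min(p0[1], p1[1]) - hw - 1))
    r1 <- min(size, ceiling(max(p0[1], p1[1]) + hw + 1))
    c0 <- max(1, floor(min(p0[2], p1[2]) - hw - 1))
    c1 <- min(size, ceiling(max(p0[2], p1[2]) + hw + 1))
    rr <- r0:r1; cc <- c0:c1
    ab <- p1 - p0
    den <- sum(ab^2)
    pr <- outer(rr - p0[1], rep(1, length(cc)))
    pc <- outer(rep(1, length(rr)), cc - p0[2])
    tt <- if (den == 0) pr * 0 else (pr * ab[1] + pc * ab[2]) / den
    tt <- pmin(pmax(tt, 0), 1)
    d <- sqrt((pr - tt * ab[1])^2 + (pc - tt * ab[2])^2)
    stroke <- pmin(1, pmax(0, hw + 0.5 - d))
    canvas[rr, cc] <- pmax(canvas[rr, cc], stroke)
  }
  mask <- matrix(as.integer(canvas >= 0.5), size, size)
  if (!isTRUE(spec$render_image)) return(list(image = NULL, mask = mask))

  idx_r <- matrix(seq_len(size), size, size)
  idx_c <- t(idx_r)
  ctr <- (size + 1) / 2
  vign <- 1 - 0.35 * (((idx_r - ctr)^2 + (idx_c - ctr)^2) / ctr^2)
  d_disc <- sqrt((idx_r - spec$root_position[1])^2 +
                 (idx_c - spec$root_position[2])^2)
  disc <- exp(-(d_disc / spec$disc_radius)^4)
  dark <- 1 - 0.55 * canvas
  base <- list(r = 0.82, g = 0.48, b = 0.20)
  img <- array(0, dim = c(size, size, 3))
  img[, , 1] <- (base$r * vign + 0.16 * disc) * (1 - 0.35 * canvas)
  img[, , 2] <- (base$g * vign + 0.40 * disc) * dark
  img[, , 3] <- (base$b * vign + 0.30 * disc) * dark
  noise <- matrix(rnorm(size * size, sd = 0.012), size, size)
  for (k in 1:3) img[, , k] <- pmin(1, pmax(0, img[, , k] + noise))
  list(image = img, mask = mask)
}

#' Degree-based counts of a ground-truth tree
#'
#' Counts nodes, segments, endpoints (degree 1) and bifurcations (degree >= 3)
#' of a `vessel_tree`, using the same degree definitions as
#' [basic_counts()] so generator bookkeeping and graph extraction are
#' directly comparable.
#'
#' @param tree a `vessel_tree` (the `tree` element of a `synthetic_fundus`).
#' @return a one-row tibble with columns `nodes`, `links`, `endpoints`,
#'   `bifurcations`.
#' @export
tree_counts <- function(tree) {
  deg <- tabulate(c(tree$segments$from, tree$segments$to),
                  nbins = nrow(tree$nodes))
  tibble::tibble(nodes = nrow(tree$nodes), links = nrow(tree$segments),
                 endpoints = sum(deg == 1), bifurcations = sum(deg >= 3))
}

#' Generate a two-group synthetic cohort
#'
#' Draws `n_per_group` images from each of two tree specifications, with
#' per-image seeds derived deterministically from the cohort seed, and
#' attaches group labels.
#'
#' @param healthy,disease [tree_spec()] objects for the two groups.
#' @param n_per_group images per group (0 gives an empty cohort).
#' @param seed cohort-level seed.
#' @param labels character vector of two group labels.
#' @return a list of `synthetic_fundus` objects with `group_label` set,
#'   classed `synthetic_cohort`.
#' @export
generate_cohort <- function(healthy, disease, n_per_group, seed = 1L,
                            labels = c("healthy", "disease")) {
  stopifnot(n_per_group >= 0)
  if (n_per_group == 0) return(structure(list(), class = "synthetic_cohort"))
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max, 2 * n_per_group))
  out <- vector("list", 2 * n_per_group)
  for (i in seq_len(n_per_group)) {
    sh <- healthy; sh$seed <- seeds[i]
    img <- generate_vessel_tree(sh)
    img$group_label <- labels[1]
    out[[i]] <- img
    sd2 <- disease; sd2$seed <- seeds[n_per_group + i]
    img <- generate_vessel_tree(sd2)
    img$group_label <- labels[2]
    out[[n_per_group + i]] <- img
  }
  structure(out, class = "synthetic_cohort")
}

#' Grow a diffusion-limited aggregation cluster
#'
#' On-lattice DLA with noise reduction: random walkers are released around
#' the cluster and stick on 4-neighbour contact with probability
#' `stick_prob`; walkers wandering beyond three cluster radii are
#' discarded. Noise reduction (sticking probability below 1) is the
#' standard way to reach the asymptotic DLA scaling at desk-scale particle
#' counts: it thickens the single-particle branch tips whose dust otherwise
#' depresses small-scale box counts. The planar DLA cluster has fractal
#' dimension close to 1.7, which makes it a physically motivated phantom
#' for the fractal estimator.
#'
#' @param particles number of particles in the aggregate (>= 1).
#' @param lattice lattice side in pixels.
#' @param seed integer seed.
#' @param stick_prob sticking probability on contact (noise reduction).
#' @return binary integer matrix (the aggregate mask).
#' @export
generate_dla <- function(particles, lattice = 1024, seed = 1L,
                         stick_prob = 0.05) {
  stopifnot(particles >= 1, lattice >= 64,
            stick_prob > 0, stick_prob <= 1)
  # crude upfront capacity check; growth errors too if the estimate is beaten
  est_radius <- 0.8 * particles^(1 / 1.71) + 10
  if (est_radius > lattice / 2 - 5)
    abort("lattice too small for particle count")
  withr::with_seed(seed, dla_grow_cpp(as.integer(lattice),
                                      as.integer(particles), stick_prob))
}

# dyadic box scales capped at a fraction of the object's own radius (the
# saturation cutoff), independent of how much empty lattice surrounds it
object_scales <- function(mask, fraction = 1 / 4, min_scales = 4) {
  idx <- which(unclass(mask) != 0, arr.ind = TRUE)
  ctr <- colMeans(idx)
  r <- max(sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2))
  kmax <- max(min_scales, floor(log2(max(r * fraction, 2))))
  2^(seq_len(kmax))
}

#' Box-counting dimension of DLA aggregates
#'
#' Grows one aggregate per seed, box-counts it over dyadic scales capped at
#' a quarter of the cluster radius (beyond which counts saturate), and fits
#' the scaling exponent.
#'
#' @param particles particles per aggregate.
#' @param lattice lattice side in pixels.
#' @param seeds integer vector of seeds, one aggregate each.
#' @param stick_prob sticking probability (see [generate_dla()]).
#' @return tibble with one row per seed (`seed`, `dimension`, `r_squared`)
#'   and the across-seed mean in attribute `mean_dimension`.
#' @export
dla_dimension <- function(particles = 20000, lattice = 1024, seeds = 1:3,
                          stick_prob = 0.05) {
  rows <- lapply(seeds, function(s) {
    m <- generate_dla(particles, lattice, seed = s, stick_prob = stick_prob)
    fit <- fit_dimension(box_count(m, scales = object_scales(m)))
    tibble::tibble(seed = s, dimension = fit$dimension,
                   r_squared = fit$r_squared)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_dimension") <- mean(out$dimension)
  out
}

#' Analytic fractal phantoms
#'
#' Deterministic binary masks with known box-counting dimension: a filled
#' square (D = 2), a one-pixel line (D = 1), and the Sierpinski carpet
#' (D = log 8 / log 3).
#'
#' @param kind one of `"filled_square"`, `"line"`, `"sierpinski_carpet"`.
#' @param size image side in pixels; the carpet requires a power of 3.
#' @return binary integer matrix.
#' @export
make_phantom <- function(kind = c("filled_square", "line", "sierpinski_carpet"),
                         size = 256) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 1) abort("size must be positive")
  switch(kind,
    filled_square = matrix(1L, size, size),
    line = {
      m <- matrix(0L, size, size)
      m[size %/% 2, ] <- 1L
      m
    },
    sierpinski_carpet = {
      k <- round(log(size) / log(3))
      if (3^k != size) abort("sierpinski_carpet requires size to be a power of 3")
      cell <- matrix(1L, 3, 3); cell[2, 2] <- 0L
      m <- matrix(1L, 1, 1)
      for (i in seq_len(k)) m <- kronecker(cell, m)
      m
    })
}

#' Write a synthetic image, its mask and ground truth to disk
#'
#' Rasters go to PNG, the ground-truth tree to JSON (node and segment
#' records).
#'
#' @param x a `synthetic_fundus`.
#' @param dir output directory (created if missing).
#' @param name base file name.
#' @return invisibly, a named list of the written paths.
#' @export
write_synthetic <- function(x, dir, name = "synthetic") {
  stopifnot(inherits(x, "synthetic_fundus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(name, ".png"))
  mask_path <- file.path(dir, paste0(name, "_mask.png"))
  tree_path <- file.path(dir, paste0(name, "_tree.json"))
  if (is.null(x$image)) {
    img_path <- NULL
  } else {
    png::writePNG(x$image, img_path)
  }
  png::writePNG(matrix(as.numeric(x$mask), nrow(x$mask)), mask_path)
  jsonlite::write_json(
    list(nodes = x$tree$nodes, segments = x$tree$segments,
         disc = x$disc, group_label = x$group_label),
    tree_path, digits = NA, auto_unbox = TRUE)
  invisible(list(image = img_path, mask = mask_path, tree = tree_path))
}

#' Write a synthetic cohort and its manifest
#'
#' Writes each image (raster, mask, ground truth) plus a manifest CSV with
#' columns `path`, `mask_path`, `label`, `seed`, `disc_row`, `disc_col`,
#' `disc_radius` — the format accepted by [run_cohort()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @return the manifest as a tibble (also written to `manifest.csv`).
#' @export
write_cohort <- function(cohort, dir) {
  rows <- purrr::imap(cohort, function(img, i) {
    paths <- write_synthetic(img, dir, sprintf("img%03d", i))
    tibble::tibble(path = paths$image, mask_path = paths$mask,
                   label = img$group_label, seed = img$spec$seed,
                   disc_row = img$disc$center[1], disc_col = img$disc$center[2],
                   disc_radius = img$disc$radius)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
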