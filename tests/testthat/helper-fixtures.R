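# Shared fixtures, all built in code.

as_mask <- function(m) structure(m, class = "vessel_mask", source = "test")

# solid rectangle mask inside a larger frame
rect_mask <- function(h = 5, w = 100, frame = c(20, 120)) {
  m <- matrix(0L, frame[1], frame[2])
  r0 <- (frame[1] - h) %/% 2
  c0 <- (frame[2] - w) %/% 2
  m[r0 + seq_len(h), c0 + seq_len(w)] <- 1L
  as_mask(m)
}

# one-pixel-wide plus sign (two crossing lines), arms of length `arm`
plus_skeleton <- function(arm = 10) {
  n <- 2 * arm + 1
  m <- matrix(0L, n + 4, n + 4)
  mid <- arm + 3
  m[mid, 3:(n + 2)] <- 1L
  m[3:(n + 2), mid] <- 1L
  structure(m, class = "skeleton")
}

line_skeleton <- function(len = 50) {
  m <- matrix(0L, 9, len + 8)
  m[5, 5:(4 + len)] <- 1L
  structure(m, class = "skeleton")
}

# a tree spec whose rasterization is clean enough for graph-recovery checks
clean_tree_spec <- function(seed, size = 512) {
  tree_spec(image_size = size, root_width = 6, max_depth = 4,
            branch_probability = 0.85, initial_length = 95,
            length_decay = 0.85, width_decay = 0.75,
            branch_angle_spread = 0.65, seed = seed)
}

# hand-built weighted graph in the vessel_graph layout
toy_graph <- function(from, to, weight, n_nodes = max(c(from, to)),
                      central = 1L) {
  structure(
    list(nodes = tibble::tibble(id = seq_len(n_nodes),
                                row = as.numeric(seq_len(n_nodes)),
                                col = 0,
                                kind = "bifurcation",
                                degree = tabulate(c(from, to), n_nodes)),
         segments = tibble::tibble(id = seq_along(from), from = from,
                                   to = to, length = 1, n_pixels = 1,
                                   width = 1, weight = weight),
         central_id = central, px_label = NULL, dim = NULL),
    class = "vessel_graph")
}

# exhaustive shortest-path oracle: minimum weight sum over all simple paths
brute_force_distance <- function(from, to, weight, n_nodes, source) {
  best <- rep(Inf, n_nodes)
  best[source] <- 0
  adj <- lapply(seq_len(n_nodes), function(v) {
    i <- which(from == v | to == v)
    data.frame(other = ifelse(from[i] == v, to[i], from[i]), w = weight[i])
  })
  recurse <- function(v, dist, visited) {
    if (dist < best[v]) best[v] <<- dist
    a <- adj[[v]]
    for (i in seq_len(nrow(a))) {
      u <- a$other[i]
      if (!visited[u]) {
        visited[u] <- TRUE
        recurse(u, dist + a$w[i], visited)
        visited[u] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n_nodes)
  visited[source] <- TRUE
  recurse(source, 0, visited)
  best
}

# random connected weighted graph: a random spanning tree plus extra edges
random_weighted_graph <- function(n_nodes, extra = 2) {
  from <- integer(0); to <- integer(0)
  for (v in 2:n_nodes) {
    from <- c(from, sample.int(v - 1, 1)); to <- c(to, v)
  }
  for (i in seq_len(extra)) {
    pair <- sample.int(n_nodes, 2)
    from <- c(from, pair[1]); to <- c(to, pair[2])
  }
  list(from = from, to = to,
       weight = round(runif(length(from), 0.5, 3), 3))
}

# brute-force box counting: explicit double loop over the grid
brute_force_box_count <- function(mask, eps) {
  m <- unclass(mask)
  n <- 0
  for (r0 in seq(1, nrow(m), by = eps)) {
    for (c0 in seq(1, ncol(m), by = eps)) {
      blk <- m[r0:min(r0 + eps - 1, nrow(m)),
               c0:min(c0 + eps - 1, ncol(m)), drop = FALSE]
      if (any(blk != 0)) n <- n + 1
    }
  }
  n
}

# Brute-force oracle on the skeleton's pixel adjacency graph: cluster
# 8-adjacent junction pixels (degree >= 3) into one vertex, keep a single
# direct edge per cluster pair, then contract every degree-2 vertex.
# Returns node count, edge count and sorted degree sequence.
pixel_graph_contraction <- function(skeleton) {
  px <- which(unclass(skeleton) == 1L, arr.ind = TRUE)
  n <- nrow(px)
  key <- paste(px[, 1], px[, 2])
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      j <- match(paste(px[i, 1] + dr, px[i, 2] + dc), key)
      if (!is.na(j) && j > i) { from <- c(from, i); to <- c(to, j) }
    }
  }
  deg <- tabulate(c(from, to), nbins = n)
  # cluster adjacent junction pixels
  rep_of <- seq_len(n)
  find <- function(x) { while (rep_of[x] != x) x <- rep_of[x]; x }
  for (e in seq_along(from)) {
    if (deg[from[e]] >= 3 && deg[to[e]] >= 3)
      rep_of[find(from[e])] <- find(to[e])
  }
  from <- vapply(from, find, integer(1))
  to <- vapply(to, find, integer(1))
  # drop intra-cluster edges; dedupe direct cluster-cluster adjacencies
  intra <- from == to
  from <- from[!intra]; to <- to[!intra]
  jn <- unique(vapply(seq_len(n), find, integer(1))[deg >= 3])
  direct <- from %in% jn & to %in% jn
  pair_key <- paste(pmin(from, to), pmax(from, to))
  dup <- direct & duplicated(pair_key)
  from <- from[!dup]; to <- to[!dup]
  repeat {
    deg2 <- tabulate(c(from, to), nbins = n)
    v <- which(deg2 == 2)
    v <- v[vapply(v, function(x) {
      inc <- which(from == x | to == x)
      length(inc) == 2          # not a self-loop
    }, logical(1))]
    if (!length(v)) break
    x <- v[1]
    inc <- which(from == x | to == x)
    a <- if (from[inc[1]] == x) to[inc[1]] else from[inc[1]]
    b <- if (from[inc[2]] == x) to[inc[2]] else from[inc[2]]
    from <- c(from[-inc], a); to <- c(to[-inc], b)
  }
  deg2 <- tabulate(c(from, to), nbins = n)
  keep <- deg2 > 0
  list(n_nodes = sum(keep), n_edges = length(from),
       degrees = sort(deg2[keep]))
}
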