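#' Skeletonize a vessel mask
#'
#' Topology-preserving Zhang–Suen thinning: every vessel is reduced to a
#' (approximately) one-pixel-wide centerline without changing its length,
#' location or orientation; the 8-connected component count of the mask is
#' preserved.
#'
#' @param mask a `vessel_mask` or 0/1 matrix.
#' @return integer matrix of class `skeleton`.
#' @export
skeletonize <- function(mask) {
  m <- unclass(mask)
  storage.mode(m) <- "integer"
  if (sum(m) == 0) {
    warn("empty mask: skeleton is empty")
    return(structure(m, class = "skeleton"))
  }
  structure(thin_cpp(m), class = "skeleton")
}

# 8-neighbour count of set pixels, computed by shifted sums on a padded copy
neighbour_counts <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- sk
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  acc
}

# Remove tip chains shorter than min_spur pixels that end at a junction
# (thinning artifacts that would otherwise inflate endpoint counts).
prune_spurs <- function(sk, min_spur) {
  if (min_spur <= 0) return(sk)
  repeat {
    nb <- neighbour_counts(sk)
    tips <- which(sk == 1L & nb == 1L)
    removed_any <- FALSE
    for (t in tips) {
      r <- (t - 1) %% nrow(sk) + 1
      c <- (t - 1) %/% nrow(sk) + 1
      path <- list(c(r, c))
      prev <- c(-1L, -1L)
      hit_junction <- FALSE
      while (length(path) < min_spur) {
        cur <- path[[length(path)]]
        nbrs <- neighbours_of(sk, cur[1], cur[2])
        nbrs <- nbrs[!(nbrs[, 1] == prev[1] & nbrs[, 2] == prev[2]), ,
                     drop = FALSE]
        if (nrow(nbrs) == 0) break
        if (nrow(nbrs) > 1) { hit_junction <- TRUE; break }
        nxt <- nbrs[1, ]
        if (nb[nxt[1], nxt[2]] >= 3) { hit_junction <- TRUE; break }
        prev <- cur
        path[[length(path) + 1]] <- nxt
      }
      if (hit_junction && length(path) < min_spur) {
        for (px in path) sk[px[1], px[2]] <- 0L
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  sk
}

# Merge away nodes with exactly two incident (distinct) segments; returns
# updated segment vectors, a map original-segment-id -> merged-segment-id,
# and the contracted node ids. Self-loops are never split or contracted.
contract_degree2 <- function(from, to, len, n_nodes) {
  ns <- length(from)
  alive <- rep(TRUE, ns)
  orig_group <- as.list(seq_len(ns))
  removed <- integer(0)
  repeat {
    idx <- which(alive)
    deg <- tabulate(c(from[idx], to[idx]), nbins = n_nodes)
    progressed <- FALSE
    for (v in which(deg == 2)) {
      inc <- idx[from[idx] == v | to[idx] == v]
      if (length(inc) != 2) next          # a self-loop: leave it alone
      s1 <- inc[1]; s2 <- inc[2]
      a <- if (from[s1] == v) to[s1] else from[s1]
      b <- if (from[s2] == v) to[s2] else from[s2]
      from[s1] <- a; to[s1] <- b
      len[s1] <- len[s1] + len[s2] - 1    # shared node pixel counted once
      orig_group[[s1]] <- c(orig_group[[s1]], orig_group[[s2]])
      alive[s2] <- FALSE
      removed <- c(removed, v)
      progressed <- TRUE
      break
    }
    if (!progressed) break
  }
  new_idx <- which(alive)
  label_map <- integer(ns)
  for (j in seq_along(new_idx))
    label_map[orig_group[[new_idx[j]]]] <- j
  list(from = from[new_idx], to = to[new_idx], len = len[new_idx],
       label_map = label_map, removed = removed)
}

neighbours_of <- function(sk, r, c) {
  out <- matrix(integer(), 0, 2)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && cc >= 1 && rr <= nrow(sk) && cc <= ncol(sk) &&
        sk[rr, cc] == 1L)
      out <- rbind(out, c(rr, cc))
  }
  out
}

#' Extract the vessel graph from a skeleton
#'
#' Junction pixels (>= 3 set 8-neighbours) are clustered (adjacent junction
#' pixels merge into a single bifurcation node at their centroid), tip
#' pixels (1 neighbour) become endpoints, and segments are traced along the
#' degree-2 chains between nodes. Segment length `L` is the number of
#' skeleton pixels spanned by the link (chain pixels plus one pixel at each
#' node). Short spurs attached to junctions are pruned first. Self-loops and
#' parallel links are retained; an isolated cycle with no junction or tip
#' gets a single node and a self-loop. A skeleton containing set pixels but
#' no node anywhere is a pure cycle and raises an error.
#'
#' @param skeleton a [skeletonize()] result.
#' @param mask optional raw mask; when supplied, [estimate_widths()] is
#'   applied before returning.
#' @param min_spur prune tip branches shorter than this many pixels when
#'   they end at a junction.
#' @param junction_merge consolidate junction nodes joined by links shorter
#'   than this many pixels (thinning can split one wide Y-junction into
#'   several nearby 3-junctions); 0 disables.
#' @return an object of class `vessel_graph`: list with tibbles `nodes`
#'   (`id`, `row`, `col`, `kind`, `degree`) and `segments` (`id`, `from`,
#'   `to`, `length`, `n_pixels`, `width`, `weight`), `central_id`, and the
#'   segment-labelled skeleton (`px_label`).
#' @export
extract_graph <- function(skeleton, mask = NULL, min_spur = 3, junction_merge = 6) {
  sk <- unclass(skeleton)
  storage.mode(sk) <- "integer"
  if (sum(sk) == 0) abort("empty skeleton")
  sk <- prune_spurs(sk, min_spur)
  nb <- neighbour_counts(sk)

  junction <- matrix(as.integer(sk == 1L & nb >= 3L), nrow(sk), ncol(sk))
  jlab <- cc_label_cpp(junction)
  n_junctions <- max(jlab)
  tips <- which(sk == 1L & nb <= 1L)   # tips and isolated pixels

  # pure-cycle components: pick their first pixel as a node
  comp <- cc_label_cpp(sk)
  comp_has_node <- rep(FALSE, max(comp))
  if (n_junctions > 0) comp_has_node[unique(comp[jlab > 0])] <- TRUE
  if (length(tips)) comp_has_node[unique(comp[tips])] <- TRUE
  cycle_nodes <- integer(0)
  if (any(!comp_has_node)) {
    if (!any(comp_has_node))
      abort("skeleton is a pure cycle: no junctions or endpoints")
    for (ci in which(!comp_has_node)) cycle_nodes <- c(cycle_nodes,
                                                       which(comp == ci)[1])
    warn(sprintf("%d isolated cycle(s): one node each was created",
                 length(cycle_nodes)))
  }

  # node-id raster: junction clusters first, then tips, then cycle nodes
  nid <- matrix(0L, nrow(sk), ncol(sk))
  nid[jlab > 0] <- jlab[jlab > 0]
  next_id <- n_junctions
  for (t in tips) { next_id <- next_id + 1L; nid[t] <- next_id }
  for (t in cycle_nodes) { next_id <- next_id + 1L; nid[t] <- next_id }
  n_nodes <- next_id

  # node positions (cluster centroids) and structural kinds
  rows <- rep(0, n_nodes); cols <- rep(0, n_nodes); npix <- rep(0L, n_nodes)
  idx <- which(nid > 0)
  for (i in idx) {
    id <- nid[i]
    rows[id] <- rows[id] + (i - 1) %% nrow(sk) + 1
    cols[id] <- cols[id] + (i - 1) %/% nrow(sk) + 1
    npix[id] <- npix[id] + 1L
  }
  rows <- rows / npix; cols <- cols / npix

  # trace segments between node pixels along degree-2 chains
  visited <- matrix(FALSE, nrow(sk), ncol(sk))
  seg_from <- integer(); seg_to <- integer(); seg_len <- integer()
  px_label <- matrix(0L, nrow(sk), ncol(sk))
  node_px_seg <- integer(n_nodes)  # lowest incident segment per node (0 = none)
  direct_seen <- character(0)

  claim_node_pixels <- function(node_id, seg_id) {
    if (node_px_seg[node_id] == 0L) node_px_seg[node_id] <<- seg_id
  }

  node_pixels <- which(nid > 0)
  for (p in node_pixels) {
    pr <- (p - 1) %% nrow(sk) + 1
    pc <- (p - 1) %/% nrow(sk) + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      qr <- pr + dr; qc <- pc + dc
      if (qr < 1 || qc < 1 || qr > nrow(sk) || qc > ncol(sk)) next
      if (sk[qr, qc] != 1L) next
      if (nid[qr, qc] > 0L) {
        # direct node-node adjacency (possibly different clusters)
        a <- nid[pr, pc]; b <- nid[qr, qc]
        if (a == b) next
        # one direct link per node pair: clusters touching along several
        # pixel pairs are still a single adjacency
        key <- paste(min(a, b), max(a, b))
        if (key %in% direct_seen) next
        direct_seen <- c(direct_seen, key)
        sid <- length(seg_from) + 1L
        seg_from <- c(seg_from, min(a, b)); seg_to <- c(seg_to, max(a, b))
        seg_len <- c(seg_len, 2L)
        claim_node_pixels(a, sid); claim_node_pixels(b, sid)
      } else if (!visited[qr, qc]) {
        # walk the chain
        path_r <- qr; path_c <- qc
        visited[qr, qc] <- TRUE
        prev_r <- pr; prev_c <- pc
        cur_r <- qr; cur_c <- qc
        end_node <- 0L
        repeat {
          found <- FALSE
          for (er in -1:1) {
            for (ec in -1:1) {
              if (er == 0 && ec == 0) next
              nr2 <- cur_r + er; nc2 <- cur_c + ec
              if (nr2 < 1 || nc2 < 1 || nr2 > nrow(sk) || nc2 > ncol(sk)) next
              if (sk[nr2, nc2] != 1L) next
              if (nr2 == prev_r && nc2 == prev_c) next
              if (nid[nr2, nc2] > 0L) {
                end_node <- nid[nr2, nc2]; found <- TRUE
              } else if (!visited[nr2, nc2]) {
                prev_r <- cur_r; prev_c <- cur_c
                cur_r <- nr2; cur_c <- nc2
                visited[nr2, nc2] <- TRUE
                path_r <- c(path_r, nr2); path_c <- c(path_c, nc2)
                found <- TRUE
              } else next
              break
            }
            if (found) break
          }
          if (!found || end_node > 0L) break
        }
        if (end_node == 0L) {
          # dangling chain re-entering visited territory (tiny loop); close
          # it as a self-loop on the starting node
          end_node <- nid[pr, pc]
        }
        a <- nid[pr, pc]
        # a 1-2 pixel chain wedged inside one junction cluster is a thinning
        # artifact, not a self-loop
        if (end_node == a && length(path_r) < 3) next
        sid <- length(seg_from) + 1L
        seg_from <- c(seg_from, a); seg_to <- c(seg_to, end_node)
        seg_len <- c(seg_len, length(path_r) + 2L)
        px_label[cbind(path_r, path_c)] <- sid
        claim_node_pixels(a, sid); claim_node_pixels(end_node, sid)
      }
    }
  }

  # label node pixels with an incident segment so every skeleton pixel
  # carries a segment id for raw-pixel assignment
  for (p in node_pixels) {
    sid <- node_px_seg[nid[p]]
    if (sid > 0L) px_label[p] <- sid
  }

  # (a) consolidate junctions: thinning a wide Y-junction can leave two or
  # three 3-junctions a few pixels apart joined by stub links or tiny
  # loops; merge junction nodes joined by links shorter than
  # `junction_merge` and drop the short self-loops this exposes
  ns <- length(seg_from)
  seg_len <- as.numeric(seg_len)
  seg_alive <- rep(TRUE, ns)
  redirect <- seq_len(ns)
  removed_nodes <- integer(0)
  repeat {
    idx <- which(seg_alive)
    deg <- tabulate(c(seg_from[idx], seg_to[idx]), nbins = n_nodes)
    noloop <- seg_from[idx] != seg_to[idx]
    cand <- idx[noloop & seg_len[idx] <= junction_merge &
                deg[seg_from[idx]] >= 3 & deg[seg_to[idx]] >= 3]
    if (length(cand)) {
      s <- cand[1]; a <- seg_from[s]; b <- seg_to[s]
      wsum <- npix[a] + npix[b]
      rows[a] <- (rows[a] * npix[a] + rows[b] * npix[b]) / wsum
      cols[a] <- (cols[a] * npix[a] + cols[b] * npix[b]) / wsum
      npix[a] <- wsum
      seg_alive[s] <- FALSE
      seg_from[seg_from == b] <- a
      seg_to[seg_to == b] <- a
      inc <- which(seg_alive & (seg_from == a | seg_to == a))
      redirect[s] <- if (length(inc)) inc[1] else 0L
      removed_nodes <- c(removed_nodes, b)
      next
    }
    loops <- idx[!noloop & seg_len[idx] <= junction_merge + 2]
    loops <- loops[deg[seg_from[loops]] > 2]   # keep isolated-cycle loops
    if (!length(loops)) break
    s <- loops[1]; a <- seg_from[s]
    seg_alive[s] <- FALSE
    inc <- which(seg_alive & (seg_from == a | seg_to == a))
    redirect[s] <- if (length(inc)) inc[1] else 0L
  }

  # (b) contract degree-2 nodes (junction-cluster artifacts on thick or
  # diagonal paths): their two segments merge into one, lengths adding (the
  # shared node pixel counted once)
  alive_idx <- which(seg_alive)
  ct <- contract_degree2(seg_from[alive_idx], seg_to[alive_idx],
                         seg_len[alive_idx], n_nodes)
  label_map <- integer(ns)
  for (s in seq_len(ns)) {
    cur <- s
    while (cur != 0L && !seg_alive[cur]) cur <- redirect[cur]
    label_map[s] <- if (cur == 0L) 0L
                    else ct$label_map[match(cur, alive_idx)]
  }
  px_label[px_label > 0] <- label_map[px_label[px_label > 0]]
  seg_from <- ct$from; seg_to <- ct$to; seg_len <- ct$len
  removed_nodes <- c(removed_nodes, ct$removed)
  keep_nodes <- setdiff(seq_len(n_nodes), removed_nodes)
  node_remap <- match(seq_len(n_nodes), keep_nodes)
  seg_from <- node_remap[seg_from]; seg_to <- node_remap[seg_to]
  rows <- rows[keep_nodes]; cols <- cols[keep_nodes]
  n_nodes <- length(keep_nodes)

  deg <- tabulate(c(seg_from, seg_to), nbins = n_nodes)
  kind <- ifelse(deg == 1, "endpoint",
                 ifelse(deg >= 3, "bifurcation", "through"))
  g <- structure(
    list(nodes = tibble::tibble(id = seq_len(n_nodes), row = rows, col = cols,
                                kind = kind, degree = deg),
         segments = tibble::tibble(id = seq_along(seg_from), from = seg_from,
                                   to = seg_to, length = as.numeric(seg_len),
                                   n_pixels = NA_real_, width = NA_real_,
                                   weight = NA_real_),
         central_id = NA_integer_, px_label = px_label,
         dim = dim(sk)),
    class = "vessel_graph")
  if (!is.null(mask)) g <- estimate_widths(g, mask)
  g
}

#' Estimate segment widths from the raw mask
#'
#' Every raw-mask pixel is assigned to its nearest segment-labelled skeleton
#' pixel (multi-source breadth-first propagation), giving the pixel count
#' `N` of each link; the width follows from `N = L x W` as `W = N / L`,
#' floored at 1 pixel.
#'
#' @param graph a `vessel_graph` (with its `px_label` raster).
#' @param mask the raw `vessel_mask` the skeleton was derived from.
#' @return the graph with `n_pixels` and `width` populated.
#' @export
estimate_widths <- function(graph, mask) {
  m <- unclass(mask); storage.mode(m) <- "integer"
  stopifnot(all(dim(m) == graph$dim))
  lab <- propagate_labels_cpp(graph$px_label, m)
  n_seg <- nrow(graph$segments)
  n_px <- tabulate(lab[lab > 0], nbins = n_seg)
  if (any(n_px == 0))
    warn(sprintf("%d segment(s) received no raw pixels; width floored to 1",
                 sum(n_px == 0)))
  graph$segments$n_pixels <- as.numeric(n_px)
  graph$segments$width <- pmax(1, n_px / graph$segments$length)
  graph
}

#' Mark the central node at the optic disc
#'
#' The node nearest the disc centre becomes the central node (the optic
#' nerve head, where all transported blood enters and leaves the network);
#' ties break to the lowest node id. If the nearest node lies farther than
#' 3 disc radii a `fundusgraph_central_failure` error is signalled.
#'
#' @param graph a `vessel_graph`.
#' @param disc an `optic_disc` (or list with `center` and `radius`).
#' @return the graph with `central_id` set and the node's kind relabelled
#'   `"central"`.
#' @export
assign_central_node <- function(graph, disc) {
  if (nrow(graph$nodes) == 0) abort("empty graph")
  d <- sqrt((graph$nodes$row - disc$center[1])^2 +
            (graph$nodes$col - disc$center[2])^2)
  ord <- order(d, graph$nodes$id)
  best <- ord[1]
  if (d[best] > 3 * disc$radius)
    stop_fundus("fundusgraph_central_failure",
                sprintf("nearest node is %.1f px from the disc (> 3 radii)",
                        d[best]))
  graph$central_id <- graph$nodes$id[best]
  graph$nodes$kind[best] <- "central"
  graph
}

#' Apply link weights
#'
#' Sets every segment weight to `w = L^l * W^a`; the exponents select the
#' physical cost carried by a link (`l = 0, a = 1`: vessel width; `l = 1,
#' a = 2`: vessel volume; `l = 1, a = -2`: flow resistance). Weights are
#' strictly positive because `L, W >= 1`.
#'
#' @param graph a `vessel_graph` with lengths and widths populated.
#' @param l exponent on segment length.
#' @param a exponent on segment width.
#' @return the graph with `weight` populated and a `weight_config`
#'   attribute.
#' @export
apply_weights <- function(graph, l, a) {
  stopifnot(is.finite(l), is.finite(a))
  if (anyNA(graph$segments$width))
    abort("widths not estimated; call estimate_widths() first")
  graph$segments$weight <- graph$segments$length^l * graph$segments$width^a
  attr(graph, "weight_config") <- c(l = l, a = a)
  graph
}

# igraph view of a vessel graph (keeps self-loops and parallel links)
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$segments[, c("from", "to", "length", "width", "weight")],
    directed = FALSE,
    vertices = graph$nodes[, c("id", "row", "col", "kind")])
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes, %d segments%s\n",
              nrow(x$nodes), nrow(x$segments),
              if (!is.na(x$central_id))
                sprintf(", central node %d", x$central_id) else ""))
  invisible(x)
}

#' Serialize a vessel graph
#'
#' Writes the node and segment tables as CSV and, optionally, the graph in
#' GraphML via igraph.
#'
#' @param graph a `vessel_graph`.
#' @param dir output directory.
#' @param name base name for the files.
#' @param graphml also write `<name>.graphml`.
#' @return invisibly, the written paths.
#' @export
write_graph_csv <- function(graph, dir, name = "graph", graphml = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  np <- file.path(dir, paste0(name, "_nodes.csv"))
  sp <- file.path(dir, paste0(name, "_segments.csv"))
  utils::write.csv(graph$nodes, np, row.names = FALSE)
  utils::write.csv(graph$segments, sp, row.names = FALSE)
  paths <- list(nodes = np, segments = sp)
  if (graphml) {
    gp <- file.path(dir, paste0(name, ".graphml"))
    igraph::write_graph(as_igraph(graph), gp, format = "graphml")
    paths$graphml <- gp
  }
  invisible(paths)
}
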