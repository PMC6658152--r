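#' Weighted distances to the central node
#'
#' Exact single-source weighted shortest paths from every node to the
#' central one (Dijkstra via igraph), together with the hop count (number of
#' links) of each shortest path. Nodes in components that do not contain the
#' central node are flagged unreachable.
#'
#' @param graph a weighted `vessel_graph` with the central node assigned.
#' @return tibble of class `distance_profile`: `node_id`, `distance`,
#'   `hops`, `reachable` (the central node itself is excluded).
#' @export
central_distances <- function(graph) {
  if (is.na(graph$central_id)) abort("no central node assigned")
  if (anyNA(graph$segments$weight)) abort("weights not applied")
  ig <- as_igraph(graph)
  central <- which(igraph::V(ig)$name == as.character(graph$central_id))
  d <- as.numeric(igraph::distances(ig, v = central,
                                    weights = igraph::E(ig)$weight))
  sp <- suppressWarnings(
    igraph::shortest_paths(ig, from = central, to = igraph::V(ig),
                           weights = igraph::E(ig)$weight, output = "epath"))
  hops <- lengths(sp$epath)
  ids <- as.integer(igraph::V(ig)$name)
  keep <- ids != graph$central_id
  structure(
    tibble::tibble(node_id = ids[keep], distance = d[keep],
                   hops = hops[keep], reachable = is.finite(d[keep])),
    class = c("distance_profile", class(tibble::tibble())),
    weight_config = attr(graph, "weight_config"))
}

new_feature_samples <- function(values, method, config) {
  l <- if (is.null(config)) NA_real_ else unname(config["l"])
  a <- if (is.null(config)) NA_real_ else unname(config["a"])
  structure(
    tibble::tibble(method = method, l = l, a = a, value = values),
    class = c("feature_samples", class(tibble::tibble())))
}

#' Central node-distance samples (C-NDD)
#'
#' One sample per reachable non-central node: its weighted shortest-path
#' distance to the central node. The normalized histogram of these samples
#' is the C-NDD of the image.
#'
#' @param profile a [central_distances()] result.
#' @return a `feature_samples` tibble (`method`, `l`, `a`, `value`).
#' @export
cndd_samples <- function(profile) {
  v <- profile$distance[profile$reachable]
  if (!length(v)) abort("no node is reachable from the central node")
  new_feature_samples(v, "cndd", attr(profile, "weight_config"))
}

#' Central mean-weight samples (CMWD)
#'
#' One sample per reachable non-central node: the mean link weight along its
#' shortest path to the central node (path distance divided by hop count).
#'
#' @inheritParams cndd_samples
#' @return a `feature_samples` tibble.
#' @export
cmwd_samples <- function(profile) {
  keep <- profile$reachable
  if (!any(keep)) abort("no node is reachable from the central node")
  v <- profile$distance[keep] / profile$hops[keep]
  new_feature_samples(v, "cmwd", attr(profile, "weight_config"))
}

#' Weighted-degree (strength) samples (WDD)
#'
#' One sample per node: its strength, the sum of the weights of its incident
#' links (self-loops count twice). The canonical configuration `l = 0,
#' a = 1` makes the weight of each link the width of the vessel.
#'
#' @param graph a weighted `vessel_graph`.
#' @return a `feature_samples` tibble.
#' @export
wdd_samples <- function(graph) {
  if (nrow(graph$nodes) == 0) abort("empty graph")
  if (anyNA(graph$segments$weight)) abort("weights not applied")
  ig <- as_igraph(graph)
  s <- igraph::strength(ig, weights = igraph::E(ig)$weight, loops = TRUE)
  new_feature_samples(as.numeric(s), "wdd", attr(graph, "weight_config"))
}

#' Basic network counts
#'
#' Number of nodes, links, endpoints (nodes with exactly one neighbour) and
#' bifurcation points (nodes with 3 or more neighbours), by degree.
#'
#' @param graph a `vessel_graph`.
#' @return one-row tibble: `nodes`, `links`, `endpoints`, `bifurcations`.
#' @export
basic_counts <- function(graph) {
  deg <- tabulate(c(graph$segments$from, graph$segments$to),
                  nbins = nrow(graph$nodes))
  tibble::tibble(nodes = nrow(graph$nodes),
                 links = nrow(graph$segments),
                 endpoints = sum(deg == 1),
                 bifurcations = sum(deg >= 3))
}
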