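#' Shared histogram bin edges across a cohort
#'
#' Pairwise Jensen–Shannon divergences require every image's distribution
#' on one common support: the edges span the pooled 0.5th–99.5th percentile
#' of all sample sets, divided into `n_bins` uniform bins.
#'
#' @param sample_sets list of numeric vectors (or `feature_samples`
#'   tibbles), one per image.
#' @param n_bins number of uniform bins.
#' @return numeric vector of `n_bins + 1` edges.
#' @export
common_bin_edges <- function(sample_sets, n_bins = 64) {
  pooled <- unlist(lapply(sample_sets, function(s) {
    if (is.data.frame(s)) s$value else s
  }))
  if (!length(pooled)) abort("no samples supplied")
  qs <- quantile(pooled, c(0.005, 0.995), names = FALSE)
  if (diff(qs) == 0) abort("pooled samples have zero range")
  seq(qs[1], qs[2], length.out = n_bins + 1)
}

#' Normalized histogram on given edges
#'
#' Values outside the edge range are clipped into the end bins, so every
#' sample contributes; the result sums to 1.
#'
#' @param samples numeric vector (or a `feature_samples` tibble).
#' @param edges bin edges from [common_bin_edges()].
#' @return numeric probability vector of length `length(edges) - 1`.
#' @export
to_histogram <- function(samples, edges) {
  v <- if (is.data.frame(samples)) samples$value else samples
  if (!length(v)) abort("empty sample set")
  v <- pmin(pmax(v, edges[1]), edges[length(edges)])
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(edges) - 1L)
  h <- tabulate(idx, nbins = length(edges) - 1L)
  h / sum(h)
}

#' Histogram set for a cohort
#'
#' Builds the shared edges and the per-image normalized histograms in one
#' step.
#'
#' @inheritParams common_bin_edges
#' @return list of class `histogram_set`: `edges` and `probs` (images x
#'   bins matrix).
#' @export
histogram_set <- function(sample_sets, n_bins = 64) {
  edges <- common_bin_edges(sample_sets, n_bins)
  probs <- t(vapply(sample_sets, to_histogram, numeric(n_bins),
                    edges = edges))
  structure(list(edges = edges, probs = probs), class = "histogram_set")
}

#' Jensen–Shannon divergence
#'
#' `JSD(P, Q) = H((P+Q)/2) - (H(P) + H(Q))/2` with Shannon entropy `H` in
#' natural logarithms, so the value lies in `[0, ln 2]`; zero-probability
#' bins contribute zero. Symmetric, and zero iff `P = Q`.
#'
#' @param p,q probability vectors of equal length (each summing to 1 within
#'   `tol`).
#' @param tol tolerance on the probability sums.
#' @return a scalar divergence in nats.
#' @export
js_divergence <- function(p, q, tol = 1e-6) {
  if (length(p) != length(q)) abort("P and Q must have equal length")
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol)
    abort("P and Q must each sum to 1")
  ent <- function(x) {
    x <- x[x > 0]
    -sum(x * log(x))
  }
  max(0, ent((p + q) / 2) - (ent(p) + ent(q)) / 2)
}

#' Pairwise Jensen–Shannon divergence matrix
#'
#' Symmetric N x N matrix with zero diagonal whose entries are the JS
#' divergences between the per-image histograms; this matrix is the input
#' of the IsoMap embedding.
#'
#' @param histograms a [histogram_set()] (or a plain probability matrix,
#'   images in rows).
#' @return numeric matrix of class `divergence_matrix`.
#' @export
divergence_matrix <- function(histograms) {
  probs <- if (inherits(histograms, "histogram_set")) histograms$probs
           else as.matrix(histograms)
  n <- nrow(probs)
  if (n < 3) abort("need at least 3 images")
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- js_divergence(probs[i, ], probs[j, ])
    }
  }
  rownames(m) <- colnames(m) <- rownames(probs)
  structure(m, class = c("divergence_matrix", "matrix"))
}

#' IsoMap embedding into two features
#'
#' Classic IsoMap on a precomputed distance matrix: a k-nearest-neighbour
#' graph is built from the distances (k is increased automatically, with a
#' message, until the graph is connected), geodesic distances are computed
#' over that graph, and classical multidimensional scaling maps each image
#' to two coordinates. With `k = N - 1` the neighbourhood graph is complete
#' and the embedding reduces exactly to classical MDS. Deterministic: signs
#' are fixed so each coordinate's largest-magnitude entry is positive.
#'
#' @param dist_matrix symmetric distance matrix (e.g. a
#'   [divergence_matrix()]).
#' @param k number of nearest neighbours.
#' @return tibble of class `embedding2d`: `image`, `iso1`, `iso2`; the k
#'   actually used is in the `k_used` attribute.
#' @export
isomap_2d <- function(dist_matrix, k = 10) {
  d <- unclass(dist_matrix)
  n <- nrow(d)
  if (n < 3) abort("need at least 3 images to embed")
  k <- min(max(2L, as.integer(k)), n - 1L)
  repeat {
    g <- knn_graph(d, k)
    if (igraph::is_connected(g)) break
    if (k >= n - 1) abort("neighbourhood graph cannot be connected")
    k <- k + 1L
    rlang::inform(sprintf("neighbourhood graph disconnected; k increased to %d", k))
  }
  geo <- igraph::distances(g, weights = igraph::E(g)$weight)
  xy <- suppressWarnings(cmdscale(geo, k = 2))
  if (ncol(xy) < 2) xy <- cbind(xy, 0)[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i_max <- which.max(abs(xy[, j]))
    if (xy[i_max, j] < 0) xy[, j] <- -xy[, j]
  }
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(tibble::tibble(image = ids, iso1 = xy[, 1], iso2 = xy[, 2]),
            class = c("embedding2d", class(tibble::tibble())),
            k_used = k)
}

knn_graph <- function(d, k) {
  n <- nrow(d)
  edges <- integer(0)
  weights <- numeric(0)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- setdiff(ord, i)[seq_len(k)]
    edges <- c(edges, rbind(i, ord))
    weights <- c(weights, d[i, ord])
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::E(g)$weight <- weights
  igraph::simplify(g, edge.attr.comb = list(weight = "first"))
}

#' Two-sample t-test with pooled variance
#'
#' Equal-variance two-sample t-test of the null hypothesis that the two
#' samples come from distributions with equal means (two-sided). Degenerate
#' inputs with zero pooled variance give `p = 1` when the means are equal
#' and `p = 0` (flagged) when they differ.
#'
#' @param sample_a,sample_b numeric vectors with >= 2 values each.
#' @return object of class `group_test`: `statistic`, `df`, `p_value`,
#'   `method`, `degenerate` flag.
#' @export
ttest2 <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  tt <- tryCatch(stats::t.test(sample_a, sample_b, var.equal = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) {   # zero (or numerically zero) pooled variance
    equal <- isTRUE(all.equal(mean(sample_a), mean(sample_b)))
    return(new_group_test(if (equal) 0 else Inf,
                          length(sample_a) + length(sample_b) - 2,
                          if (equal) 1 else 0, "ttest2", degenerate = TRUE))
  }
  new_group_test(unname(tt$statistic), unname(tt$parameter),
                 tt$p.value, "ttest2")
}

new_group_test <- function(stat, df, p, method, degenerate = FALSE,
                           extra = list()) {
  structure(c(list(statistic = stat, df = df, p_value = p, method = method,
                   degenerate = degenerate), extra),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s: t = %.4g, df = %.3g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
glance.group_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic, df = x$df,
                 p_value = x$p_value, degenerate = x$degenerate)
}

#' Group separation in a 2-D feature plane
#'
#' Projects the per-image features onto their Fisher discriminant direction
#' (the best direction of the plane) and tests the projections with the
#' pooled-variance two-sample t-test. Because the direction is chosen to
#' maximize the separation of the same samples that are then tested, the
#' naive projected t-test is optimistically biased; by default the p-value
#' is therefore computed from the exact null distribution of the maximized
#' statistic (Hotelling's T-squared, an F transform), which is calibrated:
#' under identical groups the p-value is uniform. `p_correction = "none"`
#' gives the naive projected t-test instead, and
#' `method = "first_coordinate"` tests the first feature coordinate alone.
#'
#' @param features an `embedding2d`, a matrix/data frame of 2 columns, or a
#'   single-column matrix (then a plain t-test is performed).
#' @param labels two-group labels, one per row of `features`.
#' @param method `"fisher"` (projection on the best direction) or
#'   `"first_coordinate"`.
#' @param p_correction `"selection"` (default; Hotelling's T-squared F
#'   transform accounting for direction selection) or `"none"`.
#' @return a `group_test` with the projection direction attached.
#' @export
group_separation <- function(features, labels,
                             method = c("fisher", "first_coordinate"),
                             p_correction = c("selection", "none")) {
  method <- match.arg(method)
  p_correction <- match.arg(p_correction)
  x <- if (inherits(features, "embedding2d"))
    as.matrix(features[, c("iso1", "iso2")])
  else as.matrix(features)
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2 || min(table(labels)) < 2)
    abort("need two groups with >= 2 members each")

  if (method == "first_coordinate" || ncol(x) == 1) {
    tt <- ttest2(x[labels == groups[1], 1], x[labels == groups[2], 1])
    tt$method <- "first_coordinate"
    return(tt)
  }
  bd <- best_direction(x, labels)
  proj <- bd$projections
  tt <- ttest2(proj[labels == groups[1]], proj[labels == groups[2]])
  n <- length(labels)
  p_dim <- ncol(x)
  if (p_correction == "selection" && !bd$fallback && !tt$degenerate &&
      n - 1 - p_dim > 0) {
    t2 <- tt$statistic^2
    fstat <- t2 * (n - 1 - p_dim) / ((n - 2) * p_dim)
    p <- pf(fstat, p_dim, n - 1 - p_dim, lower.tail = FALSE)
    return(new_group_test(tt$statistic, tt$df, p, "fisher_projection",
                          extra = list(direction = bd$direction,
                                       p_correction = "selection")))
  }
  new_group_test(tt$statistic, tt$df, tt$p_value, "fisher_projection",
                 degenerate = tt$degenerate,
                 extra = list(direction = bd$direction,
                              p_correction = "none"))
}
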