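#' Box counting of a binary mask
#'
#' Covers the image with a grid of boxes of size `eps` anchored at the
#' origin and counts the boxes containing at least one set pixel, for each
#' scale. The default scales are the dyadic sequence 2, 4, 8, ... up to a
#' quarter of the smaller image side.
#'
#' @param mask binary matrix.
#' @param scales integer vector of box sizes; default dyadic.
#' @return tibble of class `boxcount_table` with columns `eps`, `n_boxes`.
#' @export
box_count <- function(mask, scales = NULL) {
  m <- unclass(mask)
  if (sum(m != 0) == 0) abort("empty mask: box counting undefined")
  if (is.null(scales)) scales <- default_scales(dim(m))
  scales <- sort(unique(as.integer(scales)))
  n <- vapply(scales, function(eps) {
    nr <- ceiling(nrow(m) / eps) * eps
    nc <- ceiling(ncol(m) / eps) * eps
    p <- matrix(0L, nr, nc)
    p[seq_len(nrow(m)), seq_len(ncol(m))] <- (m != 0) + 0L
    rg <- rep(seq_len(nr / eps), each = eps)
    cg <- rep(seq_len(nc / eps), each = eps)
    byrow <- rowsum(p, rg)                      # (nr/eps) x nc
    bycol <- rowsum(t(byrow), cg)               # (nc/eps) x (nr/eps)
    sum(bycol > 0)
  }, numeric(1))
  structure(tibble::tibble(eps = scales, n_boxes = n),
            class = c("boxcount_table", class(tibble::tibble())),
            mask_dim = dim(m))
}

default_scales <- function(dims) {
  top <- min(dims) / 4
  s <- 2^(1:30)
  s[s <= top]
}

#' Fit the box-counting dimension
#'
#' Least-squares slope of `log N(eps)` against `log(1/eps)`: the scaling
#' exponent `D` in `N(eps) ~ eps^-D`. If the residual at the single largest
#' scale exceeds 3x the median absolute residual (grid saturation), that
#' scale is dropped from the fit and flagged.
#'
#' @param table a [box_count()] result with at least 4 scales.
#' @return object of class `fractal_fit`: `dimension`, `r_squared`,
#'   `eps_range`, `n_scales`, `excluded_scales`, `table`.
#' @export
fit_dimension <- function(table) {
  if (nrow(table) < 4) abort("need at least 4 scales to fit a dimension")
  if (length(unique(table$n_boxes)) == 1) {
    warn("degenerate box-count table (all counts equal): D = 0")
    return(new_fractal_fit(0, 1, range(table$eps), nrow(table), integer(0),
                           table))
  }
  x <- log(1 / table$eps)
  y <- log(table$n_boxes)
  fit <- lm(y ~ x)
  res <- abs(stats::residuals(fit))
  excluded <- integer(0)
  i_big <- which.max(table$eps)
  if (nrow(table) > 4 && res[i_big] > 3 * stats::median(res)) {
    excluded <- table$eps[i_big]
    fit <- lm(y[-i_big] ~ x[-i_big])
  }
  d <- unname(coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  kept <- setdiff(table$eps, excluded)
  new_fractal_fit(d, r2, range(kept), length(kept), excluded, table)
}

new_fractal_fit <- function(d, r2, eps_range, n_scales, excluded, table) {
  structure(list(dimension = d, r_squared = r2, eps_range = eps_range,
                 n_scales = n_scales, excluded_scales = excluded,
                 table = table),
            class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("<fractal_fit> D = %.4f (R^2 = %.4f, eps %d..%d over %d scales%s)\n",
              x$dimension, x$r_squared, x$eps_range[1], x$eps_range[2],
              x$n_scales,
              if (length(x$excluded_scales))
                sprintf(", dropped eps=%s",
                        paste(x$excluded_scales, collapse = ",")) else ""))
  invisible(x)
}

#' @export
tidy.fractal_fit <- function(x, ...) {
  tibble::tibble(term = "dimension", estimate = x$dimension)
}

#' @export
glance.fractal_fit <- function(x, ...) {
  tibble::tibble(dimension = x$dimension, r_squared = x$r_squared,
                 eps_min = x$eps_range[1], eps_max = x$eps_range[2],
                 n_scales = x$n_scales,
                 n_excluded = length(x$excluded_scales))
}

#' Fractal-dimension pair of a mask
#'
#' Box-counting dimension of the raw mask and of its skeleton, computed
#' with identical scale settings; one image becomes one point in the
#' (D_skeleton, D_raw) plane.
#'
#' @param mask binary vessel mask.
#' @param scales optional scale vector passed to [box_count()].
#' @param skeleton optional precomputed [skeletonize()] result.
#' @return one-row tibble: `d_skeleton`, `d_raw`, `r2_skeleton`, `r2_raw`.
#' @export
fd_pair <- function(mask, scales = NULL, skeleton = NULL) {
  if (is.null(scales)) scales <- default_scales(dim(mask))
  if (is.null(skeleton)) skeleton <- skeletonize(mask)
  f_raw <- fit_dimension(box_count(mask, scales))
  f_skel <- fit_dimension(box_count(skeleton, scales))
  tibble::tibble(d_skeleton = f_skel$dimension, d_raw = f_raw$dimension,
                 r2_skeleton = f_skel$r_squared, r2_raw = f_raw$r_squared)
}

#' Fisher discriminant direction in a feature plane
#'
#' The direction that best separates two groups of 2-D points (Fisher
#' linear discriminant: pooled within-group covariance inverse applied to
#' the mean difference), with the per-point scalar projections used for
#' group testing. A singular pooled covariance falls back to the raw
#' mean-difference direction with a warning.
#'
#' @param points matrix or data frame with two numeric columns (e.g. the
#'   `(d_skeleton, d_raw)` fractal plane or an IsoMap plane).
#' @param labels group labels, exactly two distinct values, >= 2 points
#'   each.
#' @return object of class `fisher_direction`: unit `direction`,
#'   `projections`, `labels`, `fallback` flag.
#' @export
best_direction <- function(points, labels) {
  x <- as.matrix(points[, 1:2])
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2) abort("exactly two groups are required")
  if (min(table(labels)) < 2) abort("need >= 2 points per group")
  x0 <- x[labels == groups[1], , drop = FALSE]
  x1 <- x[labels == groups[2], , drop = FALSE]
  sw <- (crossprod(scale(x0, scale = FALSE)) +
         crossprod(scale(x1, scale = FALSE))) /
    (nrow(x0) + nrow(x1) - 2)
  dm <- colMeans(x1) - colMeans(x0)
  w <- tryCatch(solve(sw, dm), error = function(e) NULL)
  fallback <- FALSE
  if (is.null(w) || !all(is.finite(w))) {
    warn("singular pooled covariance: using mean-difference direction")
    w <- dm
    fallback <- TRUE
  }
  nw <- sqrt(sum(w^2))
  if (nw == 0) w <- c(1, 0) else w <- w / nw
  # sign convention: largest-magnitude component positive
  if (w[which.max(abs(w))] < 0) w <- -w
  structure(list(direction = w, projections = as.numeric(x %*% w),
                 labels = labels, groups = groups, fallback = fallback),
            class = "fisher_direction")
}
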