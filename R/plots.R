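#' @export
autoplot.boxcount_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = log(1 / .data$eps),
                                       y = log(.data$n_boxes))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = expression(log(1 / epsilon)),
                  y = expression(log(N(epsilon))),
                  title = "Box-counting scaling")
}

#' @export
autoplot.fractal_fit <- function(object, ...) {
  autoplot(object$table) +
    ggplot2::labs(subtitle = sprintf("D = %.3f (R² = %.3f)",
                                     object$dimension, object$r_squared))
}

#' @export
autoplot.embedding2d <- function(object, labels = NULL, ...) {
  df <- object
  if (!is.null(labels)) df$label <- labels
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$iso1, y = .data$iso2))
  if (!is.null(labels)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = "IsoMap 1", y = "IsoMap 2",
                    title = "IsoMap embedding of JS divergences")
}

#' Fractal-dimension plane of a cohort
#'
#' One point per image in the (D_skeleton, D_raw) plane, coloured by group.
#'
#' @param fd tibble with `d_skeleton`, `d_raw` and optionally `label`
#'   (e.g. the `fd` element of a `cohort_report`).
#' @return a ggplot.
#' @export
plot_fd_plane <- function(fd) {
  p <- ggplot2::ggplot(fd, ggplot2::aes(x = .data$d_skeleton,
                                        y = .data$d_raw))
  if ("label" %in% names(fd))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 2)
  else p <- p + ggplot2::geom_point(size = 2)
  p + ggplot2::labs(x = "D (skeletonized)", y = "D (raw mask)",
                    title = "Fractal dimension plane")
}

#' Per-image and mean histograms of a histogram set
#'
#' Semi-transparent per-image histograms with the group mean drawn solid,
#' one facet-free panel per group.
#'
#' @param hs a [histogram_set()].
#' @param labels optional group labels (one per image).
#' @return a ggplot.
#' @export
plot_histogram_set <- function(hs, labels = NULL) {
  mids <- hs$edges[-1] - diff(hs$edges) / 2
  n <- nrow(hs$probs)
  if (is.null(labels)) labels <- rep("all", n)
  df <- tibble::tibble(
    image = rep(seq_len(n), each = length(mids)),
    label = rep(labels, each = length(mids)),
    value = rep(mids, n),
    prob = as.numeric(t(hs$probs)))
  means <- dplyr::summarise(dplyr::group_by(df, .data$label, .data$value),
                            prob = mean(.data$prob), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$prob,
                                   colour = .data$label)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$image), alpha = 0.25,
                       linewidth = 0.3) +
    ggplot2::geom_line(data = means, linewidth = 1) +
    ggplot2::labs(x = "value", y = "probability",
                  title = "Per-image histograms and group means")
}
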