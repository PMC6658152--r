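#' Pipeline configuration
#'
#' Collects every tunable of the cohort pipeline. The default weight
#' configurations are the four canonical rows of the group reports:
#' C-NDD with `(l = 1, a = -2)` (flow resistance) and `(l = 1, a = 2)`
#' (vessel volume), CMWD with `(l = 1, a = -2)`, and WDD with
#' `(l = 0, a = 1)` (vessel width).
#'
#' @param weight_configs tibble with columns `method` (`cndd`, `cmwd`,
#'   `wdd`), `l`, `a`.
#' @param n_bins histogram bins shared across the cohort.
#' @param isomap_k IsoMap neighbourhood size.
#' @param min_spur spur-pruning threshold (pixels) in graph extraction.
#' @param fractal_scales optional box sizes for [box_count()].
#' @param segmentation list of [segment_vessels()] parameters.
#' @param p_correction passed to [group_separation()].
#' @param allow_mixed_resolution permit images of different sizes in one
#'   cohort (off by default: pixel-unit lengths and widths are not
#'   comparable across resolutions).
#' @param use_ground_truth_mask for synthetic images, use the generator
#'   mask and disc instead of running segmentation and disc detection.
#' @return a list of class `run_config`.
#' @export
run_config <- function(weight_configs = NULL,
                       n_bins = 64,
                       isomap_k = 10,
                       min_spur = 3,
                       fractal_scales = NULL,
                       segmentation = list(),
                       p_correction = "selection",
                       allow_mixed_resolution = FALSE,
                       use_ground_truth_mask = FALSE) {
  if (is.null(weight_configs)) {
    weight_configs <- tibble::tibble(
      method = c("cndd", "cndd", "cmwd", "wdd"),
      l = c(1, 1, 1, 0),
      a = c(-2, 2, -2, 1))
  }
  structure(list(weight_configs = weight_configs, n_bins = n_bins,
                 isomap_k = isomap_k, min_spur = min_spur,
                 fractal_scales = fractal_scales,
                 segmentation = segmentation, p_correction = p_correction,
                 allow_mixed_resolution = allow_mixed_resolution,
                 use_ground_truth_mask = use_ground_truth_mask),
            class = "run_config")
}

method_key <- function(method, l, a) sprintf("%s_l%g_a%g", method, l, a)

#' Process one image through the full pipeline
#'
#' Runs segmentation (or accepts a supplied mask), optic-disc location (or
#' supplied coordinates), skeletonization, graph extraction, width
#' estimation, central-node assignment, and computes the basic counts, the
#' fractal-dimension pair and the feature samples for every configured
#' `(method, l, a)`. Any stage failure is recorded in `status`
#' (`segmentation_failed`, `disc_not_found`, `central_failed`) and the
#' remaining stages are skipped; such images are later discarded from
#' cohort statistics.
#'
#' @param x a `synthetic_fundus`, a file path to an image, an RGB array or
#'   a `vessel_mask`.
#' @param config a [run_config()].
#' @param mask optional `vessel_mask` (bypasses segmentation).
#' @param disc optional `optic_disc` or `(row, col)` centre (bypasses
#'   detection).
#' @param label optional group label.
#' @return list of class `image_record`: `status`, `counts`, `fd`,
#'   `samples` (named list of `feature_samples`), `graph`, `label`.
#' @export
run_image <- function(x, config = run_config(), mask = NULL, disc = NULL,
                      label = NA_character_) {
  rec <- list(status = "ok", counts = NULL, fd = NULL, samples = list(),
              graph = NULL, label = label)
  image <- NULL
  if (inherits(x, "synthetic_fundus")) {
    image <- x$image
    if (is.na(rec$label)) rec$label <- x$group_label
    if (config$use_ground_truth_mask) {
      if (is.null(mask)) mask <- structure(x$mask, class = "vessel_mask",
                                           source = "ground_truth")
      if (is.null(disc)) disc <- structure(x$disc, class = "optic_disc")
    }
  } else if (is.character(x)) {
    image <- read_raster(x)
  } else if (inherits(x, "vessel_mask")) {
    mask <- x
  } else if (is.array(x) || is.matrix(x)) {
    image <- x
  }

  if (is.null(mask)) {
    mask <- tryCatch(segment_vessels(enhance_contrast(image),
                                     k = config$segmentation$k %||% 0.4),
                     fundusgraph_segmentation_failure = function(e) NULL)
    if (is.null(mask)) {
      rec$status <- "segmentation_failed"
      return(structure(rec, class = "image_record"))
    }
  }
  if (is.null(disc)) {
    disc <- tryCatch(locate_optic_disc(if (is.null(image)) mask else image,
                                       mask),
                     fundusgraph_disc_not_found = function(e) NULL)
    if (is.null(disc)) {
      rec$status <- "disc_not_found"
      return(structure(rec, class = "image_record"))
    }
  } else if (!inherits(disc, "optic_disc")) {
    disc <- locate_optic_disc(image, mask, center = disc)
  }

  skel <- skeletonize(mask)
  graph <- extract_graph(skel, mask = mask, min_spur = config$min_spur)
  graph <- tryCatch(assign_central_node(graph, disc),
                    fundusgraph_central_failure = function(e) NULL)
  if (is.null(graph)) {
    rec$status <- "central_failed"
    return(structure(rec, class = "image_record"))
  }

  rec$counts <- basic_counts(graph)
  rec$fd <- fd_pair(mask, scales = config$fractal_scales, skeleton = skel)
  for (i in seq_len(nrow(config$weight_configs))) {
    wc <- config$weight_configs[i, ]
    gw <- apply_weights(graph, wc$l, wc$a)
    samp <- switch(wc$method,
      cndd = cndd_samples(central_distances(gw)),
      cmwd = cmwd_samples(central_distances(gw)),
      wdd = wdd_samples(gw),
      abort(sprintf("unknown method '%s'", wc$method)))
    rec$samples[[method_key(wc$method, wc$l, wc$a)]] <- samp
  }
  rec$graph <- graph
  structure(rec, class = "image_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full cohort analysis
#'
#' Processes every image, discards failures (keeping the accounting:
#' usable + discarded = cohort size), builds shared-bin histograms, the
#' pairwise Jensen–Shannon divergence matrix and the 2-D IsoMap embedding
#' for each configured distribution method, and reports one group test per
#' method row: distribution methods are tested on the Fisher projection of
#' their IsoMap plane, the basic counts with a plain two-sample t-test, the
#' two fractal dimensions individually and jointly ("FD best direction").
#'
#' @param cohort a `synthetic_cohort`, a list of `synthetic_fundus`, or a
#'   manifest data frame with columns `path` (or `mask_path`) and `label`
#'   (optional `disc_row`, `disc_col`, `disc_radius`).
#' @param config a [run_config()].
#' @return object of class `cohort_report`: `report` (tibble: method, l, a,
#'   statistic, p_value), `images` (per-image status), `counts`, `fd`,
#'   `embeddings` (named list of `embedding2d`), `divergences` (named list
#'   of `divergence_matrix`), `n_usable`, `n_discarded`.
#' @export
run_cohort <- function(cohort, config = run_config()) {
  is_manifest <- is.data.frame(cohort)
  n <- if (is_manifest) nrow(cohort) else length(cohort)
  if (n == 0) abort("empty cohort")

  records <- vector("list", n)
  labels <- character(n)
  dims <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    if (is_manifest) {
      row <- cohort[i, ]
      mask <- if (!is.null(row$mask_path) && !is.na(row$mask_path))
        load_mask(row$mask_path) else NULL
      disc <- if (!is.null(row$disc_row) && !is.na(row$disc_row))
        structure(list(center = c(row$disc_row, row$disc_col),
                       radius = row$disc_radius %||% (min(dim(mask)) / 16)),
                  class = "optic_disc") else NULL
      x <- if (!is.null(row$path) && !is.na(row$path)) row$path else mask
      records[[i]] <- run_image(x, config, mask = mask, disc = disc,
                                label = row$label)
      if (!is.null(mask)) dims[i, ] <- dim(mask)
    } else {
      records[[i]] <- run_image(cohort[[i]], config)
      dims[i, ] <- dim(cohort[[i]]$mask)
    }
    labels[i] <- records[[i]]$label
  }
  ok_dims <- stats::complete.cases(dims)
  if (any(ok_dims) && nrow(unique(dims[ok_dims, , drop = FALSE])) > 1 &&
      !config$allow_mixed_resolution)
    abort(paste("cohort mixes image resolutions; pixel-unit features are",
                "not comparable (set allow_mixed_resolution to override)"))

  status <- vapply(records, function(r) r$status, "")
  usable <- which(status == "ok")
  images <- tibble::tibble(index = seq_len(n), label = labels,
                           status = status)
  if (length(usable) < 4)
    abort("fewer than 4 usable images; cannot embed")

  counts <- dplyr::bind_rows(lapply(records[usable], function(r) r$counts))
  counts$label <- labels[usable]
  fd <- dplyr::bind_rows(lapply(records[usable], function(r) r$fd))
  fd$label <- labels[usable]

  groups <- unique(labels[usable])
  test_groups <- length(groups) == 2 &&
    min(table(labels[usable])) >= 2

  report <- list()
  embeddings <- list()
  divergences <- list()
  for (i in seq_len(nrow(config$weight_configs))) {
    wc <- config$weight_configs[i, ]
    key <- method_key(wc$method, wc$l, wc$a)
    sets <- lapply(records[usable], function(r) r$samples[[key]])
    hs <- histogram_set(sets, config$n_bins)
    rownames(hs$probs) <- as.character(usable)
    dm <- divergence_matrix(hs)
    emb <- isomap_2d(dm, config$isomap_k)
    divergences[[key]] <- dm
    embeddings[[key]] <- emb
    if (test_groups) {
      gt <- group_separation(emb, labels[usable],
                             p_correction = config$p_correction)
      report[[length(report) + 1]] <- tibble::tibble(
        analysis = toupper(wc$method), l = wc$l, a = wc$a,
        statistic = gt$statistic, p_value = gt$p_value)
    }
  }

  if (test_groups) {
    for (cn in c("nodes", "links", "endpoints", "bifurcations")) {
      tt <- ttest2(counts[[cn]][counts$label == groups[1]],
                   counts[[cn]][counts$label == groups[2]])
      report[[length(report) + 1]] <- tibble::tibble(
        analysis = cn, l = NA_real_, a = NA_real_,
        statistic = tt$statistic, p_value = tt$p_value)
    }
    for (cn in c("d_skeleton", "d_raw")) {
      tt <- ttest2(fd[[cn]][fd$label == groups[1]],
                   fd[[cn]][fd$label == groups[2]])
      report[[length(report) + 1]] <- tibble::tibble(
        analysis = if (cn == "d_skeleton") "FD skeletonized" else "FD raw",
        l = NA_real_, a = NA_real_,
        statistic = tt$statistic, p_value = tt$p_value)
    }
    gt <- group_separation(as.matrix(fd[, c("d_skeleton", "d_raw")]),
                           fd$label, p_correction = config$p_correction)
    report[[length(report) + 1]] <- tibble::tibble(
      analysis = "FD best direction", l = NA_real_, a = NA_real_,
      statistic = gt$statistic, p_value = gt$p_value)
  } else if (length(usable)) {
    warn("group testing skipped: need two groups with >= 2 usable images each")
  }

  structure(list(report = dplyr::bind_rows(report), images = images,
                 counts = counts, fd = fd, embeddings = embeddings,
                 divergences = divergences,
                 n_usable = length(usable), n_discarded = n - length(usable)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d usable image(s), %d discarded\n",
              x$n_usable, x$n_discarded))
  if (nrow(x$report)) print(x$report)
  invisible(x)
}

#' @export
tidy.cohort_report <- function(x, ...) x$report

#' @export
glance.cohort_report <- function(x, ...) {
  tibble::tibble(n_usable = x$n_usable, n_discarded = x$n_discarded,
                 n_methods = nrow(x$report),
                 min_p = if (nrow(x$report)) min(x$report$p_value) else NA_real_)
}

#' Write all cohort outputs as CSV
#'
#' Emits `report.csv` (the group-test table), `counts.csv`, `fd.csv`,
#' `status.csv`, and per-method `jsd_<method>.csv` /
#' `embedding_<method>.csv`.
#'
#' @param x a `cohort_report`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_cohort_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$report, file.path(dir, "report.csv"), row.names = FALSE)
  utils::write.csv(x$counts, file.path(dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(x$fd, file.path(dir, "fd.csv"), row.names = FALSE)
  utils::write.csv(x$images, file.path(dir, "status.csv"), row.names = FALSE)
  for (key in names(x$embeddings)) {
    utils::write.csv(x$embeddings[[key]],
                     file.path(dir, sprintf("embedding_%s.csv", key)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(unclass(x$divergences[[key]])),
                     file.path(dir, sprintf("jsd_%s.csv", key)),
                     row.names = FALSE)
  }
  invisible(dir)
}
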