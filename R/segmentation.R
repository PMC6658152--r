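#' Contrast enhancement of a fundus photograph
#'
#' Produces a normalized vesselness image in which vessels are bright on a
#' dark background: the green channel (highest vessel/background contrast in
#' fundus photography) is background-corrected by subtracting a large-kernel
#' median estimate, then contrast-limited adaptive histogram equalization is
#' applied. On a flat (zero-variance) input the image is returned unchanged
#' with a `flat` flag.
#'
#' @param image RGB array (H x W x 3) or grayscale matrix, values in \[0,1\].
#' @param median_radius radius of the background median filter in pixels;
#'   default scales with image size.
#' @param use_clahe apply adaptive histogram equalization after background
#'   subtraction.
#' @return matrix of class `enhanced_image` with values in \[0,1\] and
#'   attributes `provenance` (character) and `flat` (logical).
#' @export
enhance_contrast <- function(image, median_radius = NULL, use_clahe = TRUE) {
  green <- if (length(dim(image)) == 3) image[, , 2] else as.matrix(image)
  if (stats::sd(green) == 0) {
    warn("image has zero variance; nothing to enhance")
    return(structure(green, class = "enhanced_image",
                     provenance = "flat input, returned unchanged",
                     flat = TRUE))
  }
  if (is.null(median_radius))
    median_radius <- max(8L, as.integer(round(min(dim(green)) / 24)))
  g01 <- pmin(pmax(green, 0), 1)
  bg <- EBImage::medianFilter(g01, size = median_radius)
  bg <- matrix(as.numeric(bg), nrow(green), ncol(green))
  x <- pmax(bg - g01, 0)            # vessels darker than background -> bright
  rng <- range(x)
  if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng)
  prov <- sprintf("green channel; median background (radius %d) subtracted",
                  median_radius)
  if (use_clahe) {
    xe <- try(EBImage::clahe(x, nx = 8, ny = 8, limit = 2), silent = TRUE)
    if (!inherits(xe, "try-error")) {
      x <- matrix(as.numeric(xe), nrow(green), ncol(green))
      rng <- range(x)
      if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng)
      prov <- paste0(prov, "; CLAHE 8x8 clip 2")
    }
  }
  structure(x, class = "enhanced_image", provenance = prov, flat = FALSE)
}

# Otsu threshold on an arbitrary-range image; bin edges span the data range
# so the classification is invariant to adding a constant.
otsu_threshold <- function(x, n_bins = 256) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(findInterval(x, seq(r[1], r[2], length.out = n_bins + 1),
                             rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- seq(r[1], r[2], length.out = n_bins + 1)[-1] - diff(r) / (2 * n_bins)
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mt <- mu[n_bins]
  sb <- (mt * w - mu)^2 / (w * (1 - w))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Segment vessels from an enhanced image
#'
#' Default segmenter: efficient graph-based region merging
#' (Felzenszwalb–Huttenlocher) on the enhanced image, classification of the
#' resulting regions as vessel when their mean enhanced intensity exceeds an
#' Otsu threshold, and retention of the largest 8-connected vessel
#' component. Because region merging uses intensity differences and the
#' threshold is computed on range-based bins, the output is invariant to
#' adding a constant to the enhanced image.
#'
#' @param enhanced an [enhance_contrast()] result (or any matrix, vessels
#'   bright).
#' @param k adaptive-merging scale parameter of the region merger; larger
#'   values give larger regions.
#' @param min_region regions smaller than this (pixels) are absorbed into a
#'   neighbour.
#' @param min_component_frac minimum size of the largest vessel component,
#'   as a fraction of all image pixels, for the segmentation to count as
#'   successful.
#' @return integer matrix of class `vessel_mask` (1 = vessel), with
#'   attribute `source = "automated"`. On failure a classed error
#'   `fundusgraph_segmentation_failure` is signalled (mirroring images that
#'   must be discarded from a cohort).
#' @export
segment_vessels <- function(enhanced, k = 0.4, min_region = 30,
                            min_component_frac = 0.01) {
  x <- unclass(enhanced)
  labels <- fh_segment_cpp(x, k, as.integer(min_region))
  n_reg <- max(labels)
  reg_mean <- as.numeric(rowsum(as.numeric(x), as.integer(labels))) /
    tabulate(labels, nbins = n_reg)
  thr <- otsu_threshold(x)
  vessel_reg <- which(reg_mean > thr)
  if (!length(vessel_reg))
    stop_fundus("fundusgraph_segmentation_failure",
                "no region classified as vessel")
  vm <- matrix(0L, nrow(x), ncol(x))
  vm[labels %in% vessel_reg] <- 1L
  # bridge 1-2 px classification gaps so thin vessels stay attached to the
  # main component
  vm_closed <- EBImage::closing(vm, EBImage::makeBrush(3, "box"))
  vm_closed <- matrix(as.integer(vm_closed != 0), nrow(x), ncol(x))
  comp <- cc_label_cpp(vm_closed)
  if (max(comp) == 0)
    stop_fundus("fundusgraph_segmentation_failure", "empty vessel mask")
  sizes <- tabulate(comp[comp > 0], nbins = max(comp))
  vm[] <- as.integer(comp == which.max(sizes) & vm_closed == 1L)
  if (sum(vm) < min_component_frac * length(vm))
    stop_fundus("fundusgraph_segmentation_failure",
                "largest vessel component below minimum size")
  structure(vm, class = "vessel_mask", source = "automated")
}

#' Locate the optic disc
#'
#' Scores every pixel by the product of smoothed brightness and local vessel
#' density (all retinal vessels converge at the bright disc) and takes the
#' peak. Confidence is the ratio of the best peak to the second-best peak
#' found outside the first one's neighbourhood; below 1.2, or when no
#' sufficiently bright region exists, a `fundusgraph_disc_not_found` error is
#' signalled so the pipeline can discard the image. Supplying `center`
#' bypasses detection and echoes the coordinates.
#'
#' @param image RGB array or grayscale matrix.
#' @param mask a `vessel_mask` of identical dimensions.
#' @param center optional known `(row, col)` disc centre (bypass).
#' @param radius optional known disc radius in pixels.
#' @param confidence_threshold minimum peak-to-second-peak ratio.
#' @return list of class `optic_disc`: `center`, `radius`, `confidence`.
#' @export
locate_optic_disc <- function(image, mask, center = NULL, radius = NULL,
                              confidence_threshold = 1.2) {
  size <- min(dim(mask)[1:2])
  if (!is.null(center)) {
    return(structure(list(center = center,
                          radius = if (is.null(radius)) size / 16 else radius,
                          confidence = 1), class = "optic_disc"))
  }
  gray <- if (length(dim(image)) == 3)
    (image[, , 1] + image[, , 2] + image[, , 3]) / 3 else as.matrix(image)
  stopifnot(all(dim(gray) == dim(mask)))
  # difference of Gaussians at the disc scale: a bright local bump stands
  # out while the global vignette cancels
  b1 <- matrix(as.numeric(EBImage::gblur(EBImage::Image(gray),
                                         sigma = size / 48)),
               nrow(gray), ncol(gray))
  b2 <- matrix(as.numeric(EBImage::gblur(EBImage::Image(gray),
                                         sigma = size / 8)),
               nrow(gray), ncol(gray))
  bright <- pmax(b1 - b2, 0)
  dens <- matrix(as.numeric(EBImage::gblur(EBImage::Image(unclass(mask) + 0),
                                           sigma = size / 20)),
                 nrow(gray), ncol(gray))
  score <- bright * (0.2 + dens)
  peak <- which.max(score)
  pr <- (peak - 1) %% nrow(score) + 1
  pc <- (peak - 1) %/% nrow(score) + 1
  z <- (bright[pr, pc] - mean(bright)) / (stats::sd(bright) + 1e-12)
  # radius from the bright blob around the peak
  half <- (bright[pr, pc] + stats::median(bright)) / 2
  rr <- pmax(1, pr - round(size / 8)):pmin(nrow(gray), pr + round(size / 8))
  cc <- pmax(1, pc - round(size / 8)):pmin(ncol(gray), pc + round(size / 8))
  area <- sum(bright[rr, cc] > half)
  r_est <- min(max(sqrt(area / pi), size / 40), size / 8)
  # second peak outside the first one's neighbourhood
  masked <- score
  rr2 <- pmax(1, pr - round(3 * r_est)):pmin(nrow(gray), pr + round(3 * r_est))
  cc2 <- pmax(1, pc - round(3 * r_est)):pmin(ncol(gray), pc + round(3 * r_est))
  masked[rr2, cc2] <- -Inf
  second <- max(masked)
  baseline <- stats::median(score)
  confidence <- if (is.finite(second) && second > baseline)
    (score[pr, pc] - baseline) / (second - baseline) else Inf
  if (z < 2 || confidence < confidence_threshold)
    stop_fundus("fundusgraph_disc_not_found",
                sprintf("optic disc not found (confidence %.2f, z %.1f)",
                        confidence, z))
  structure(list(center = c(pr, pc), radius = r_est,
                 confidence = min(confidence, 1e6)),
            class = "optic_disc")
}

#' Read a vessel mask from disk
#'
#' Any nonzero pixel becomes 1; multi-channel rasters are reduced by their
#' maximum over channels. The result is marked as a manual segmentation.
#'
#' @param path PNG/JPEG/TIFF file.
#' @return integer matrix of class `vessel_mask` with `source = "manual"`.
#' @export
load_mask <- function(path) {
  x <- read_raster(path)
  if (length(dim(x)) == 3) x <- apply(x, c(1, 2), max)
  m <- matrix(as.integer(x > 0), nrow(x), ncol(x))
  if (sum(m) == 0) warn(sprintf("mask %s is empty", path))
  structure(m, class = "vessel_mask", source = "manual")
}

#' Write a binary mask as PNG
#' @param mask a `vessel_mask` or 0/1 matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(unclass(mask) != 0), nrow(mask), ncol(mask)),
                path)
  invisible(path)
}

# Raster reader: PNG via the png package, everything else via EBImage
# (transposed so that dim 1 = rows, matching matrix convention).
read_raster <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read %s", path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) return(png::readPNG(path))
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2) t(img) else aperm(img, c(2, 1, 3))
}
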