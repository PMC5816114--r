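#' Segmentation settings for pellet micrographs
#'
#' @param threshold_method `"otsu"` (default) picks the global threshold by
#'   Otsu's method; `"fixed"` uses `fixed_threshold`.
#' @param fixed_threshold grey level separating foreground from background
#'   when `threshold_method = "fixed"`, in image units.
#' @param min_area smallest particle kept, um^2.
#' @param despeckle_radius radius (px) of a median filter applied before
#'   thresholding; 0 disables it.
#' @param exclude_edge_touching drop particles touching the image border
#'   (default TRUE: partial particles bias Feret measurements).
#' @param pixel_size calibration, um per pixel; must be positive.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area = 0,
                                despeckle_radius = 0,
                                exclude_edge_touching = TRUE,
                                pixel_size = 1) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    stop("`fixed_threshold` is required when threshold_method = \"fixed\"", call. = FALSE)
  }
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  if (min_area < 0) stop("`min_area` must be non-negative", call. = FALSE)
  structure(
    list(threshold_method = threshold_method,
         fixed_threshold = fixed_threshold,
         min_area = min_area,
         despeckle_radius = as.integer(despeckle_radius),
         exclude_edge_touching = isTRUE(exclude_edge_touching),
         pixel_size = pixel_size),
    class = "segmentation_config"
  )
}

#' Segment a grayscale micrograph into labelled particles
#'
#' Thresholds the image (Otsu or fixed level, after an optional median-filter
#' despeckle), labels 8-connected foreground components, and removes
#' components smaller than `min_area` or touching the border when configured.
#' An image with no foreground simply yields an all-zero mask.
#'
#' @param image numeric matrix, one grey channel, rows = image rows.
#' @param cfg a [segmentation_config()].
#' @return Integer label mask of the same dimension: 0 background, each kept
#'   particle one positive label (labels consecutive from 1).
#' @export
segment_particles <- function(image, cfg = segmentation_config()) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a 2D numeric matrix (single grey channel)", call. = FALSE)
  }
  stopifnot(inherits(cfg, "segmentation_config"))
  img <- image
  rng <- range(img)
  # EBImage filters expect intensities in [0, 1]
  norm <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  if (cfg$despeckle_radius > 0) {
    norm <- EBImage::medianFilter(norm, cfg$despeckle_radius)
  }
  thr <- if (cfg$threshold_method == "otsu") {
    if (rng[2] == rng[1]) 1.1  # flat image: nothing above threshold
    else EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else {
    if (rng[2] > rng[1]) (cfg$fixed_threshold - rng[1]) / (rng[2] - rng[1]) else 1.1
  }
  bw <- norm > thr
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  lab <- matrix(as.integer(lab), nrow = nrow(image))
  # size filter (min_area is in um^2)
  min_px <- cfg$min_area / cfg$pixel_size^2
  counts <- tabulate(lab[lab > 0L])
  drop <- which(counts > 0 & counts < min_px)
  if (cfg$exclude_edge_touching) {
    edge_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, edge_labels[edge_labels > 0L])
  }
  if (length(drop) > 0) lab[lab %in% drop] <- 0L
  # relabel consecutively, preserving scan order
  kept <- sort(unique(lab[lab > 0L]))
  if (length(kept) > 0) {
    remap <- integer(max(kept)); remap[kept] <- seq_along(kept)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}
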