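#' Specify a synthetic pellet micrograph
#'
#' Describes an artificial grayscale micrograph: canvas, pixel calibration,
#' background and noise, and a list of objects to render. Two morphology
#' classes emulate the range seen in liquid-grown actinomycete cultures:
#' `"pellet"` renders a dense elliptical body with a radially decaying
#' fringe (compact aggregates), `"mat"` a branched random-walk skeleton
#' dilated into an irregular patch (dispersed mycelial mats).
#'
#' @param canvas_size integer length 2, image size in pixels (rows, cols).
#' @param pixel_size calibration, um per pixel; positive.
#' @param pellets data frame with one row per object: columns `x`, `y`
#'   (center, px), `target_feret` (um), `target_circularity` (0-1), `class`
#'   (`"pellet"` or `"mat"`).
#' @param background_level,noise_sd background intensity and Gaussian noise
#'   sd, in [0, 1] image units.
#' @param amplitude foreground intensity above background.
#' @param allow_edge_clip permit objects whose footprint leaves the canvas
#'   (default FALSE: they raise a placement error).
#' @param seed integer seed; identical specs render identical images.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(canvas_size = c(512, 512), pixel_size = 1,
                       pellets = NULL, background_level = 0.1,
                       noise_sd = 0.01, amplitude = 0.7,
                       allow_edge_clip = FALSE, seed = 1400) {
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  if (is.null(pellets)) {
    pellets <- data.frame(x = numeric(0), y = numeric(0),
                          target_feret = numeric(0),
                          target_circularity = numeric(0),
                          class = character(0), stringsAsFactors = FALSE)
  }
  need <- c("x", "y", "target_feret", "target_circularity", "class")
  if (!all(need %in% names(pellets))) {
    stop("`pellets` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(pellets$class %in% c("pellet", "mat"))) {
    stop("object class must be \"pellet\" or \"mat\"", call. = FALSE)
  }
  structure(
    list(canvas_size = as.integer(canvas_size), pixel_size = pixel_size,
         pellets = pellets, background_level = background_level,
         noise_sd = noise_sd, amplitude = amplitude,
         allow_edge_clip = isTRUE(allow_edge_clip), seed = as.integer(seed)),
    class = "image_spec"
  )
}

# Circularity of a smooth ellipse with axis ratio q (Ramanujan perimeter);
# inverted numerically to pick the axis ratio that realizes a target
# circularity for the "pellet" class.
ellipse_circularity <- function(q) {
  4 * pi * (pi * q / 4) / (ramanujan_perimeter(0.5, q / 2))^2
}
axis_ratio_for_circularity <- function(target) {
  target <- clamp(target, ellipse_circularity(0.05) + 1e-6, 0.999)
  stats::uniroot(function(q) ellipse_circularity(q) - target,
                 c(0.05, 1), tol = 1e-10)$root
}

# Rasterize one dense pellet: elliptical core with a soft edge ramp.
# Returns linear pixel indices of the object footprint and edge weights.
draw_pellet <- function(nr, nc, cx, cy, radius_px, q, angle) {
  rmax <- ceiling(radius_px + 3)
  xs <- max(1, floor(cx - rmax)):min(nc, ceiling(cx + rmax))
  ys <- max(1, floor(cy - rmax)):min(nr, ceiling(cy + rmax))
  g <- expand.grid(y = ys, x = xs)
  dx <- g$x - cx; dy <- g$y - cy
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  rho <- sqrt((u / radius_px)^2 + (v / (radius_px * q))^2)
  # solid to rho = 0.9, linear ramp to zero at rho = 1.1
  w <- clamp((1.1 - rho) / 0.2, 0, 1)
  keep <- w > 0
  list(idx = (g$x[keep] - 1) * nr + g$y[keep], w = w[keep],
       inside = rho[keep] <= 1)
}

# Rasterize one mycelial mat: branched 2D random walk from the center
# (branching probability 0.2 per step), stopped once the walk spans the
# target Feret, then dilated by a 2-px disc.
draw_mat <- function(nr, nc, cx, cy, radius_px) {
  step <- 2.5
  walkers <- list(list(p = c(cx, cy), dir = stats::runif(1, 0, 2 * pi)))
  pts <- matrix(c(cx, cy), 1)
  maxr <- 0
  steps <- 0
  while (maxr < radius_px && steps < 4000 && length(walkers) > 0) {
    nw <- list()
    for (wk in walkers) {
      dir <- wk$dir + stats::rnorm(1, 0, 0.5)
      p <- wk$p + step * c(cos(dir), sin(dir))
      # reflect at the budget radius so the mat stays inside its footprint
      if (sqrt(sum((p - c(cx, cy))^2)) > radius_px) next
      pts <- rbind(pts, p)
      maxr <- max(maxr, sqrt(sum((p - c(cx, cy))^2)))
      nw[[length(nw) + 1]] <- list(p = p, dir = dir)
      if (stats::runif(1) < 0.2) {
        nw[[length(nw) + 1]] <- list(p = p, dir = dir + sample(c(-1, 1), 1) * pi / 2)
      }
      steps <- steps + 1
    }
    walkers <- nw
    if (length(walkers) > 12) walkers <- walkers[sample.int(length(walkers), 12)]
    if (length(walkers) == 0 && maxr < radius_px) {
      walkers <- list(list(p = c(cx, cy), dir = stats::runif(1, 0, 2 * pi)))
    }
  }
  # stamp a 2-px disc at every path point
  offs <- expand.grid(dy = -2:2, dx = -2:2)
  offs <- offs[offs$dx^2 + offs$dy^2 <= 4, ]
  px <- round(rep(pts[, 1], each = nrow(offs))) + rep(offs$dx, nrow(pts))
  py <- round(rep(pts[, 2], each = nrow(offs))) + rep(offs$dy, nrow(pts))
  keep <- px >= 1 & px <= nc & py >= 1 & py <= nr
  idx <- unique((px[keep] - 1) * nr + py[keep])
  list(idx = idx, w = rep(1, length(idx)), inside = rep(TRUE, length(idx)))
}

#' Render a synthetic micrograph with ground truth
#'
#' Draws every object of the spec onto a noisy background and returns the
#' image together with a ground-truth label mask and table. Objects must not
#' overlap, and must lie fully inside the canvas unless
#' `allow_edge_clip = TRUE`; violations raise an error naming the object.
#'
#' @param spec an [image_spec()].
#' @return List with `image` (numeric matrix in [0, 1]), `mask` (integer
#'   label matrix; label i = spec row i) and `truth` (data frame of object
#'   index, class, center, intended Feret in um and circularity). Identical
#'   spec (including seed) renders a bit-identical result.
#' @export
render_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  nr <- spec$canvas_size[1]; nc <- spec$canvas_size[2]
  with_seed(spec$seed, {
    img <- matrix(spec$background_level, nr, nc)
    mask <- matrix(0L, nr, nc)
    pl <- spec$pellets
    n <- nrow(pl)
    if (n > 0) {
      radii <- pl$target_feret / 2 / spec$pixel_size
      # placement checks before any drawing
      for (i in seq_len(n)) {
        r_full <- radii[i] * 1.1 + 3
        if (!spec$allow_edge_clip &&
            (pl$x[i] - r_full < 1 || pl$x[i] + r_full > nc ||
             pl$y[i] - r_full < 1 || pl$y[i] + r_full > nr)) {
          stop("placement error: object ", i, " leaves the canvas", call. = FALSE)
        }
        if (i > 1) {
          d <- sqrt((pl$x[i] - pl$x[seq_len(i - 1)])^2 +
                      (pl$y[i] - pl$y[seq_len(i - 1)])^2)
          too_close <- d < (radii[i] + radii[seq_len(i - 1)]) * 1.1 + 6
          if (any(too_close)) {
            stop("placement error: object ", i, " overlaps object ",
                 which(too_close)[1], call. = FALSE)
          }
        }
      }
      for (i in seq_len(n)) {
        if (pl$class[i] == "pellet") {
          q <- axis_ratio_for_circularity(pl$target_circularity[i])
          # the target Feret is the major axis: radius_px is the semi-major
          ob <- draw_pellet(nr, nc, pl$x[i], pl$y[i], radii[i], q,
                            angle = stats::runif(1, 0, pi))
        } else {
          ob <- draw_mat(nr, nc, pl$x[i], pl$y[i], radii[i])
        }
        img[ob$idx] <- pmax(img[ob$idx], spec$background_level + spec$amplitude * ob$w)
        mask[ob$idx[ob$inside]] <- i
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    }
    img <- clamp(img, 0, 1)
    truth <- data.frame(
      object = seq_len(n),
      class = pl$class,
      x = pl$x, y = pl$y,
      target_feret = pl$target_feret,
      target_circularity = pl$target_circularity,
      stringsAsFactors = FALSE
    )
    list(image = img, mask = mask, truth = truth)
  })
}

#' Read or write a grayscale micrograph
#'
#' Thin wrappers around EBImage for single-channel TIFF/PNG files. Images
#' are exchanged as numeric matrices with rows = image rows and intensities
#' in [0, 1]; multichannel input is averaged to one grey channel.
#'
#' @param path file path (.tif/.tiff/.png).
#' @return `read_micrograph`: a numeric matrix.
#' @export
read_micrograph <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3) d <- apply(d, c(1, 2), mean)
  # EBImage stores x (columns) first; transpose to rows = image rows
  t(d)
}

#' @rdname read_micrograph
#' @param image numeric matrix in [0, 1].
#' @export
write_micrograph <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(image)), path)
  invisible(path)
}
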