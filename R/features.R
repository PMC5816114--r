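#' The twelve particle shape and texture features
#'
#' Canonical names, in canonical order, of the per-particle features measured
#' by [measure_particles()] and emulated by [sample_population()]:
#'
#' * `area` -- particle area, um^2.
#' * `circularity` -- `4 * pi * area / perimeter^2`, capped at 1; 1 for a
#'   perfect disk, lower for rough or elongated outlines.
#' * `max_feret` -- largest caliper distance across the particle, um.
#' * `perimeter` -- outer boundary length, um.
#' * `roundness` -- `4 * area / (pi * max_feret^2)`; penalizes elongation.
#' * `mean_intensity`, `sd_intensity` -- grey-level statistics over the
#'   particle's pixels, in image units.
#' * `min_feret` -- smallest caliper distance, um.
#' * `ellipse_perimeter` -- perimeter of the moment-equivalent ellipse, um.
#' * `bmd` -- box mass dimension: growth exponent of pixel mass inside
#'   centred boxes of increasing size (2 for a filled smooth shape).
#' * `bsd` -- box surface dimension: box-counting dimension of the particle
#'   boundary (1 for a smooth outline).
#' * `perimeter_ratio` -- convex hull perimeter / particle perimeter; 1 for
#'   convex particles, smaller for branched or ruffled ones.
#'
#' @return Character vector of length 12.
#' @export
pellet_features <- function() {
  c("area", "circularity", "max_feret", "perimeter", "roundness",
    "mean_intensity", "sd_intensity", "min_feret", "ellipse_perimeter",
    "bmd", "bsd", "perimeter_ratio")
}

# Provenance columns carried alongside the features in every particle table.
provenance_columns <- function() c("condition", "image_id", "label", "true_component")

# Check that `records` is a data frame holding the requested feature columns.
validate_records <- function(records, features = pellet_features(),
                             require_condition = FALSE) {
  if (!is.data.frame(records)) stop("`records` must be a data frame", call. = FALSE)
  missing <- setdiff(features, names(records))
  if (length(missing) > 0) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (require_condition && !"condition" %in% names(records)) {
    stop("`records` must carry a `condition` column", call. = FALSE)
  }
  invisible(records)
}
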