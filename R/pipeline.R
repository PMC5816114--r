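# End-to-end workflow: per-condition inputs (micrographs or feature CSVs)
# to population tables, similarity profiles and PC-space comparisons.

#' Condition metadata
#'
#' Describes how one condition was cultivated: vessel, agitation rate and
#' shaking orbit. Used for report annotation only; it does not influence
#' any computation.
#'
#' @param condition condition name.
#' @param vessel `"shake_flask"` or `"mtp_96_v_bottom"`.
#' @param agitation_rpm agitation rate, rpm (non-negative).
#' @param orbit_mm shaking orbit, mm (e.g. 25.4 for a 1 in. orbital shaker,
#'   1 for an MTP vortex).
#' @return An object of class `condition_meta`.
#' @export
condition_meta <- function(condition, vessel = c("shake_flask", "mtp_96_v_bottom"),
                           agitation_rpm = 0, orbit_mm = NA_real_) {
  vessel <- match.arg(vessel)
  if (agitation_rpm < 0) stop("`agitation_rpm` must be non-negative", call. = FALSE)
  structure(list(condition = condition, vessel = vessel,
                 agitation_rpm = agitation_rpm, orbit_mm = orbit_mm),
            class = "condition_meta")
}

#' Read a pipeline configuration file
#'
#' The configuration is YAML with the schema (all paths relative to the
#' file's directory):
#'
#' ```yaml
#' reference: shake_flask          # exactly one reference condition
#' pixel_size: 0.65                # um/px, for image inputs
#' seed: 1400
#' standardize: true               # standardize features before PCA
#' fwer: 0.05
#' segmentation:                   # optional, see segmentation_config()
#'   threshold_method: otsu
#'   min_area: 50
#' conditions:
#'   shake_flask:
#'     features: shake_flask.csv   # either a feature CSV ...
#'   rpm_1400:
#'     images: [img1.tif, img2.tif]  # ... or micrographs to segment
#' ```
#'
#' @param path YAML file.
#' @return The configuration as a list, ready for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (cond in names(cfg$conditions)) {
    for (field in c("features", "images")) {
      if (!is.null(cfg$conditions[[cond]][[field]])) {
        cfg$conditions[[cond]][[field]] <-
          file.path(base, cfg$conditions[[cond]][[field]])
      }
    }
  }
  cfg
}

collect_condition_records <- function(name, entry, seg_cfg, pixel_size) {
  if (!is.null(entry$features)) {
    recs <- do.call(rbind, lapply(entry$features, read_feature_csv))
    recs$condition <- name
    return(recs)
  }
  if (!is.null(entry$images)) {
    parts <- lapply(entry$images, function(p) {
      img <- read_micrograph(p)
      mask <- segment_particles(img, seg_cfg)
      measure_particles(mask, img, pixel_size = pixel_size,
                        image_id = basename(p), condition = name)
    })
    return(do.call(rbind, parts))
  }
  stop("condition `", name, "` needs either `features` or `images`", call. = FALSE)
}

#' Run the full morphology comparison workflow
#'
#' Executes, per condition: ingest feature CSVs or segment-and-measure
#' micrographs, apply exclusions, fit the two-component population model;
#' then fit the PCA on the reference condition, project all conditions, and
#' score each non-reference condition against the reference with a
#' per-feature similarity profile and a PC-score Tukey test. All tables are
#' written to `out_dir`, each stamped with a hash of the configuration, and
#' a log of every setting is kept alongside.
#'
#' @param config configuration list (see [read_run_config()] for the
#'   schema). A missing or unknown `reference` is an error before any
#'   computation starts.
#' @param out_dir output directory, created if needed; NULL writes nothing.
#' @return Invisibly, a list with `records`, `fits`, `population_table`,
#'   `pca`, `profiles`, `pc_tests`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.null(config$conditions) || length(config$conditions) == 0) {
    stop("`config$conditions` is empty", call. = FALSE)
  }
  reference <- config$reference
  if (is.null(reference) || !reference %in% names(config$conditions)) {
    stop("`config$reference` must name one of the configured conditions",
         call. = FALSE)
  }
  pixel_size <- config$pixel_size %||% 1
  seed <- config$seed %||% 1400
  standardize <- config$standardize %||% TRUE
  fwer <- config$fwer %||% 0.05
  seg_cfg <- do.call(segmentation_config,
                     c(config$segmentation %||% list(), list(pixel_size = pixel_size)))
  cfg_hash <- fnv1a_hash(paste(deparse(config[setdiff(names(config), "conditions")]),
                               collapse = ""))
  stamp <- paste0("pelletmorph config ", cfg_hash, ", seed ", seed)

  records <- list()
  for (cond in names(config$conditions)) {
    recs <- collect_condition_records(cond, config$conditions[[cond]],
                                      seg_cfg, pixel_size)
    excl <- config$conditions[[cond]]$exclude
    if (!is.null(excl)) recs <- exclude_particles(recs, as.data.frame(excl))
    records[[cond]] <- recs
  }
  all_records <- do.call(rbind, lapply(records, function(r) {
    r[, intersect(c(pellet_features(), provenance_columns()), names(r))]
  }))
  rownames(all_records) <- NULL

  fits <- list()
  for (cond in names(records)) {
    fits[[cond]] <- fit_bigaussian(records[[cond]], seed = seed)
  }
  pop_tab <- population_table(fits)

  pca <- fit_pca(records[[reference]], standardize = standardize)
  others <- setdiff(names(records), reference)
  profiles <- list()
  pc_tests <- list()
  for (cond in others) {
    profiles[[cond]] <- similarity_profile(cond, reference, all_records, fwer = fwer)
    pc_tests[[cond]] <- cbind(condition = cond,
                              pc_similarity(cond, reference, all_records, pca,
                                            fwer = fwer))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "fits"), showWarnings = FALSE)
    write_feature_csv(all_records, file.path(out_dir, "features.csv"),
                      header_comment = stamp)
    write_table <- function(df, name) {
      con <- file(file.path(out_dir, name), "w")
      writeLines(paste0("# ", stamp), con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    write_table(pop_tab, "population_table.csv")
    writeLines(c(paste0("# ", stamp),
                 utils::capture.output(print(format_population_table(pop_tab)))),
               file.path(out_dir, "population_table.txt"))
    if (length(profiles) > 0) {
      prof_tab <- do.call(rbind, lapply(names(profiles), function(cond) {
        p <- profiles[[cond]]
        cbind(data.frame(condition = cond),
              as.data.frame(as.list(ifelse(p$accept, "+", "-"))),
              data.frame(total = p$total))
      }))
      write_table(prof_tab, "similarity_profiles.csv")
      write_table(do.call(rbind, pc_tests), "pc_similarity.csv")
    }
    for (cond in names(fits)) {
      write_population_fit(fits[[cond]], file.path(out_dir, "fits",
                                                   paste0(cond, ".json")))
    }
    writeLines(c(
      paste0("# ", stamp),
      paste0("reference: ", reference),
      paste0("pixel_size: ", pixel_size),
      paste0("standardize: ", standardize),
      paste0("fwer: ", fwer),
      paste0("seed: ", seed),
      paste0("conditions: ", paste(names(records), collapse = ", ")),
      paste0("records per condition: ",
             paste(vapply(records, nrow, 0L), collapse = ", "))
    ), file.path(out_dir, "pipeline.log"))
  }

  invisible(list(records = all_records, fits = fits, population_table = pop_tab,
                 pca = pca, profiles = profiles, pc_tests = pc_tests))
}
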