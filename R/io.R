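# Readers and writers for the pipeline's table and model files.

#' Read and write particle feature tables
#'
#' Feature tables are plain CSV with one header row and one row per
#' particle: the twelve feature columns of [pellet_features()] plus the
#' provenance columns `condition`, `image_id`, `label`, `true_component`.
#' Extra columns are preserved with a warning; a missing required column is
#' an error naming it. Numeric values round-trip losslessly (written with
#' full precision).
#'
#' @param path CSV file path.
#' @return `read_feature_csv`: the particle table as a data frame.
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c(pellet_features(), provenance_columns())
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("feature CSV ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(records), required)
  if (length(extra) > 0) {
    warning("feature CSV carries extra column(s), preserved: ",
            paste(extra, collapse = ", "))
  }
  for (f in pellet_features()) {
    if (!is.numeric(records[[f]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(records[[f]]))) &
                     !is.na(records[[f]]))
      stop("malformed value in column `", f, "` at data line ",
           if (length(bad) > 0) bad[1] else "?", " of ", path, call. = FALSE)
    }
  }
  records
}

#' @rdname read_feature_csv
#' @param records particle table to write.
#' @param header_comment optional character vector written as leading
#'   `#`-comment lines (e.g. a config hash).
#' @export
write_feature_csv <- function(records, path, header_comment = NULL) {
  validate_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Serialize a population fit to JSON (and back)
#'
#' All fields of a [fit_bigaussian()] result are stored in a structured,
#' human-readable JSON file so fits can be archived next to the report
#' tables and reloaded without refitting.
#'
#' @param fit a `population_fit`.
#' @param path JSON file path.
#' @export
write_population_fit <- function(fit, path) {
  stopifnot(inherits(fit, "population_fit"))
  payload <- list(
    features = fit$features,
    mu = fit$mu, sds = fit$sds,
    ci = fit$ci,
    covs = fit$covs,
    pf1 = fit$pf1, weights = fit$weights,
    assignments = fit$assignments,
    loglik = fit$loglik, loglik_trace = fit$loglik_trace,
    n_iter = fit$n_iter, converged = fit$converged,
    degenerate = fit$degenerate, n = fit$n, seed = fit$seed
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_population_fit
#' @return `read_population_fit`: the restored `population_fit`.
#' @export
read_population_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- matrix(unlist(p$mu), 2, 2,
               dimnames = list(cluster = c("1", "2"), feature = p$features))
  sds <- matrix(unlist(p$sds), 2, 2, dimnames = dimnames(mu))
  structure(
    list(mu = mu, sds = sds,
         ci = lapply(p$ci, function(x) {
           v <- unlist(x)
           names(v) <- c("mean", "lower", "upper")
           v
         }),
         covs = lapply(p$covs, function(m) matrix(unlist(m), 2, 2)),
         pf1 = p$pf1, weights = unlist(p$weights),
         assignments = as.data.frame(p$assignments),
         loglik = p$loglik, loglik_trace = unlist(p$loglik_trace),
         n_iter = p$n_iter, converged = p$converged,
         degenerate = p$degenerate, features = p$features,
         n = p$n, seed = p$seed),
    class = "population_fit"
  )
}
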