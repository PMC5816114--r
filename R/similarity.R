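# Cross-condition similarity scoring: PCA learned on a reference condition,
# projection of every condition into that space, and Tukey HSD comparisons
# per feature and per principal component.

#' Fit a PCA model on a reference condition
#'
#' Principal components are obtained by eigendecomposition of the
#' (optionally standardized) covariance matrix of the reference records'
#' feature columns. The model stores the reference centering/scaling so any
#' other condition can later be projected into the *same* space with
#' [pca_project()] -- the model is never refit on test data. Loadings follow
#' the sign convention that each component's largest-magnitude entry is
#' positive, making fits reproducible across linear-algebra backends.
#'
#' @param records reference particle table; needs more rows than features
#'   and no missing feature values.
#' @param features feature columns to use (default the 12 of
#'   [pellet_features()]).
#' @param standardize divide each centered feature by its sd (default TRUE:
#'   the features mix um^2, um and unitless scales). A constant feature
#'   makes standardization impossible and raises an error naming it.
#' @return An object of class `pca_model` with `feature_names`, `center`,
#'   `scale` (NULL when not standardized), orthonormal `loadings` (features
#'   x components) and `explained_variance` fractions (non-increasing).
#' @export
fit_pca <- function(records, features = pellet_features(), standardize = TRUE) {
  validate_records(records, features)
  X <- as.matrix(records[, features])
  if (any(!is.finite(X))) stop("missing feature values; PCA needs complete records", call. = FALSE)
  if (nrow(X) <= length(features)) {
    stop("need more records (", nrow(X), ") than features (", length(features), ")",
         call. = FALSE)
  }
  center <- colMeans(X)
  scale <- NULL
  Xc <- sweep(X, 2, center)
  if (standardize) {
    scale <- apply(X, 2, stats::sd)
    if (any(scale == 0)) {
      stop("constant feature(s) cannot be standardized: ",
           paste(features[scale == 0], collapse = ", "), call. = FALSE)
    }
    Xc <- sweep(Xc, 2, scale, "/")
  }
  S <- stats::cov(Xc)
  e <- eigen(S, symmetric = TRUE)
  V <- e$vectors
  # sign convention: largest-magnitude loading of each component is positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- features
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  ev <- pmax(e$values, 0)
  structure(
    list(feature_names = features, center = center, scale = scale,
         loadings = V, explained_variance = ev / sum(ev),
         standardize = standardize, n = nrow(X)),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model on", length(x$feature_names), "features,", x$n, "reference records",
      if (x$standardize) "(standardized)\n" else "(covariance)\n")
  ev <- x$explained_variance
  cat("  explained variance: ",
      paste(sprintf("PC%d %.1f%%", seq_len(min(4, length(ev))), 100 * ev[seq_len(min(4, length(ev)))]),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Project records into a reference PCA space
#'
#' Applies the reference model's centering, scaling and loadings to new
#' records: `scores = ((X - center) / scale) %*% loadings`. The model is not
#' refit, so conditions can be compared in the space where the reference
#' condition shows its variability.
#'
#' @param records particle table with all model features.
#' @param model a [fit_pca()] result.
#' @return Data frame of PC scores; a `condition` column is carried through
#'   when present in `records`.
#' @export
pca_project <- function(records, model) {
  stopifnot(inherits(model, "pca_model"))
  missing <- setdiff(model$feature_names, names(records))
  if (length(missing) > 0) {
    stop("records lack model feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(records[, model$feature_names])
  Xc <- sweep(X, 2, model$center)
  if (!is.null(model$scale)) Xc <- sweep(Xc, 2, model$scale, "/")
  scores <- Xc %*% model$loadings
  out <- as.data.frame(scores)
  if ("condition" %in% names(records)) out$condition <- records$condition
  out
}

#' Tukey HSD comparison of several groups
#'
#' All pairwise mean comparisons with family-wise error controlled at `fwer`
#' through the studentized-range distribution: the interval for a pair (i, j)
#' is `mean_j - mean_i +/- q * sqrt(s2/2 * (1/n_i + 1/n_j))` with `q` the
#' upper `fwer` quantile of the studentized range for k groups and N - k
#' degrees of freedom and `s2` the pooled within-group variance. Unequal
#' group sizes are handled by the Tukey--Kramer adjustment. An interval
#' containing zero is flagged `accept`: the groups are not distinguishable
#' at this family-wise level, which the similarity workflow reads as
#' "significantly similar" (see the package vignette for the logical caveat).
#'
#' @param groups named list mapping group (condition) to a numeric sample;
#'   at least 2 groups of at least 2 values each.
#' @param fwer family-wise error rate (default 0.05).
#' @param equivalence_margin optional positive margin delta: when supplied,
#'   `accept` instead requires the whole interval to lie inside
#'   `[-delta, delta]` -- a TOST-style equivalence reading that demonstrates
#'   similarity positively rather than reading failure-to-reject as
#'   similarity. Off (NULL) by default.
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `mean_diff` (= mean of `group2` minus mean of `group1`), `lower`,
#'   `upper`, `accept`.
#' @export
tukey_hsd <- function(groups, fwer = 0.05, equivalence_margin = NULL) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("`groups` must be a named list of at least two samples", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("all groups must be named", call. = FALSE)
  }
  ns <- lengths(groups)
  if (any(ns < 2)) {
    stop("every group needs at least 2 values (offending: ",
         paste(names(groups)[ns < 2], collapse = ", "), ")", call. = FALSE)
  }
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, 0)
  vars <- vapply(groups, stats::var, 0)
  s2 <- sum((ns - 1) * vars) / (N - k)
  q <- stats::qtukey(1 - fwer, nmeans = k, df = N - k)
  pairs <- utils::combn(names(groups), 2)
  out <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    mean_diff = means[pairs[2, ]] - means[pairs[1, ]],
    stringsAsFactors = FALSE
  )
  hw <- q * sqrt(s2 / 2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  out$lower <- out$mean_diff - hw
  out$upper <- out$mean_diff + hw
  out$accept <- if (is.null(equivalence_margin)) {
    out$lower <= 0 & out$upper >= 0
  } else {
    if (equivalence_margin <= 0) stop("`equivalence_margin` must be positive", call. = FALSE)
    out$lower >= -equivalence_margin & out$upper <= equivalence_margin
  }
  rownames(out) <- NULL
  out
}

# Pull one pair's row out of a tukey_hsd result, orienting it as
# (test - reference).
extract_pair <- function(tuk, test, reference) {
  i <- which(tuk$group1 == reference & tuk$group2 == test)
  if (length(i) == 1) return(tuk[i, , drop = FALSE])
  i <- which(tuk$group1 == test & tuk$group2 == reference)
  if (length(i) != 1) stop("pair not found in Tukey result", call. = FALSE)
  row <- tuk[i, , drop = FALSE]
  row[, c("group1", "group2")] <- row[, c("group2", "group1")]
  md <- row$mean_diff
  row$mean_diff <- -md
  lo <- row$lower
  row$lower <- -row$upper
  row$upper <- -lo
  row
}

#' Per-feature similarity profile of two conditions
#'
#' For each of the twelve features, runs a Tukey HSD over *all* conditions
#' present in `records` (the whole family of pairwise comparisons, as the
#' studentized-range calibration requires) and extracts the accept flag for
#' the (test, reference) pair. The profile counts how many features are
#' "significantly similar" -- the higher the total (max 12), the closer the
#' test condition's morphology is to the reference.
#'
#' @param test_condition,reference_condition condition labels present in
#'   `records$condition`.
#' @param records combined particle table of all conditions.
#' @param fwer family-wise error rate per feature family.
#' @param features feature columns (default all 12).
#' @return Object of class `similarity_profile`: per-feature `accept` flags,
#'   the per-feature Tukey rows (`detail`), and `total`.
#' @export
similarity_profile <- function(test_condition, reference_condition, records,
                               fwer = 0.05, features = pellet_features()) {
  validate_records(records, features, require_condition = TRUE)
  conds <- unique(records$condition)
  for (cond in c(test_condition, reference_condition)) {
    if (!cond %in% conds) stop("unknown condition: ", cond, call. = FALSE)
  }
  accepts <- logical(length(features))
  names(accepts) <- features
  detail <- list()
  for (f in features) {
    groups <- split(records[[f]], records$condition)
    tuk <- tukey_hsd(groups, fwer = fwer)
    row <- extract_pair(tuk, test_condition, reference_condition)
    row$feature <- f
    accepts[f] <- row$accept
    detail[[f]] <- row
  }
  structure(
    list(test = test_condition, reference = reference_condition,
         accept = accepts, total = sum(accepts),
         detail = do.call(rbind, detail), fwer = fwer),
    class = "similarity_profile"
  )
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat("Similarity of", x$test, "vs", x$reference,
      sprintf("(FWER %.2f):\n", x$fwer))
  marks <- ifelse(x$accept, "+", "-")
  cat(" ", paste(sprintf("%s %s", names(x$accept), marks), collapse = ", "), "\n")
  cat("  total:", x$total, "of", length(x$accept), "features similar\n")
  invisible(x)
}

#' Tukey HSD on reference-space principal components
#'
#' Projects all conditions into the reference PCA space and compares the
#' test condition with the reference on the first two component scores,
#' again with the full all-pairwise Tukey family across conditions. The
#' first component typically captures pellet size, the second its shape, so
#' acceptance on both means the test condition reproduces the reference
#' morphology in the directions where it varies most.
#'
#' @param test_condition,reference_condition condition labels.
#' @param records combined particle table of all conditions.
#' @param model [fit_pca()] model fitted on the reference condition.
#' @param components which PC scores to compare (default 1:2).
#' @param fwer family-wise error rate per component family.
#' @return Data frame with one row per component: `component`, `mean_diff`,
#'   `lower`, `upper`, `accept`.
#' @export
pc_similarity <- function(test_condition, reference_condition, records, model,
                          components = 1:2, fwer = 0.05) {
  stopifnot(inherits(model, "pca_model"))
  validate_records(records, model$feature_names, require_condition = TRUE)
  scores <- pca_project(records, model)
  rows <- list()
  for (pc in components) {
    col <- paste0("PC", pc)
    groups <- split(scores[[col]], scores$condition)
    tuk <- tukey_hsd(groups, fwer = fwer)
    row <- extract_pair(tuk, test_condition, reference_condition)
    rows[[col]] <- data.frame(component = col, mean_diff = row$mean_diff,
                              lower = row$lower, upper = row$upper,
                              accept = row$accept, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
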