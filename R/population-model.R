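# Two-component bivariate Gaussian mixture fitted by EM, used to describe a
# culture condition as a population of small and large pellets.

# Log density of rows of X under a bivariate normal via Cholesky.
log_dmvnorm <- function(X, mu, S) {
  L <- chol(S)
  z <- forwardsolve(t(L), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(L))) - 0.5 * ncol(X) * log(2 * pi)
}

# Single EM run from an initial responsibility matrix. Keeps the
# log-likelihood trace; floors collapsing covariances.
em_run <- function(X, R, tol, max_iter, var_floor = 1e-6, det_floor = 1e-12) {
  n <- nrow(X)
  ll_old <- -Inf
  trace <- numeric(0)
  floored <- FALSE
  w <- NULL; mus <- NULL; Ss <- NULL; ll <- -Inf
  for (it in seq_len(max_iter)) {
    # M step
    w <- colMeans(R)
    w <- pmax(w, 1e-10); w <- w / sum(w)
    mus <- vector("list", 2); Ss <- vector("list", 2)
    for (k in 1:2) {
      rk <- R[, k]
      nk <- sum(rk)
      mu <- colSums(X * rk) / nk
      Xc <- sweep(X, 2, mu)
      S <- crossprod(Xc * rk, Xc) / nk
      if (det(S) < det_floor) {
        e <- eigen(S, symmetric = TRUE)
        e$values <- pmax(e$values, var_floor)
        S <- e$vectors %*% diag(e$values) %*% t(e$vectors)
        floored <- TRUE
      }
      mus[[k]] <- mu
      Ss[[k]] <- S
    }
    # E step
    lp <- cbind(log(w[1]) + log_dmvnorm(X, mus[[1]], Ss[[1]]),
                log(w[2]) + log_dmvnorm(X, mus[[2]], Ss[[2]]))
    m <- pmax(lp[, 1], lp[, 2])
    lse <- m + log(exp(lp[, 1] - m) + exp(lp[, 2] - m))
    ll <- sum(lse)
    R <- exp(lp - lse)
    trace <- c(trace, ll)
    if (it > 1 && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(loglik = ll, weights = w, means = mus, covs = Ss, resp = R,
       n_iter = length(trace), converged = length(trace) < max_iter,
       loglik_trace = trace, variance_floored = floored)
}

#' Fit a two-component bivariate Gaussian mixture to a particle population
#'
#' Characterizes one condition's particles as a mixture of two bivariate
#' Gaussians (full covariance) in the plane spanned by `features` --
#' by default (max Feret diameter, circularity), the plane in which
#' liquid-grown mycelial cultures separate into a small-pellet and a
#' large-pellet population. Fitted by expectation-maximization with
#' multiple restarts: the first restart initializes deterministically by
#' splitting the data at the median of the first feature, the remaining ones
#' use random responsibilities; the best log-likelihood wins. Components are
#' always relabelled so cluster 1 has the smaller mean of the first feature.
#'
#' @param records particle table containing `features` columns.
#' @param features two feature column names.
#' @param seed integer seed for the random restarts (default 1400 so
#'   repeated runs agree; override for sensitivity checks).
#' @param restarts number of EM starts (>= 1).
#' @param tol EM stops when the log-likelihood improves by less than this.
#' @param max_iter iteration cap per restart.
#' @param weighted_ci if TRUE (default), per-cluster confidence intervals
#'   and sds use responsibility weights, so the interval is centred exactly
#'   on the mixture mean; FALSE computes them on hard-assigned members,
#'   which can fall visibly off the mixture mean when components overlap.
#' @return An object of class `population_fit`: per-cluster means (`mu`,
#'   rows = clusters), standard deviations (`sds`), 95% CIs (`ci`, computed
#'   with [confidence_interval()] on cluster members), covariance matrices
#'   (`covs`), participation factor of cluster 1 in percent (`pf1`), hard
#'   assignments and responsibilities (`assignments`), the log-likelihood and
#'   its per-iteration trace, and convergence diagnostics. A fit whose
#'   covariance had to be floored (e.g. all records identical) is flagged
#'   `degenerate`.
#' @export
fit_bigaussian <- function(records, features = c("max_feret", "circularity"),
                           seed = 1400, restarts = 10, tol = 1e-8,
                           max_iter = 500, weighted_ci = TRUE) {
  if (length(features) != 2) stop("`features` must name two columns", call. = FALSE)
  validate_records(records, features)
  X <- as.matrix(records[, features])
  if (any(!is.finite(X))) stop("`records` contain missing feature values", call. = FALSE)
  n <- nrow(X)
  if (n < 10) {
    stop("at least 10 records are needed to fit the mixture (got ", n, ")",
         call. = FALSE)
  }
  best <- NULL
  with_seed(seed, {
    subseeds <- sample.int(2^31 - 2, restarts)
    for (r in seq_len(restarts)) {
      set.seed(subseeds[r])
      if (r == 1) {
        # deterministic start: split at the median of the first feature
        lower <- X[, 1] <= stats::median(X[, 1])
        R <- cbind(0.05 + 0.9 * lower, 0.05 + 0.9 * !lower)
      } else {
        a <- stats::runif(n)
        R <- cbind(a, 1 - a)
      }
      run <- em_run(X, R, tol = tol, max_iter = max_iter)
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
  })
  if (best$variance_floored) {
    warning("component covariance collapsed; variance floored at 1e-6 (degenerate fit)")
  }
  # relabel so cluster 1 has the smaller mean of the first feature
  o <- order(vapply(best$means, function(m) m[1], 0))
  mu <- rbind(best$means[[o[1]]], best$means[[o[2]]])
  dimnames(mu) <- list(cluster = c("1", "2"), feature = features)
  covs <- best$covs[o]
  w <- best$weights[o]
  resp1 <- best$resp[, o[1]]
  hard <- ifelse(resp1 >= 0.5, 1L, 2L)
  sds <- matrix(NA_real_, 2, 2, dimnames = dimnames(mu))
  ci <- list()
  for (k in 1:2) {
    members <- hard == k
    for (j in 1:2) {
      v <- X[members, j]
      if (weighted_ci) {
        wk <- if (k == 1) resp1 else 1 - resp1
        mw <- sum(wk * X[, j]) / sum(wk)
        sdw <- sqrt(sum(wk * (X[, j] - mw)^2) / (sum(wk) - 1))
        nw <- sum(wk)
        hw <- 1.96 * sdw / sqrt(nw)
        ci[[paste0("cluster", k, "_", features[j])]] <- c(mean = mw, lower = mw - hw, upper = mw + hw)
        sds[k, j] <- sdw
      } else {
        ci[[paste0("cluster", k, "_", features[j])]] <-
          if (length(v) >= 1) confidence_interval(v) else c(mean = NA, lower = NA, upper = NA)
        sds[k, j] <- if (length(v) > 1) stats::sd(v) else NA_real_
      }
    }
  }
  structure(
    list(mu = mu, sds = sds, ci = ci, covs = covs,
         pf1 = 100 * w[1], weights = w,
         assignments = data.frame(cluster = hard, resp_cluster1 = resp1),
         loglik = best$loglik, loglik_trace = best$loglik_trace,
         n_iter = best$n_iter, converged = best$converged,
         degenerate = best$variance_floored,
         features = features, n = n, seed = seed),
    class = "population_fit"
  )
}

#' @export
print.population_fit <- function(x, ...) {
  cat("Two-component Gaussian population fit (", x$n, " particles, ",
      x$n_iter, " EM iterations)\n", sep = "")
  for (k in 1:2) {
    cat(sprintf("  cluster %d: %s = %.4g, %s = %.3g\n", k,
                x$features[1], x$mu[k, 1], x$features[2], x$mu[k, 2]))
  }
  cat(sprintf("  participation factor of cluster 1: %.1f%%\n", x$pf1))
  cat(sprintf("  loglik %.4f, converged: %s%s\n", x$loglik, x$converged,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Mean and 95% confidence interval of a sample
#'
#' The interval is `mean +/- 1.96 * sd / sqrt(n)` with the sample standard
#' deviation (n - 1 denominator). A single observation yields the degenerate
#' interval (mean, mean, mean) with a warning.
#'
#' @param values numeric sample, at least one value.
#' @return Named numeric: `mean`, `lower`, `upper`.
#' @export
confidence_interval <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty sample", call. = FALSE)
  m <- mean(values)
  if (length(values) == 1) {
    warning("confidence interval from a single observation is degenerate")
    return(c(mean = m, lower = m, upper = m))
  }
  hw <- 1.96 * stats::sd(values) / sqrt(length(values))
  c(mean = m, lower = m - hw, upper = m + hw)
}

#' Particles closest to a cluster centroid
#'
#' Selects the `k` hard-assigned members of a cluster nearest to the cluster
#' centroid, with distances measured in z-scored feature space (so the two
#' features contribute comparably despite their different units). These are
#' the natural particles to display as representative of the cluster.
#'
#' @param fit a [fit_bigaussian()] result.
#' @param records the particle table the fit was computed on (same order).
#' @param cluster 1 (smaller pellets) or 2 (larger pellets).
#' @param k how many particles to return.
#' @return The `k` selected rows of `records`, sorted by distance, with a
#'   `centroid_distance` column appended.
#' @export
representative_particles <- function(fit, records, cluster = 2, k = 1) {
  stopifnot(inherits(fit, "population_fit"), cluster %in% c(1, 2))
  validate_records(records, fit$features)
  if (nrow(records) != nrow(fit$assignments)) {
    stop("`records` must be the table the fit was computed on", call. = FALSE)
  }
  members <- which(fit$assignments$cluster == cluster)
  if (k > length(members)) {
    stop("cluster ", cluster, " has only ", length(members),
         " members; cannot select ", k, call. = FALSE)
  }
  X <- as.matrix(records[, fit$features])
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  centroid <- colMeans(Z[members, , drop = FALSE])
  d <- sqrt(rowSums(sweep(Z[members, , drop = FALSE], 2, centroid)^2))
  o <- order(d)[seq_len(k)]
  out <- records[members[o], , drop = FALSE]
  out$centroid_distance <- d[o]
  out
}

#' Summarize population fits across conditions
#'
#' Builds the standard population report: one block per condition with one
#' row per feature, giving the cluster means, their 95% confidence
#' intervals, and the participation factor of cluster 1.
#'
#' @param fits named list of [fit_bigaussian()] results (names = conditions).
#' @return Data frame with columns `condition`, `feature`, `mu1`,
#'   `ci1_lower`, `ci1_upper`, `mu2`, `ci2_lower`, `ci2_upper`, `pf1`.
#'   Format it for display with [format_population_table()].
#' @export
population_table <- function(fits) {
  if (length(fits) < 1) stop("at least one fit is required", call. = FALSE)
  if (is.null(names(fits))) names(fits) <- paste0("condition_", seq_along(fits))
  rows <- list()
  for (cond in names(fits)) {
    fit <- fits[[cond]]
    for (j in seq_along(fit$features)) {
      f <- fit$features[j]
      ci1 <- fit$ci[[paste0("cluster1_", f)]]
      ci2 <- fit$ci[[paste0("cluster2_", f)]]
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, feature = f,
        mu1 = fit$mu[1, j], ci1_lower = unname(ci1["lower"]), ci1_upper = unname(ci1["upper"]),
        mu2 = fit$mu[2, j], ci2_lower = unname(ci2["lower"]), ci2_upper = unname(ci2["upper"]),
        pf1 = fit$pf1, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Format a population table for display
#'
#' Rounds as in the standard report: Feret diameters to whole um,
#' circularity to 2 decimals, participation factor to whole percent.
#'
#' @param tab result of [population_table()].
#' @return Data frame of character columns ready for printing.
#' @export
format_population_table <- function(tab) {
  is_feret <- grepl("feret", tab$feature)
  fmt <- function(x, feret) {
    ifelse(feret, sprintf("%.0f", x), sprintf("%.2f", x))
  }
  data.frame(
    condition = tab$condition,
    feature = ifelse(is_feret, "Feret's diameter", "Circularity"),
    mu1 = fmt(tab$mu1, is_feret),
    ci_mu1 = paste0(fmt(tab$ci1_lower, is_feret), "-", fmt(tab$ci1_upper, is_feret)),
    mu2 = fmt(tab$mu2, is_feret),
    ci_mu2 = paste0(fmt(tab$ci2_lower, is_feret), "-", fmt(tab$ci2_upper, is_feret)),
    pf1 = sprintf("%.0f", tab$pf1),
    stringsAsFactors = FALSE
  )
}
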