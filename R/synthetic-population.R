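#' Specify a two-component pellet population
#'
#' A `population_spec` describes a heterogeneous mycelial culture as a
#' two-component population in (max Feret diameter, circularity) space: a
#' cluster of smaller pellets and a cluster of larger ones, each bivariate
#' Gaussian, mixed in given proportions. [sample_population()] draws particle
#' feature tables from it; it is the generative inverse of the mixture model
#' fitted by [fit_bigaussian()].
#'
#' @param component_means list of two numeric vectors `c(feret, circularity)`:
#'   per-component population means (Feret in um, circularity unitless).
#' @param component_sds list of two numeric vectors `c(feret, circularity)`:
#'   per-component standard deviations; strictly positive.
#' @param weights numeric length 2, mixing proportions; non-negative, must
#'   sum to 1 (tolerance 1e-9).
#' @param n number of particles to draw; non-negative integer.
#' @param seed integer seed making [sample_population()] deterministic.
#' @param condition label stored in the `condition` column of sampled tables.
#' @param feature_link function deriving the remaining ten features from
#'   sampled (feret, circularity); the default, [default_feature_link()],
#'   uses near-elliptical geometric relations plus lognormal noise.
#'
#' @details Feret diameters are drawn from Gaussians truncated at zero.
#' Because some published population parameters have standard deviations of
#' the same order as the mean, naive truncation would inflate the realized
#' component mean well beyond the nominal value. The sampler therefore
#' re-solves the Gaussian location parameter so that the *realized* mean of
#' the truncated draw equals `component_means`; the sd is kept as the
#' Gaussian scale parameter, so under strong truncation the realized sd is
#' somewhat smaller than nominal. [population_moments()] reports the exact
#' realized moments. Circularity draws are clipped to (0, 1].
#'
#' @return An object of class `population_spec`.
#' @seealso [reference_population_specs()] for published parameter sets,
#'   [sample_population()], [derive_sd_from_ci()].
#' @export
population_spec <- function(component_means, component_sds, weights,
                            n = 500, seed = 1400, condition = "synthetic",
                            feature_link = default_feature_link) {
  if (length(component_means) != 2 || length(component_sds) != 2) {
    stop("exactly two components are required", call. = FALSE)
  }
  component_means <- lapply(component_means, as.numeric)
  component_sds <- lapply(component_sds, as.numeric)
  if (any(vapply(component_means, length, 0L) != 2) ||
      any(vapply(component_sds, length, 0L) != 2)) {
    stop("each component needs a (feret, circularity) pair", call. = FALSE)
  }
  weights <- as.numeric(weights)
  if (length(weights) != 2 || any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must be two non-negative proportions summing to 1", call. = FALSE)
  }
  if (any(unlist(component_sds) <= 0)) {
    stop("`component_sds` must be strictly positive", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 0) stop("`n` must be a non-negative integer", call. = FALSE)
  structure(
    list(component_means = component_means, component_sds = component_sds,
         weights = weights, n = n, seed = as.integer(seed),
         condition = as.character(condition), feature_link = feature_link),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Two-component pellet population spec (condition: ", x$condition, ")\n", sep = "")
  for (k in 1:2) {
    cat(sprintf("  component %d: feret %.4g um (sd %.4g), circularity %.3g (sd %.3g), weight %.3g\n",
                k, x$component_means[[k]][1], x$component_sds[[k]][1],
                x$component_means[[k]][2], x$component_sds[[k]][2], x$weights[k]))
  }
  cat("  n =", x$n, " seed =", x$seed, "\n")
  invisible(x)
}

#' Invert the confidence-interval formula into a standard deviation
#'
#' The population tables report per-cluster means with 95% confidence
#' intervals computed as `1.96 * sd / sqrt(n)`. Given a CI half-width and the
#' cluster size, this returns the implied sample standard deviation,
#' `ci_halfwidth * sqrt(n_cluster) / 1.96` -- the scale used to re-simulate a
#' published population.
#'
#' @param ci_halfwidth half-width of the 95% CI (same units as the feature);
#'   non-negative.
#' @param n_cluster number of particles in the cluster; at least 1.
#' @return The implied standard deviation.
#' @export
derive_sd_from_ci <- function(ci_halfwidth, n_cluster) {
  if (any(ci_halfwidth < 0)) stop("`ci_halfwidth` must be non-negative", call. = FALSE)
  if (any(n_cluster < 1)) stop("`n_cluster` must be at least 1", call. = FALSE)
  ci_halfwidth * sqrt(n_cluster) / 1.96
}

# Moments of a N(m, s) truncated below at `a`.
truncnorm_moments <- function(m, s, a = 0) {
  alpha <- (a - m) / s
  lambda <- stats::dnorm(alpha) / stats::pnorm(alpha, lower.tail = FALSE)
  mean <- m + s * lambda
  var <- s^2 * (1 - lambda * (lambda - alpha))
  c(mean = mean, sd = sqrt(var))
}

# Location parameter m such that N(m, s) truncated below at `a` has mean `mu`.
# The truncated mean is strictly increasing in m with range (a, Inf).
truncnorm_match_mean <- function(mu, s, a = 0) {
  if (mu <= a) stop("target mean must exceed the truncation bound", call. = FALSE)
  f <- function(m) unname(truncnorm_moments(m, s, a)["mean"]) - mu
  lo <- mu - 10 * s
  while (f(lo) > 0) lo <- lo - 10 * s
  stats::uniroot(f, c(lo, mu), tol = 1e-12)$root
}

# Moments of a N(m, s) clipped (censored) to [lo, hi].
clipnorm_moments <- function(m, s, lo, hi) {
  a <- (lo - m) / s
  b <- (hi - m) / s
  Pa <- stats::pnorm(a); Pb <- stats::pnorm(b)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  EX <- m * (Pb - Pa) - s * (pb - pa) + lo * Pa + hi * (1 - Pb)
  EX2 <- (m^2 + s^2) * (Pb - Pa) + s^2 * (a * pa - b * pb) - 2 * m * s * (pb - pa) +
    lo^2 * Pa + hi^2 * (1 - Pb)
  c(mean = EX, sd = sqrt(max(EX2 - EX^2, 0)))
}

#' Realized per-component moments of a population spec
#'
#' The sampler truncates Feret diameters at zero (mean-matched, see
#' [population_spec()]) and clips circularity to (0, 1], so the realized
#' moments of a sampled table differ slightly from the nominal parameters
#' when the truncation is strong. This returns the exact moments of the
#' sampling distribution, per component and feature.
#'
#' @param spec a [population_spec()].
#' @return A data frame with columns `component`, `feature`, `mean`, `sd`.
#' @export
population_moments <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  out <- list()
  for (k in 1:2) {
    mu <- spec$component_means[[k]]; sd <- spec$component_sds[[k]]
    m_loc <- truncnorm_match_mean(mu[1], sd[1], a = 0)
    fm <- truncnorm_moments(m_loc, sd[1], a = 0)
    cm <- clipnorm_moments(mu[2], sd[2], lo = .circ_floor, hi = 1)
    out[[k]] <- data.frame(
      component = k,
      feature = c("max_feret", "circularity"),
      mean = c(fm["mean"], cm["mean"]),
      sd = c(fm["sd"], cm["sd"]),
      row.names = NULL
    )
  }
  do.call(rbind, out)
}

# Smallest admissible circularity: keeps draws inside the open interval (0, 1].
.circ_floor <- 1e-6

# Rejection sampler for the zero-truncated Gaussian.
rtrunc_feret <- function(n, m, s) {
  x <- stats::rnorm(n, m, s)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), m, s)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Default link from (feret, circularity) to the remaining ten features
#'
#' The population model lives in (max Feret, circularity) space; the other
#' ten features are derived deterministically from near-elliptical geometry
#' plus multiplicative lognormal noise (sdlog 0.08), chosen so that feature
#' ranks are preserved: a particle that is larger or rounder than another in
#' the generative plane stays so, on average, in every derived feature.
#' Perimeter is back-computed from the circularity definition so that
#' `circularity = 4 * pi * area / perimeter^2` holds exactly before noise.
#'
#' @param feret,circularity numeric vectors of sampled generative features.
#' @return Data frame with the ten derived feature columns.
#' @export
default_feature_link <- function(feret, circularity) {
  n <- length(feret)
  eps <- function(sdlog = 0.08) exp(stats::rnorm(n, 0, sdlog))
  # axis ratio of the equivalent ellipse, tied to circularity
  q <- clamp(circularity * eps(), 0.05, 1)
  roundness <- q
  area <- (pi / 4) * feret^2 * q
  perimeter <- sqrt(4 * pi * area / clamp(circularity, .circ_floor, 1)) * eps(0.02)
  min_feret <- pmin(q * feret * eps(0.05), feret)
  ellipse_perimeter <- ramanujan_perimeter(feret / 2, min_feret / 2)
  perimeter_ratio <- clamp(ellipse_perimeter / perimeter * eps(0.05), 0.05, 1)
  bmd <- clamp(2 - 0.6 * (1 - circularity) * eps(), 1, 2)
  bsd <- clamp(1 + 0.5 * (1 - circularity) * eps(), 1, 2)
  mean_intensity <- clamp(0.35 + 0.4 * circularity * eps(), 0, 1)
  sd_intensity <- clamp(0.05 + 0.15 * (1 - circularity) * eps(), 0, 1)
  data.frame(area = area, perimeter = perimeter, roundness = roundness,
             mean_intensity = mean_intensity, sd_intensity = sd_intensity,
             min_feret = min_feret, ellipse_perimeter = ellipse_perimeter,
             bmd = bmd, bsd = bsd, perimeter_ratio = perimeter_ratio)
}

#' Draw a particle feature table from a two-component population
#'
#' Samples `spec$n` particles: each particle is assigned to a component by
#' the mixing weights, its Feret diameter and circularity are drawn from the
#' component's (truncated/clipped) Gaussians, and the remaining ten features
#' are derived through the spec's feature link. The true component of every
#' particle is kept as ground truth.
#'
#' @param spec a [population_spec()].
#' @return Data frame with the twelve feature columns of [pellet_features()]
#'   plus `condition`, `image_id`, `label` and `true_component`. Identical
#'   spec (including seed) gives an identical table.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  empty <- function() {
    cols <- c(pellet_features(), provenance_columns())
    out <- as.data.frame(lapply(cols, function(x) numeric(0)))
    names(out) <- cols
    out$condition <- character(0); out$image_id <- character(0)
    out
  }
  if (spec$n == 0) return(empty())
  with_seed(spec$seed, {
    comp <- sample(1:2, spec$n, replace = TRUE, prob = spec$weights)
    feret <- numeric(spec$n); circ <- numeric(spec$n)
    for (k in 1:2) {
      idx <- which(comp == k)
      if (length(idx) == 0) next
      mu <- spec$component_means[[k]]; sd <- spec$component_sds[[k]]
      m_loc <- truncnorm_match_mean(mu[1], sd[1], a = 0)
      feret[idx] <- rtrunc_feret(length(idx), m_loc, sd[1])
      circ[idx] <- clamp(stats::rnorm(length(idx), mu[2], sd[2]), .circ_floor, 1)
    }
    linked <- spec$feature_link(feret, circ)
    out <- data.frame(linked, max_feret = feret, circularity = circ,
                      condition = spec$condition, image_id = NA_character_,
                      label = seq_len(spec$n), true_component = comp,
                      stringsAsFactors = FALSE)
    out[, c(pellet_features(), provenance_columns())]
  })
}

#' Published population parameters for *S. lividans* cultivation conditions
#'
#' Two-component population specs for shake-flask cultures (100 ml flask,
#' 1 in. orbit, 200 rpm) and 100 ul V-bottom microtitre-plate cultures
#' vortexed at 800--1800 rpm on a 1 mm orbit, as reported for
#' *Streptomyces lividans* grown 24 h in TSBS. Component means are the
#' published per-cluster (Feret, circularity) means; standard deviations are
#' derived from the published 95% CIs with [derive_sd_from_ci()], taking the
#' cluster size as the participation factor times `n`. Where a printed CI is
#' clipped at the physical bound 0, the half-width is taken from the upper
#' side. The per-condition particle count is not published for the MTP
#' conditions; `n` defaults to 500, the approximate shake-flask count.
#'
#' @param n particles per condition.
#' @param seed base seed; condition `i` uses `seed + i`.
#' @return Named list of [population_spec()] objects: `shake_flask`,
#'   `rpm_800`, `rpm_1000`, `rpm_1200`, `rpm_1400`, `rpm_1600`, `rpm_1800`.
#' @export
reference_population_specs <- function(n = 500, seed = 1400) {
  # condition, feret mu1, ci1 lo/hi, feret mu2, ci2 lo/hi,
  # circ mu1, ci lo/hi, circ mu2, ci lo/hi, PF1 (%)
  params <- list(
    shake_flask = list(f1 = c(87, 78, 95),   f2 = c(313, 303, 323),
                       c1 = c(0.53, 0.49, 0.56), c2 = c(0.49, 0.48, 0.50), pf1 = 51),
    rpm_800     = list(f1 = c(59, 54, 65),   f2 = c(288, 255, 321),
                       c1 = c(0.53, 0.50, 0.56), c2 = c(0.39, 0.35, 0.43), pf1 = 75),
    rpm_1000    = list(f1 = c(99, 84, 113),  f2 = c(312, 245, 378),
                       c1 = c(0.30, 0, 0.34),    c2 = c(0.55, 0.49, 0.62), pf1 = 28),
    rpm_1200    = list(f1 = c(101, 94, 108), f2 = c(360, 348, 372),
                       c1 = c(0.41, 0, 0.44),    c2 = c(0.60, 0.58, 0.61), pf1 = 65),
    rpm_1400    = list(f1 = c(67, 59, 75),   f2 = c(326, 309, 343),
                       c1 = c(0.50, 0.46, 0.55), c2 = c(0.49, 0.46, 0.52), pf1 = 47),
    rpm_1600    = list(f1 = c(46, 42, 50),   f2 = c(312, 293, 332),
                       c1 = c(0.44, 0.41, 0.48), c2 = c(0.52, 0.49, 0.54), pf1 = 49),
    rpm_1800    = list(f1 = c(62, 56, 69),   f2 = c(341, 317, 366),
                       c1 = c(0.53, 0.50, 0.56), c2 = c(0.48, 0.44, 0.51), pf1 = 86)
  )
  halfwidth <- function(v) {
    # v = c(mean, lo, hi); a CI printed with lower bound 0 was clipped at the
    # physical bound, so use the upper half-width
    if (v[2] <= 0) v[3] - v[1] else (v[3] - v[2]) / 2
  }
  specs <- list()
  for (i in seq_along(params)) {
    p <- params[[i]]
    w1 <- p$pf1 / 100
    n1 <- max(round(w1 * n), 2L)
    n2 <- max(n - n1, 2L)
    specs[[names(params)[i]]] <- population_spec(
      component_means = list(c(p$f1[1], p$c1[1]), c(p$f2[1], p$c2[1])),
      component_sds = list(
        c(derive_sd_from_ci(halfwidth(p$f1), n1), derive_sd_from_ci(halfwidth(p$c1), n1)),
        c(derive_sd_from_ci(halfwidth(p$f2), n2), derive_sd_from_ci(halfwidth(p$c2), n2))
      ),
      weights = c(w1, 1 - w1),
      n = n, seed = seed + i, condition = names(params)[i]
    )
  }
  specs
}
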