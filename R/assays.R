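# Production readouts used to compare cultivation platforms.

#' Tyrosinase activity from an L-DOPA conversion time course
#'
#' Tyrosinase secreted into the culture supernatant converts
#' L-3,4-dihydroxyphenylalanine; the product absorbs at 475 nm, so the
#' activity is the rate of absorbance increase. The rate is the ordinary
#' least-squares slope over the chosen window, scaled by the dilution
#' factor. A negative slope is returned with a warning (it signals no
#' activity rather than an input error).
#'
#' @param time time points, minutes, strictly increasing.
#' @param a475 absorbance at 475 nm at each time point (AU).
#' @param dilution_factor multiplicative correction for sample dilution.
#' @param window optional integer indices of the points to fit (default:
#'   all points).
#' @param auto_window if TRUE, selects the contiguous window of at least 4
#'   points with the highest R-squared (a simple linear-range detector) and
#'   reports it.
#' @return List: `rate` (delta A475 per minute, dilution-corrected),
#'   `r_squared`, `n_points`, `window` (indices used).
#' @export
tyrosinase_rate <- function(time, a475, dilution_factor = 1,
                            window = NULL, auto_window = FALSE) {
  if (length(time) != length(a475)) stop("`time` and `a475` lengths differ", call. = FALSE)
  if (length(time) < 3) stop("at least 3 time points are required", call. = FALSE)
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing", call. = FALSE)
  ols <- function(i) {
    fit <- stats::lm(a475[i] ~ time[i])
    sst <- sum((a475[i] - mean(a475[i]))^2)
    ssr <- sum(stats::residuals(fit)^2)
    r2 <- if (sst > 0) 1 - ssr / sst else 0  # constant window: no linear signal
    list(slope = unname(stats::coef(fit)[2]), r2 = r2)
  }
  idx <- seq_along(time)
  if (!is.null(window)) {
    idx <- window
  } else if (auto_window) {
    best <- NULL
    for (a in 1:(length(time) - 3)) {
      for (b in (a + 3):length(time)) {
        r2 <- ols(a:b)$r2
        if (is.null(best) || r2 > best$r2) best <- list(r2 = r2, idx = a:b)
      }
    }
    idx <- best$idx
    message("auto-selected linear window: points ", min(idx), "-", max(idx))
  }
  if (length(idx) < 3) stop("fit window must contain at least 3 points", call. = FALSE)
  fit <- ols(idx)
  slope <- fit$slope
  r2 <- fit$r2
  if (slope < 0) warning("negative slope: no detectable tyrosinase activity")
  list(rate = slope * dilution_factor, r_squared = r2,
       n_points = length(idx), window = idx)
}

#' Actinorhodin concentration from absorbance at 542 nm
#'
#' Beer--Lambert quantification of the blue polyketide actinorhodin:
#' `concentration = a542 / (epsilon * path_length) * dilution_factor`, with
#' the molar extinction coefficient at 542 nm defaulting to
#' 18600 L mol^-1 cm^-1. The extraction protocol's phase-volume correction
#' is not inferred automatically: fold it into `dilution_factor`.
#'
#' @param a542 absorbance at 542 nm (AU), non-negative; vectorized.
#' @param epsilon molar extinction coefficient, L mol^-1 cm^-1.
#' @param path_length cuvette path, cm; positive.
#' @param dilution_factor multiplicative correction for dilution.
#' @return Molar concentration (mol/L), same length as `a542`.
#' @export
actinorhodin_concentration <- function(a542, epsilon = 18600, path_length = 1,
                                       dilution_factor = 1) {
  if (any(a542 < 0)) stop("`a542` must be non-negative", call. = FALSE)
  if (path_length <= 0) stop("`path_length` must be positive", call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  a542 / (epsilon * path_length) * dilution_factor
}
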