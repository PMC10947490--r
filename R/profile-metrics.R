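#' Fraction of wear time across acceleration bands
#'
#' Summarises a subject's wear-time intensity distribution as the diurnally
#' weighted fraction of wear time spent in each of 25 contiguous acceleration
#' bands.  Bands are left-open/right-closed with the first band closed at 0.
#'
#' @param series an [epoch_series()].
#' @param mask [detect_nonwear()] result.
#' @param weights [diurnal_weights()] result; `NULL` weights wear epochs
#'   equally.
#' @param bands band edges, see [default_bands()].
#' @return object of class `intensity_distribution`: data frame with `lower`,
#'   `upper`, `midpoint` and `fraction` per band; fractions sum to 1.
#' @export
intensity_distribution <- function(series, mask, weights = NULL,
                                   bands = default_bands()) {
  stopifnot(inherits(series, "epoch_series"), inherits(mask, "wear_mask"))
  if (!any(mask$wear)) stop("no wear epochs: cannot form intensity distribution")
  w <- if (is.null(weights)) as.numeric(mask$wear) else weights$weights
  stopifnot(length(w) == nrow(series))
  idx <- band_index(series$acceleration, bands)
  n_bands <- length(bands) - 1L
  frac <- vapply(seq_len(n_bands),
                 function(k) sum(w[mask$wear & idx == k]), numeric(1))
  frac <- frac / sum(frac)
  out <- data.frame(lower = bands[-length(bands)], upper = bands[-1],
                    midpoint = band_midpoints(bands), fraction = frac)
  class(out) <- c("intensity_distribution", "data.frame")
  out
}

#' Fit the intensity gradient
#'
#' The time-intensity relation is negative and curvilinear: children spend
#' most wear time at low accelerations and progressively less at higher
#' intensities.  On natural-log axes the relation is close to linear, and its
#' slope -- the intensity gradient -- summarises how steeply time falls away
#' with intensity (more negative = activity concentrated at low intensity).
#' Fits ordinary least squares of `ln(fraction)` on `ln(band midpoint)` over
#' bands with positive fraction; zero-fraction bands are excluded (`ln 0`
#' undefined) and the number of bands used is reported.
#'
#' @param dist an [intensity_distribution()].
#' @return object of class `ig_fit`: list with gradient `b1`, intercept `b0`,
#'   two-sided 95% confidence interval for `b1` from the t distribution with
#'   `n - 2` df, `r2` and `n_bands` used.
#' @export
fit_intensity_gradient <- function(dist) {
  stopifnot(inherits(dist, "intensity_distribution"))
  keep <- dist$fraction > 0
  n <- sum(keep)
  if (n < 3L) stop("unfittable distribution: fewer than 3 bands with positive fraction")
  x <- log(dist$midpoint[keep])
  y <- log(dist$fraction[keep])
  sxx <- sum((x - mean(x))^2)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * mean(x)
  res <- y - (b0 + b1 * x)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  s2 <- sse / (n - 2L)
  se <- sqrt(s2 / sxx)
  tcrit <- stats::qt(0.975, df = n - 2L)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  structure(list(b1 = b1, b0 = b0,
                 ci = c(lower = b1 - tcrit * se, upper = b1 + tcrit * se),
                 r2 = r2, se = se, n_bands = n),
            class = "ig_fit")
}

#' @export
print.ig_fit <- function(x, ...) {
  cat(sprintf("<ig_fit> gradient b1 = %.3f (95%% CI %.3f to %.3f), b0 = %.3f, R2 = %.3f, %d bands\n",
              x$b1, x$ci[["lower"]], x$ci[["upper"]], x$b0, x$r2, x$n_bands))
  invisible(x)
}

#' Average acceleration across wear time
#'
#' Diurnally weighted mean of wear-epoch accelerations: a proxy for the daily
#' volume of physical activity, adjusted for diurnal imbalance in non-wear.
#'
#' @inheritParams intensity_distribution
#' @return mean acceleration in m/s2.
#' @export
average_acceleration <- function(series, mask, weights = NULL) {
  stopifnot(inherits(series, "epoch_series"), inherits(mask, "wear_mask"))
  if (!any(mask$wear)) stop("no wear epochs: cannot average")
  w <- if (is.null(weights)) as.numeric(mask$wear) else weights$weights
  sum(w * series$acceleration * mask$wear) / sum(w[mask$wear])
}

#' MX metrics: intensity of the most active X minutes
#'
#' M_X is the acceleration above which the subject's most active X minutes of
#' wear time were accumulated.  With 60-s epochs this is the X-th largest
#' wear-epoch acceleration, pooled over all wear days.  M_X is non-increasing
#' in X; M480 covers the most active third of a 24-h day.
#'
#' @param series an [epoch_series()].
#' @param mask [detect_nonwear()] result.
#' @param minutes durations X (minutes) at which to read the metric.
#' @return named numeric vector `M2`, `M5`, ... in m/s2.
#' @export
mx_metrics <- function(series, mask,
                       minutes = c(2, 5, 10, 15, 30, 60, 120, 240, 480)) {
  stopifnot(inherits(series, "epoch_series"), inherits(mask, "wear_mask"),
            all(minutes >= 1), all(minutes == round(minutes)))
  acc <- series$acceleration[mask$wear]
  if (length(acc) < max(minutes)) {
    stop(sprintf("insufficient wear time: %d epochs < M%d", length(acc), max(minutes)))
  }
  srt <- sort(acc, decreasing = TRUE)
  stats::setNames(srt[minutes], paste0("M", minutes))
}

#' Moderate-to-vigorous physical activity per day
#'
#' Diurnally weighted fraction of wear epochs at or above `met_threshold`
#' metabolic equivalents, expressed as minutes per 24-h day.
#'
#' @inheritParams intensity_distribution
#' @param met_threshold METs defining moderate intensity (default 4).
#' @return MVPA in min/day (0..1440).
#' @export
mvpa_minutes <- function(series, mask, weights = NULL, met_threshold = 4) {
  stopifnot(inherits(series, "epoch_series"), inherits(mask, "wear_mask"))
  if (all(is.na(series$met_estimate))) stop("missing MET channel")
  if (!any(mask$wear)) stop("no wear epochs")
  w <- if (is.null(weights)) as.numeric(mask$wear) else weights$weights
  hit <- mask$wear & !is.na(series$met_estimate) &
    series$met_estimate >= met_threshold
  1440 * sum(w[hit]) / sum(w[mask$wear])
}

#' Standardize MX metrics by sex-specific means
#'
#' Divides each M_X by the corresponding sex-specific mean, putting the nine
#' MX metrics on a common relative scale (1 = the sex average at that X).
#'
#' @param profile named numeric vector of raw MX values.
#' @param sex_means named numeric vector of sex-specific mean MX values,
#'   covering the names in `profile`.
#' @return named numeric vector of standardized MX values.
#' @export
standardize_mx <- function(profile, sex_means) {
  stopifnot(is.numeric(profile), is.numeric(sex_means),
            all(names(profile) %in% names(sex_means)))
  m <- sex_means[names(profile)]
  if (any(!is.finite(m) | m <= 0)) stop("sex-specific mean MX must be positive")
  profile / m
}

#' Full movement profile for one subject
#'
#' Runs the whole per-subject pipeline: non-wear detection, validity
#' assessment, diurnal weighting, and the four profile metrics.
#'
#' @param series an [epoch_series()].
#' @param bands band edges for the intensity distribution.
#' @param require_valid error if the wear-time validity rules fail.
#' @param ... passed to [detect_nonwear()].
#' @return object of class `profile_metrics`: list with `subject_id`,
#'   `average_acceleration`, `ig` ([fit_intensity_gradient()] result), `mx`,
#'   `mvpa`, `wear_h`, `validity` and the `distribution`.
#' @export
subject_profile <- function(series, bands = default_bands(),
                            require_valid = TRUE, ...) {
  mask <- detect_nonwear(series, ...)
  validity <- assess_validity(series, mask)
  if (require_valid && !validity$valid) {
    stop("invalid wear record: ", paste(validity$failed, collapse = ", "))
  }
  w <- diurnal_weights(series, mask)
  dist <- intensity_distribution(series, mask, w, bands)
  structure(list(
    subject_id = series$subject_id[1],
    average_acceleration = average_acceleration(series, mask, w),
    ig = fit_intensity_gradient(dist),
    mx = mx_metrics(series, mask),
    mvpa = mvpa_minutes(series, mask, w),
    wear_h = sum(mask$wear) / 60,
    validity = validity,
    distribution = dist
  ), class = "profile_metrics")
}

#' @export
print.profile_metrics <- function(x, ...) {
  cat(sprintf("<profile_metrics> subject %s (wear %.1f h)\n", x$subject_id, x$wear_h))
  cat(sprintf("  average-acceleration: %.3f m/s2\n", x$average_acceleration))
  cat(sprintf("  intensity-gradient:   %.3f (R2 %.3f)\n", x$ig$b1, x$ig$r2))
  cat(sprintf("  MVPA:                 %.1f min/day\n", x$mvpa))
  cat("  MX (m/s2):", paste(sprintf("%s=%.2f", names(x$mx), x$mx), collapse = " "), "\n")
  invisible(x)
}
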