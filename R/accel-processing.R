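#' Convert activity counts to acceleration
#'
#' Calibrates integer sensor counts per 60-s epoch to acceleration in SI
#' units by the fixed factor 0.003 m/s2 per count.
#'
#' @param counts non-negative integer counts per epoch.
#' @param factor m/s2 per count.
#' @return acceleration in m/s2.
#' @export
#' @examples
#' counts_to_acceleration(c(0, 50, 1000))  # 0, 0.15, 3 m/s2
counts_to_acceleration <- function(counts, factor = 0.003) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  counts * factor
}

#' Default heart-rate plausibility bounds (bpm)
#'
#' A heart rate is treated as non-physiological when it is missing, below
#' `low` or above `high`.  Children's true heart rates sit well inside
#' 30-240 bpm, so values outside signal an unworn or malfunctioning sensor.
#' @export
hr_limits <- function(low = 30, high = 240) {
  stopifnot(low > 0, high > low)
  list(low = low, high = high)
}

nonphysiological_hr <- function(hr, limits = hr_limits()) {
  is.na(hr) | hr < limits$low | hr > limits$high
}

#' Detect non-wear intervals
#'
#' An interval is classified as non-wear when every epoch in it has zero
#' acceleration combined with a non-physiological heart rate and the
#' interval lasts strictly more than `min_duration` minutes (default 90).
#' A long zero-acceleration block with a plausible heart rate is sedentary
#' wear, not non-wear.  Maximal candidate runs are evaluated, so the rule is
#' local: prepending or appending wear epochs does not change the intervals
#' found.
#'
#' @param series an [epoch_series()].
#' @param min_duration minutes a candidate block must strictly exceed.
#' @param limits heart-rate plausibility bounds from [hr_limits()].
#' @return object of class `wear_mask`: list with `wear` (logical per epoch)
#'   and `intervals` (data frame with `start`, `end`, `minutes` for each
#'   non-wear interval).
#' @export
detect_nonwear <- function(series, min_duration = 90, limits = hr_limits()) {
  stopifnot(inherits(series, "epoch_series"), min_duration > 0)
  candidate <- series$acceleration == 0 & nonphysiological_hr(series$heart_rate, limits)
  r <- rle(candidate)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nonwear_run <- r$values & r$lengths > min_duration  # epochs are 1 min
  wear <- rep(TRUE, nrow(series))
  iv <- data.frame(start = series$timestamp[integer(0)],
                   end = series$timestamp[integer(0)], minutes = numeric(0))
  if (any(nonwear_run)) {
    for (j in which(nonwear_run)) wear[starts[j]:ends[j]] <- FALSE
    iv <- data.frame(
      start = series$timestamp[starts[nonwear_run]],
      end = series$timestamp[ends[nonwear_run]] + 60,
      minutes = r$lengths[nonwear_run]
    )
  }
  structure(list(wear = wear, intervals = iv, min_duration = min_duration),
            class = "wear_mask")
}

#' @export
print.wear_mask <- function(x, ...) {
  cat(sprintf("<wear_mask> %d/%d wear epochs, %d non-wear interval(s) (>%g min rule)\n",
              sum(x$wear), length(x$wear), nrow(x$intervals), x$min_duration))
  invisible(x)
}

#' Default day-segment boundaries
#'
#' Clock boundaries for the four day segments used by the wear-time validity
#' rules: morning 06:00-12:00, noon 12:00-15:00, afternoon 15:00-19:00,
#' evening 19:00-24:00 (half-open on the right).  Night hours (00:00-06:00)
#' belong to no segment but still count toward total wear.
#' @return named list of `c(start_hour, end_hour)` pairs.
#' @export
day_segments <- function() {
  list(morning = c(6, 12), noon = c(12, 15),
       afternoon = c(15, 19), evening = c(19, 24))
}

#' Assess wear-time validity
#'
#' A record is valid when it carries at least `total_h` hours of wear overall,
#' `weekday_h` on weekdays (Mon-Fri), `weekend_h` on weekend days, and
#' `segment_h` in each of the four day segments.  Defaults are 48/32/16/12 h.
#' Each rule is evaluated independently and reported; validity is their
#' conjunction.
#'
#' @param series an [epoch_series()].
#' @param mask [detect_nonwear()] result for the series.
#' @param total_h,weekday_h,weekend_h,segment_h thresholds in hours.
#' @param segments day-segment map, see [day_segments()].
#' @return object of class `validity_report`: list with `valid`, `failed`
#'   (labels of the rules not met) and `hours` (total, weekday, weekend and
#'   per-segment wear hours).
#' @export
assess_validity <- function(series, mask,
                            total_h = 48, weekday_h = 32, weekend_h = 16,
                            segment_h = 12, segments = day_segments()) {
  stopifnot(inherits(series, "epoch_series"), inherits(mask, "wear_mask"),
            length(mask$wear) == nrow(series))
  wear <- mask$wear
  hrs <- function(sel) sum(wear & sel) / 60
  wk <- is_weekend(series$timestamp)
  hour_frac <- minute_of_day(series$timestamp) / 60
  hours <- list(total = hrs(TRUE), weekday = hrs(!wk), weekend = hrs(wk))
  for (seg in names(segments)) {
    b <- segments[[seg]]
    hours[[seg]] <- hrs(hour_frac >= b[1] & hour_frac < b[2])
  }
  need <- c(total = total_h, weekday = weekday_h, weekend = weekend_h,
            stats::setNames(rep(segment_h, length(segments)), names(segments)))
  got <- unlist(hours)[names(need)]
  failed <- sprintf("%s>=%gh", names(need), need)[got < need]
  structure(list(valid = length(failed) == 0L, failed = failed, hours = hours,
                 thresholds = as.list(need)),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> %s; wear %.1f h (weekday %.1f, weekend %.1f)\n",
              if (x$valid) "VALID" else paste("INVALID:", paste(x$failed, collapse = ", ")),
              x$hours$total, x$hours$weekday, x$hours$weekend))
  invisible(x)
}

#' Diurnal-balance weights for wear epochs
#'
#' Non-wear rarely spreads evenly over the day, so an unweighted mean over
#' wear epochs over-represents the times of day the monitor was worn most.
#' These weights remove that imbalance: the 24 hour-of-day slots each receive
#' equal total weight, split uniformly over the wear epochs falling in the
#' slot (pooled across days).  A weighted mean over epochs then weights every
#' hour of the day equally.
#'
#' @param series an [epoch_series()].
#' @param mask [detect_nonwear()] result.
#' @param n_slots number of equal time-of-day slots (default 24 hourly).
#' @return object of class `diurnal_weights`: list with `weights` (per epoch,
#'   zero on non-wear, summing to 1), `slot` (per-epoch slot index) and
#'   `slot_epochs` (wear epochs per slot).
#' @export
diurnal_weights <- function(series, mask, n_slots = 24L) {
  stopifnot(inherits(series, "epoch_series"), inherits(mask, "wear_mask"),
            length(mask$wear) == nrow(series), n_slots >= 1L,
            1440 %% n_slots == 0)
  slot <- minute_of_day(series$timestamp) %/% (1440L %/% n_slots) + 1L
  tab <- tabulate(slot[mask$wear], nbins = n_slots)
  if (any(tab == 0L)) {
    stop(sprintf("cannot balance: empty slot (no wear epochs in slot %s)",
                 paste(which(tab == 0L), collapse = ", ")))
  }
  w <- numeric(nrow(series))
  w[mask$wear] <- 1 / (n_slots * tab[slot[mask$wear]])
  structure(list(weights = w, slot = slot, slot_epochs = tab, n_slots = n_slots),
            class = "diurnal_weights")
}

#' @export
print.diurnal_weights <- function(x, ...) {
  cat(sprintf("<diurnal_weights> %d slots, %d-%d wear epochs per slot\n",
              x$n_slots, min(x$slot_epochs), max(x$slot_epochs)))
  invisible(x)
}
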