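#' Reference activity intensity anchors
#'
#' Typical accelerations of named children's activities, used to translate a
#' difference in average-acceleration into minutes of activity: vigorous
#' play such as skipping, running and soccer sits above 4 m/s2, brisk
#' walking (5.2 km/h) around 1.5 m/s2, and slow walking (3.2 km/h) around
#' 0.75 m/s2.
#'
#' @return data frame with `label` and `acceleration` (m/s2).
#' @export
activity_anchors <- function() {
  data.frame(
    label = c("high-intensity activities (running, jumping, skipping)",
              "brisk walking (5.2 km/h)",
              "slow walking / light activity (3.2 km/h)"),
    acceleration = c(4, 1.5, 0.75)
  )
}

#' Sex-specific reference statistics for average-acceleration
#'
#' Published descriptive statistics of the 9-11-year-old cohort the default
#' synthetic generator emulates: mean and standard deviation of
#' average-acceleration (m/s2) by sex.  These are the inputs of the
#' time-reallocation translation.
#'
#' @return data frame with `sex`, `mean_avg_acc`, `sd_avg_acc`.
#' @export
reference_cohort_stats <- function() {
  data.frame(sex = c("female", "male"),
             mean_avg_acc = c(0.19, 0.22),
             sd_avg_acc = c(0.0579, 0.0696))
}

#' Minutes/day of an activity equivalent to a 1-SD volume increase
#'
#' Isotemporal reallocation: if time spent at the current average
#' acceleration is replaced by an activity at `anchor_acc`, the daily mean
#' rises by `minutes/1440 * (anchor_acc - mean_avg_acc)`.  Solving for a rise
#' of one standard deviation gives
#' `1440 * sd / (anchor_acc - mean_avg_acc)` minutes per day, returned
#' unrounded.  Minutes scale linearly in `sd` and fall as the anchor becomes
#' more intense.
#'
#' @param sd standard deviation of average-acceleration (m/s2).
#' @param mean_avg_acc mean average-acceleration (m/s2).
#' @param anchor_acc acceleration of the replacement activity (m/s2); may be
#'   a vector.
#' @return minutes per day (same length as `anchor_acc`).
#' @export
#' @examples
#' reallocation_minutes(0.0579, 0.19, c(4, 1.5, 0.75))
reallocation_minutes <- function(sd, mean_avg_acc, anchor_acc) {
  stopifnot(sd > 0, mean_avg_acc >= 0)
  if (any(anchor_acc <= mean_avg_acc)) {
    stop("activity not more intense than current average")
  }
  1440 * sd / (anchor_acc - mean_avg_acc)
}

#' Round a reallocation result for reporting
#'
#' Below `hour_cut` minutes the value is reported to the nearest minute;
#' at or above it, converted to hours and rounded to the nearest half hour.
#'
#' @param minutes unrounded minutes/day.
#' @param hour_cut minutes at which reporting switches to hours.
#' @return data frame with `value`, `unit` (`"min"` or `"h"`) and a
#'   formatted `display` string.
#' @export
round_reallocation <- function(minutes, hour_cut = 120) {
  as_hours <- minutes >= hour_cut
  value <- ifelse(as_hours, round(minutes / 60 * 2) / 2, round(minutes))
  unit <- ifelse(as_hours, "h", "min")
  data.frame(value = value, unit = unit,
             display = paste(sprintf("%g", value), unit))
}

#' Render the activity-equivalence list
#'
#' For each stratum, computes and formats the minutes/day of each anchor
#' activity that would raise average-acceleration by one standard deviation
#' if it replaced time at the current average.  Anchors not more intense
#' than the stratum mean are omitted with a warning.  Any combination of the
#' listed activities whose acceleration increases sum to the SD achieves the
#' same 1-SD rise; the returned table carries that note as an attribute.
#'
#' @param stratum_stats data frame like [reference_cohort_stats()]: one row
#'   per stratum with `sex` (or `stratum`), `mean_avg_acc`, `sd_avg_acc`.
#' @param anchors data frame with `label`, `acceleration`; defaults to
#'   [activity_anchors()].
#' @param hour_cut passed to [round_reallocation()].
#' @return data frame of class `pa_translation`: stratum, label,
#'   anchor acceleration, sd, mean, exact minutes, rounded value + unit and
#'   display string.
#' @export
render_translation <- function(stratum_stats, anchors = activity_anchors(),
                               hour_cut = 120) {
  stopifnot(all(c("mean_avg_acc", "sd_avg_acc") %in% names(stratum_stats)),
            all(c("label", "acceleration") %in% names(anchors)))
  strat <- if ("sex" %in% names(stratum_stats)) stratum_stats$sex else
    stratum_stats$stratum
  out <- list()
  for (i in seq_len(nrow(stratum_stats))) {
    m <- stratum_stats$mean_avg_acc[i]
    s <- stratum_stats$sd_avg_acc[i]
    ok <- anchors$acceleration > m
    if (any(!ok)) {
      warning(sprintf("stratum %s: anchor(s) %s not more intense than the mean; omitted",
                      strat[i], paste(anchors$label[!ok], collapse = "; ")))
    }
    a <- anchors[ok, , drop = FALSE]
    mins <- reallocation_minutes(s, m, a$acceleration)
    r <- round_reallocation(mins, hour_cut)
    out[[i]] <- data.frame(stratum = strat[i], label = a$label,
                           anchor_acc = a$acceleration, sd = s, mean = m,
                           minutes_exact = mins, value = r$value,
                           unit = r$unit, display = r$display,
                           row.names = NULL)
  }
  res <- do.call(rbind, out)
  attr(res, "note") <- paste("Any combination of the listed activities whose",
                             "acceleration increases sum to the stratum SD",
                             "achieves the same 1-SD rise in average-acceleration.")
  class(res) <- c("pa_translation", "data.frame")
  res
}

#' @export
print.pa_translation <- function(x, ...) {
  for (s in unique(x$stratum)) {
    cat(sprintf("1 SD increase in average-acceleration, %s (SD %.4f m/s2, mean %.2f m/s2):\n",
                s, x$sd[x$stratum == s][1], x$mean[x$stratum == s][1]))
    sub <- x[x$stratum == s, ]
    cat(sprintf("  %-55s %s/day\n", sub$label, sub$display), sep = "")
  }
  cat("Note:", attr(x, "note"), "\n")
  invisible(x)
}
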