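#' Construct a 60-s epoch series
#'
#' An `epoch_series` is a data frame holding one subject's combined-sensor
#' record in consecutive 60-second epochs: a timestamp, an integer activity
#' count, the calibrated acceleration in m/s2 (always exactly
#' `counts * 0.003`), heart rate in beats/min, and an estimated
#' metabolic-equivalent (MET) value.
#'
#' @param subject_id single string.
#' @param timestamp `POSIXct` vector, strictly increasing at 60-s spacing.
#' @param counts non-negative integer activity counts per epoch.
#' @param heart_rate heart rate in bpm; `NA` for missing.
#' @param met_estimate estimated METs per epoch; `NA` if the channel is
#'   unavailable.
#' @return data frame of class `epoch_series` with columns `subject_id`,
#'   `timestamp`, `counts`, `acceleration`, `heart_rate`, `met_estimate`.
#' @seealso [counts_to_acceleration()], [detect_nonwear()]
#' @export
epoch_series <- function(subject_id, timestamp, counts,
                         heart_rate = NA_real_, met_estimate = NA_real_) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            inherits(timestamp, "POSIXct"))
  n <- length(timestamp)
  if (n < 1L) stop("epoch series must contain at least one epoch")
  counts <- as.integer(round(counts))
  if (length(counts) != n) stop("counts and timestamp lengths differ")
  if (anyNA(counts) || any(counts < 0L)) stop("counts must be non-negative")
  dt <- diff(as.numeric(timestamp))
  if (n > 1L && any(dt != 60)) {
    stop("timestamps must be strictly increasing at 60-s spacing")
  }
  heart_rate <- rep_len(as.numeric(heart_rate), n)
  met_estimate <- rep_len(as.numeric(met_estimate), n)
  out <- data.frame(
    subject_id = subject_id,
    timestamp = timestamp,
    counts = counts,
    acceleration = counts_to_acceleration(counts),
    heart_rate = heart_rate,
    met_estimate = met_estimate
  )
  class(out) <- c("epoch_series", "data.frame")
  out
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> subject %s: %d epochs (%.1f h), %s .. %s\n",
              x$subject_id[1], nrow(x), nrow(x) / 60,
              format(x$timestamp[1]), format(x$timestamp[nrow(x)])))
  invisible(x)
}

# minute-of-day (0..1439) and hour-of-day slot (0..23) in the series' clock
minute_of_day <- function(timestamp) {
  lt <- as.POSIXlt(timestamp)
  lt$hour * 60L + lt$min
}

is_weekend <- function(timestamp) {
  format(timestamp, "%u") %in% c("6", "7")
}
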