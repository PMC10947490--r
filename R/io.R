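# Plain-text interchange: per-subject epoch CSVs, cohort tables, and JSON
# reports.  The epoch CSV dialect carries counts (not acceleration);
# acceleration is always re-derived as counts * 0.003 on read.

#' Write a per-subject epoch CSV
#'
#' Columns: `subject_id`, `timestamp` (ISO-8601, local clock), `counts`,
#' `heart_rate_bpm` (empty when missing), `met_estimate`.
#'
#' @param series an [epoch_series()].
#' @param path output file.
#' @export
write_epoch_csv <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  out <- data.frame(
    subject_id = series$subject_id,
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S"),
    counts = series$counts,
    heart_rate_bpm = series$heart_rate,
    met_estimate = series$met_estimate
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a per-subject epoch CSV
#'
#' Reads the dialect written by [write_epoch_csv()] (header required, UTF-8,
#' missing heart rate as an empty field) and rebuilds the calibrated
#' [epoch_series()].
#'
#' @param path input file.
#' @return an [epoch_series()].
#' @export
read_epoch_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "counts", "heart_rate_bpm", "met_estimate")
  if (!all(need %in% names(d))) {
    stop("epoch CSV must contain columns: ", paste(need, collapse = ", "))
  }
  ts <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in ", path)
  epoch_series(d$subject_id[1], ts, d$counts,
               as.numeric(d$heart_rate_bpm), as.numeric(d$met_estimate))
}

#' Write a cohort to disk
#'
#' Writes one epoch CSV per subject, the covariate/outcome table, and a JSON
#' manifest recording the master seed and every subject's generating
#' parameters (ground truth for recovery experiments).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @param epochs also write per-subject epoch CSVs (can be large).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, epochs = FALSE) {
  stopifnot(inherits(cohort, "pa_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  manifest <- list(seed = cohort$seed,
                   coefficients = unclass(cohort$coeffs),
                   subjects = cohort$subjects)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (epochs) {
    for (id in cohort$subjects$subject_id) {
      write_epoch_csv(subject_series(cohort, id),
                      file.path(dir, paste0(id, "_epochs.csv")))
    }
  }
  invisible(dir)
}

#' Write a wear/validity JSON report
#'
#' @param series an [epoch_series()].
#' @param mask [detect_nonwear()] result.
#' @param report [assess_validity()] result.
#' @param path output file.
#' @export
write_validity_json <- function(series, mask, report, path) {
  obj <- list(
    subject_id = series$subject_id[1],
    valid = report$valid,
    failed = as.list(report$failed),
    hours = report$hours,
    nonwear_intervals = data.frame(
      start = format(mask$intervals$start, "%Y-%m-%dT%H:%M:%S"),
      end = format(mask$intervals$end, "%Y-%m-%dT%H:%M:%S"),
      minutes = mask$intervals$minutes
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Collect per-subject profile metrics into a flat table
#'
#' @param profiles list of [subject_profile()] results.
#' @return data frame, one row per subject: average_acceleration, ig_b1,
#'   ig_b0, ig_r2, ig_ci_lo, ig_ci_hi, the MX columns, mvpa_min_day, wear_h.
#' @export
metrics_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "profile_metrics"))
    cbind(data.frame(subject_id = p$subject_id,
                     average_acceleration = p$average_acceleration,
                     ig_b1 = p$ig$b1, ig_b0 = p$ig$b0, ig_r2 = p$ig$r2,
                     ig_ci_lo = p$ig$ci[["lower"]], ig_ci_hi = p$ig$ci[["upper"]]),
          as.data.frame(as.list(p$mx)),
          data.frame(mvpa_min_day = p$mvpa, wear_h = p$wear_h))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write the per-subject metrics CSV and the band-fraction audit CSV
#'
#' @param profiles list of [subject_profile()] results.
#' @param metrics_path,bands_path output files (`NULL` to skip one).
#' @export
write_metrics_csv <- function(profiles, metrics_path, bands_path = NULL) {
  utils::write.csv(metrics_table(profiles), metrics_path, row.names = FALSE)
  if (!is.null(bands_path)) {
    long <- do.call(rbind, lapply(profiles, function(p) {
      cbind(subject_id = p$subject_id, as.data.frame(p$distribution))
    }))
    utils::write.csv(long, bands_path, row.names = FALSE)
  }
  invisible(metrics_path)
}

#' Write tidy model results / radar-ready group summaries
#'
#' @param x a `pa_model_sequence` (or its `results` data frame), or a
#'   [group_mx_summary()] data frame.
#' @param path output CSV.
#' @export
write_results_csv <- function(x, path) {
  if (inherits(x, "pa_model_sequence")) x <- x$results
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
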