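# Hand-built epoch fixtures.  Series start on Monday 2021-05-31 so the
# weekday/weekend split is known by construction.

monday0 <- as.POSIXct("2021-05-31 00:00:00", tz = "UTC")

make_series <- function(counts, hr = 120, met = NULL, start = monday0,
                        id = "fix") {
  n <- length(counts)
  acc <- counts * 0.003
  if (is.null(met)) met <- 1 + 2 * acc
  epoch_series(id, start + 60 * (seq_len(n) - 1), counts,
               rep_len(hr, n), rep_len(met, n))
}

# wear defined by clock windows: `windows` is a data.frame(day, start_min,
# end_min) with day 1 = Monday; wear epochs get counts 100 / HR 120,
# everything else is zero counts with HR 0 (non-wear signature).
make_wear_series <- function(days, windows, wear_counts = 100) {
  n <- days * 1440L
  counts <- integer(n)
  hr <- numeric(n)
  for (i in seq_len(nrow(windows))) {
    idx <- (windows$day[i] - 1L) * 1440L +
      (windows$start_min[i] + 1L):windows$end_min[i]
    counts[idx] <- wear_counts
    hr[idx] <- 120
  }
  make_series(counts, hr = hr)
}

# intensity distribution assembled directly from fractions (for oracle tests)
make_distribution <- function(fraction, bands = default_bands()) {
  stopifnot(length(fraction) == length(bands) - 1L)
  out <- data.frame(lower = bands[-length(bands)], upper = bands[-1],
                    midpoint = band_midpoints(bands), fraction = fraction)
  class(out) <- c("intensity_distribution", "data.frame")
  out
}

# closed-form OLS slope/intercept via the covariance-ratio formula;
# independent of the fitting code under test
ols_slope_oracle <- function(x, y) {
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(b1 = b1, b0 = mean(y) - b1 * mean(x))
}

# small cohort table with fully controlled columns
make_table <- function(n = 40, sex = "female", seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    sex = sex,
    age = runif(n, 9, 11),
    stature = rnorm(n, 140, 6),
    pubertal = rbinom(n, 1, 0.3),
    wear_time = runif(n, 96, 216),
    avg_acc = rnorm(n, 0.2, 0.06),
    intensity_gradient = rnorm(n, -1.7, 0.15),
    mvpa = runif(n, 20, 120),
    lean_mass = rnorm(n, 21, 3),
    fat_mass = rnorm(n, 7, 2),
    tblh_bmc = rnorm(n, 0.9, 0.2)
  )
}
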