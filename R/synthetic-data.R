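# Synthetic cohort generator.
#
# The epoch-level intensity process is a two-component mixture chosen so that
# its marginal time-in-band distribution has a closed form: each 60-s epoch
# is "active" with a time-of-day-dependent probability (smooth 24-h curve
# peaking mid-afternoon); active epochs draw their band from a discrete
# power law over the band midpoints (weight proportional to midpoint ^
# tail_exponent above a floor band) and then uniformly within the band;
# inactive epochs are sedentary (mostly exact zeros, otherwise a small value
# in the first band).  Diurnal modulation acts on the activity probability,
# not the magnitude, so it changes when activity happens without disturbing
# the band distribution of active time -- which keeps the analytic band
# fractions exact for records spanning whole days.

# prob. an inactive (sedentary) epoch has exactly zero counts; otherwise it
# draws uniformly within the first band
.sedentary_zero_prob <- 0.7
.met_slope <- 2  # METs = 1 + 2 * acceleration; 4 METs at 1.5 m/s2

# smooth 24-h activity-probability shape (arbitrary scale); a raised
# Gaussian bump peaking at 14:30 with a small nocturnal floor
diurnal_shape <- function(minute_of_day) {
  h <- minute_of_day / 60
  0.15 + exp(-0.5 * ((h - 14.5) / 3.5)^2)
}

#' Parameters of one synthetic subject
#'
#' @param subject_id single string.
#' @param sex `"female"` or `"male"`.
#' @param age years.
#' @param stature cm.
#' @param pubertal 0 (prepubertal) or 1 (pubertal).
#' @param base_level target mean acceleration of the subject's process over a
#'   full day, m/s2 (must exceed the sedentary floor, about 0.04 m/s2).
#' @param tail_exponent negative power-law exponent of the time-in-band
#'   distribution's upper tail; closer to 0 = heavier tail = activity spread
#'   further into high intensities.
#' @param wear_days whole days of recording, 4 to 9; the window is placed so
#'   it always contains one full weekend.
#' @param nonwear_blocks data frame with columns `day` (1-based), `start_min`
#'   (minute of day, 0-1439) and `duration_min`, or `NULL`.  Blocks are
#'   zeroed and given a non-physiological heart rate.
#' @return object of class `subject_params`.
#' @export
subject_params <- function(subject_id, sex = c("female", "male"),
                           age = 9.75, stature = 140, pubertal = 0L,
                           base_level = 0.2, tail_exponent = -1.5,
                           wear_days = 7L, nonwear_blocks = NULL) {
  sex <- match.arg(sex)
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            base_level > 0, tail_exponent < 0,
            wear_days >= 4, wear_days == round(wear_days),
            pubertal %in% c(0, 1))
  if (!is.null(nonwear_blocks)) {
    nb <- nonwear_blocks
    stopifnot(is.data.frame(nb),
              all(c("day", "start_min", "duration_min") %in% names(nb)))
    if (any(nb$duration_min <= 0)) stop("non-positive non-wear duration")
    if (any(nb$day < 1 | nb$day > wear_days) ||
        any(nb$start_min < 0 | nb$start_min > 1439)) {
      stop("non-wear block outside the recording window")
    }
    covered <- unlist(lapply(seq_len(nrow(nb)), function(i) {
      s <- (nb$day[i] - 1L) * 1440L + nb$start_min[i]
      s + seq_len(nb$duration_min[i]) - 1L
    }))
    if (anyDuplicated(covered)) stop("overlapping nonwear_blocks")
    if (max(covered) >= wear_days * 1440L) {
      stop("non-wear block extends past the recording window")
    }
  }
  structure(list(subject_id = subject_id, sex = sex, age = age,
                 stature = stature, pubertal = as.integer(pubertal),
                 base_level = base_level, tail_exponent = tail_exponent,
                 wear_days = as.integer(wear_days),
                 nonwear_blocks = nonwear_blocks),
            class = "subject_params")
}

# discrete power-law weights over band midpoints, zero below the floor band
active_band_weights <- function(tail_exponent, bands = default_bands(),
                                floor_band = 2L) {
  mids <- band_midpoints(bands)
  k <- length(mids)
  stopifnot(floor_band >= 1L, floor_band < k)
  w <- numeric(k)
  w[floor_band:k] <- mids[floor_band:k]^tail_exponent
  w / sum(w)
}

# mean acceleration of one active epoch (uniform within band; top band
# uniform over a phantom closed band, mean = its assigned midpoint)
.active_mean <- function(tail_exponent, bands, floor_band) {
  sum(active_band_weights(tail_exponent, bands, floor_band) * band_midpoints(bands))
}

.sedentary_mean <- function(bands) {
  (1 - .sedentary_zero_prob) * (bands[2] / 2)
}

# day-average activity probability implied by the target base_level
activity_probability <- function(params, bands = default_bands(),
                                 floor_band = 2L) {
  mu_sed <- .sedentary_mean(bands)
  mu_act <- .active_mean(params$tail_exponent, bands, floor_band)
  p <- (params$base_level - mu_sed) / (mu_act - mu_sed)
  if (p <= 0 || p > 1) {
    stop(sprintf("base_level %.3f unattainable with tail_exponent %.2f",
                 params$base_level, params$tail_exponent))
  }
  p
}

#' Analytic time-in-band fractions of the generating process
#'
#' Closed-form marginal fraction of time per acceleration band implied by a
#' subject's generating parameters, for records spanning whole days.  The
#' sedentary component occupies the first band; active time is spread over
#' the bands at and above `floor_band` with weight proportional to
#' `midpoint ^ tail_exponent`.  Serves as the exact oracle against which
#' empirical band fractions of generated series converge.
#'
#' @param params a [subject_params()].
#' @param bands band edges, see [default_bands()].
#' @param floor_band first band of the active power law (default 2; with
#'   `floor_band = 1` and `base_level` equal to the active-process mean the
#'   distribution is a pure power law across all bands).
#' @return an [intensity_distribution()] (fractions sum to 1).
#' @export
expected_band_fractions <- function(params, bands = default_bands(),
                                    floor_band = 2L) {
  p <- activity_probability(params, bands, floor_band)
  frac <- p * active_band_weights(params$tail_exponent, bands, floor_band)
  frac[1] <- frac[1] + (1 - p)
  out <- data.frame(lower = bands[-length(bands)], upper = bands[-1],
                    midpoint = band_midpoints(bands), fraction = frac)
  class(out) <- c("intensity_distribution", "data.frame")
  out
}

#' Expected MVPA of the generating process
#'
#' Closed-form expected minutes/day at or above `met_threshold` METs implied
#' by a subject's parameters, given the linear MET channel
#' `METs = 1 + 2 * acceleration`.
#'
#' @inheritParams expected_band_fractions
#' @param met_threshold METs defining moderate intensity.
#' @return expected MVPA in min/day.
#' @export
expected_mvpa <- function(params, bands = default_bands(), floor_band = 2L,
                          met_threshold = 4) {
  a_star <- (met_threshold - 1) / .met_slope
  p <- activity_probability(params, bands, floor_band)
  w <- active_band_weights(params$tail_exponent, bands, floor_band)
  lower <- bands[-length(bands)]
  upper <- bands[-1]
  width <- upper - lower
  width[is.infinite(width)] <- 2 * (lower[length(lower)] - lower[length(lower) - 1L])
  over <- pmin(pmax((lower + width - a_star) / width, 0), 1)
  1440 * p * sum(w * over)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate one subject's epoch series
#'
#' Simulates a contiguous 60-s epoch record over `wear_days` whole days.  The
#' window is anchored so the record always includes one full weekend (it ends
#' on a Sunday).  Heart rate is drawn around 120 bpm during wear; requested
#' non-wear blocks get zero counts and a zero (non-physiological) heart rate
#' so the downstream detector can recover them exactly.
#'
#' @param params a [subject_params()].
#' @param seed integer seed; the same seed reproduces the series bit for bit.
#' @param bands,floor_band band grid of the generating process.
#' @return an [epoch_series()].
#' @export
generate_subject_series <- function(params, seed, bands = default_bands(),
                                    floor_band = 2L) {
  stopifnot(inherits(params, "subject_params"))
  d <- params$wear_days
  n <- d * 1440L
  # end on the Sunday of a fixed reference weekend
  start_date <- as.Date("2021-06-06") - (d - 1L)
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  ts <- t0 + 60 * (seq_len(n) - 1)
  mod <- minute_of_day(ts)
  shape <- diurnal_shape(0:1439)
  p_bar <- activity_probability(params, bands, floor_band)
  p_t <- p_bar * shape[mod + 1L] / mean(shape)
  if (any(p_t > 1)) stop("base_level too high for the diurnal modulation")
  w <- active_band_weights(params$tail_exponent, bands, floor_band)
  lower <- bands[-length(bands)]
  width <- diff(bands)
  width[is.infinite(width)] <- 2 * (lower[length(lower)] - lower[length(lower) - 1L])
  with_seed(seed, {
    active <- stats::runif(n) < p_t
    band <- sample.int(length(w), n, replace = TRUE, prob = w)
    acc <- lower[band] + stats::runif(n) * width[band]
    sed_zero <- stats::runif(n) < .sedentary_zero_prob
    acc_sed <- ifelse(sed_zero, 0, stats::runif(n) * bands[2])
    acc <- ifelse(active, acc, acc_sed)
    counts <- pmax(0L, as.integer(round(acc / 0.003)))
    hr <- round(stats::rnorm(n, 120, 15))
    nb <- params$nonwear_blocks
    if (!is.null(nb)) {
      for (i in seq_len(nrow(nb))) {
        idx <- (nb$day[i] - 1L) * 1440L + nb$start_min[i] +
          seq_len(nb$duration_min[i])
        counts[idx] <- 0L
        hr[idx] <- 0
      }
    }
    met <- 1 + .met_slope * counts_to_acceleration(counts)
    epoch_series(params$subject_id, ts, counts, hr, met)
  })
}

#' Ground-truth outcome coefficients
#'
#' Linear-model coefficients used to build body-composition outcomes (kg)
#' from a subject's true activity metrics and covariates:
#' `outcome = intercept + volume * centred avg-acc + intensity * centred
#' gradient + interaction * product + age + stature + pubertal + wear_time
#' + Normal(0, sigma)`, with the activity metrics centred on the sex-stratum
#' mean.  Values are invented but scaled so simulated cohorts resemble
#' 9-11-year-olds (TBLH BMC ~0.9 kg, lean ~22 kg, fat ~7 kg).
#'
#' @param sigma_scale multiplies every noise SD (0 gives noise-free outcomes
#'   and exact coefficient recovery).
#' @return named list of per-outcome coefficient lists, class
#'   `outcome_coefficients`.
#' @export
default_outcome_coefficients <- function(sigma_scale = 1) {
  stopifnot(sigma_scale >= 0)
  co <- function(intercept, volume, intensity, interaction, age, stature,
                 pubertal, wear_time, sigma) {
    list(intercept = intercept, volume = volume, intensity = intensity,
         interaction = interaction, age = age, stature = stature,
         pubertal = pubertal, wear_time = wear_time,
         sigma = sigma * sigma_scale)
  }
  structure(list(
    tblh_bmc  = co(-1.10, 0.80,  0.15,  0.50, 0.030, 0.012, 0.040, 2e-4, 0.08),
    lean_mass = co(-1.00, 8.00,  1.20,  3.00, 0.500, 0.120, 0.800, 1e-3, 1.50),
    fat_mass  = co( 0.80, -15.0, -2.00, -5.00, 0.300, 0.020, 1.000, 0,    2.00)
  ), class = "outcome_coefficients")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic cohort
#'
#' Draws subject parameters from sex-specific distributions matching a
#' childhood cohort aged 9-11 (average-acceleration 0.19 (SD 0.058) m/s2 in
#' females and 0.22 (0.070) in males; intensity-gradients centred on -1.69
#' and -1.65), stores each subject's true activity metrics, and builds
#' body-composition outcomes from a known linear model on the centred true
#' metrics.  Epoch data are not materialised here; [subject_series()]
#' regenerates any subject's series reproducibly from the stored per-subject
#' seed.
#'
#' @param n_female,n_male stratum sizes (either may be 0).
#' @param coeffs an `outcome_coefficients` object.
#' @param seed master seed; everything downstream derives from it.
#' @return object of class `pa_cohort`: list with `table` (one row per
#'   subject: covariates, true exposures, outcomes), `subjects` (generating
#'   parameters incl. per-subject seeds), `coeffs` and `seed`.
#' @export
generate_cohort <- function(n_female, n_male,
                            coeffs = default_outcome_coefficients(),
                            seed = 1L) {
  stopifnot(n_female >= 0, n_male >= 0, n_female + n_male > 0,
            inherits(coeffs, "outcome_coefficients"))
  n <- n_female + n_male
  with_seed(seed, {
    sex <- rep(c("female", "male"), c(n_female, n_male))
    f <- sex == "female"
    subj <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      sex = sex,
      age = rtrunc_norm(n, 9.75, 0.45, 8.8, 11),
      stature = rtrunc_norm(n, 140.8, 6.1, 120, 165),
      pubertal = stats::rbinom(n, 1, ifelse(f, 0.35, 0.13)),
      base_level = rtrunc_norm(n, ifelse(f, 0.19, 0.22),
                               ifelse(f, 0.0579, 0.0696), 0.07, 0.42),
      tail_exponent = rtrunc_norm(n, ifelse(f, -1.51, -1.49),
                                  ifelse(f, 0.22, 0.29), -2.4, -1.05),
      wear_days = sample(4:9, n, replace = TRUE,
                         prob = c(0.1, 0.15, 0.25, 0.25, 0.15, 0.1)),
      series_seed = sample.int(.Machine$integer.max, n)
    )
    subj$wear_time <- subj$wear_days * 24  # continuous wear, no gaps
    truth <- lapply(seq_len(n), function(i) {
      p <- subject_params(subj$subject_id[i], subj$sex[i], subj$age[i],
                          subj$stature[i], subj$pubertal[i],
                          subj$base_level[i], subj$tail_exponent[i],
                          subj$wear_days[i])
      c(avg_acc = subj$base_level[i],
        intensity_gradient = fit_intensity_gradient(expected_band_fractions(p))$b1,
        mvpa = expected_mvpa(p))
    })
    truth <- do.call(rbind, truth)
    tab <- cbind(subj[c("subject_id", "sex", "age", "stature", "pubertal",
                        "wear_time")], as.data.frame(truth))
    # centre true exposures on the sex-stratum mean, as the analysis does
    cv <- stats::ave(tab$avg_acc, tab$sex, FUN = function(x) x - mean(x))
    ci <- stats::ave(tab$intensity_gradient, tab$sex, FUN = function(x) x - mean(x))
    for (out in names(coeffs)) {
      b <- coeffs[[out]]
      tab[[out]] <- b$intercept + b$volume * cv + b$intensity * ci +
        b$interaction * cv * ci + b$age * tab$age + b$stature * tab$stature +
        b$pubertal * tab$pubertal + b$wear_time * tab$wear_time +
        stats::rnorm(n, 0, b$sigma)
    }
    structure(list(table = tab, subjects = subj, coeffs = coeffs, seed = seed),
              class = "pa_cohort")
  })
}

#' @export
print.pa_cohort <- function(x, ...) {
  cat(sprintf("<pa_cohort> %d subjects (%d female, %d male), seed %d\n",
              nrow(x$table), sum(x$table$sex == "female"),
              sum(x$table$sex == "male"), x$seed))
  invisible(x)
}

#' Regenerate one cohort subject's epoch series
#'
#' @param cohort a [generate_cohort()] result.
#' @param subject_id id present in the cohort.
#' @param ... passed to [generate_subject_series()].
#' @return an [epoch_series()], identical on every call.
#' @export
subject_series <- function(cohort, subject_id, ...) {
  stopifnot(inherits(cohort, "pa_cohort"))
  i <- match(subject_id, cohort$subjects$subject_id)
  if (is.na(i)) stop("unknown subject_id: ", subject_id)
  s <- cohort$subjects
  p <- subject_params(s$subject_id[i], s$sex[i], s$age[i], s$stature[i],
                      s$pubertal[i], s$base_level[i], s$tail_exponent[i],
                      s$wear_days[i])
  generate_subject_series(p, seed = s$series_seed[i], ...)
}
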