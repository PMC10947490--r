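test_that("subject parameters are validated", {
  expect_error(subject_params("a", base_level = -0.1), "base_level")
  expect_error(subject_params("a", tail_exponent = 0.5), "tail_exponent")
  expect_error(subject_params("a", wear_days = 3), "wear_days")
  bad <- data.frame(day = c(1, 1), start_min = c(100, 150), duration_min = c(100, 50))
  expect_error(subject_params("a", nonwear_blocks = bad), "overlapping")
  neg <- data.frame(day = 1, start_min = 100, duration_min = 0)
  expect_error(subject_params("a", nonwear_blocks = neg), "non-positive")
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  p <- subject_params("s", wear_days = 4)
  set.seed(99); before <- runif(1); set.seed(99)
  s1 <- generate_subject_series(p, seed = 5)
  expect_identical(runif(1), before)  # RNG stream untouched
  s2 <- generate_subject_series(p, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1$counts, generate_subject_series(p, seed = 6)$counts))

  c1 <- generate_cohort(5, 5, seed = 12)
  c2 <- generate_cohort(5, 5, seed = 12)
  expect_identical(c1$table, c2$table)
  expect_identical(subject_series(c1, "S0003"), subject_series(c2, "S0003"))
})

test_that("a gap-free record has no detected non-wear and spans a weekend", {
  p <- subject_params("s", wear_days = 4)
  s <- generate_subject_series(p, seed = 2)
  expect_equal(nrow(s), 4 * 1440)
  m <- detect_nonwear(s)
  expect_true(all(m$wear))
  days <- unique(format(s$timestamp, "%u"))
  expect_true(all(c("6", "7") %in% days))  # full weekend included
  expect_identical(s$acceleration, s$counts * 0.003)
  # MET channel is monotone in acceleration
  expect_true(all(diff(s$met_estimate[order(s$acceleration)]) >= 0))
})

test_that("inserted non-wear blocks are recovered exactly by the detector", {
  nb <- data.frame(day = c(2, 3), start_min = c(600, 100),
                   duration_min = c(120, 95))
  p <- subject_params("s", wear_days = 5, nonwear_blocks = nb)
  s <- generate_subject_series(p, seed = 31)
  m <- detect_nonwear(s)
  expect_equal(nrow(m$intervals), 2L)
  expect_equal(sort(m$intervals$minutes), c(95, 120))
  expect_equal(sum(!m$wear), 215)

  # a 90-min block is not recoverable (rule is strictly > 90)
  nb90 <- data.frame(day = 2, start_min = 600, duration_min = 90)
  p90 <- subject_params("s", wear_days = 5, nonwear_blocks = nb90)
  m90 <- detect_nonwear(generate_subject_series(p90, seed = 31))
  expect_equal(nrow(m90$intervals), 0L)
})

test_that("analytic band fractions sum to 1 and follow the power law above the floor", {
  p <- subject_params("s", base_level = 0.2, tail_exponent = -1.5)
  d <- expected_band_fractions(p)
  expect_equal(sum(d$fraction), 1, tolerance = 1e-12)
  expect_true(all(d$fraction >= 0))
  ratio <- d$fraction[3:25] / d$fraction[2:24]
  expect_equal(ratio, (d$midpoint[3:25] / d$midpoint[2:24])^-1.5, tolerance = 1e-12)

  # heavier tail (-1.2) decays more slowly band-over-band than -1.54
  d12 <- expected_band_fractions(subject_params("s", tail_exponent = -1.2))
  d154 <- expected_band_fractions(subject_params("s", tail_exponent = -1.54))
  r12 <- d12$fraction[3:25] / d12$fraction[2:24]
  r154 <- d154$fraction[3:25] / d154$fraction[2:24]
  expect_true(all(r12 > r154))
  # and yields the higher (less negative) fitted gradient
  expect_gt(fit_intensity_gradient(d12)$b1, fit_intensity_gradient(d154)$b1)
})

test_that("a pure power-law configuration is fitted back exactly", {
  mids <- band_midpoints(default_bands())
  w <- mids^-1.5 / sum(mids^-1.5)
  mu <- sum(w * mids)  # active-process mean when the floor is band 1
  p <- subject_params("s", base_level = mu, tail_exponent = -1.5)
  d <- expected_band_fractions(p, floor_band = 1L)
  fit <- fit_intensity_gradient(d)
  expect_equal(fit$b1, -1.5, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("empirical band fractions converge to the analytic oracle", {
  p <- subject_params("s", base_level = 0.21, tail_exponent = -1.6,
                      wear_days = 60)
  s <- generate_subject_series(p, seed = 71)
  m <- detect_nonwear(s)
  d_emp <- intensity_distribution(s, m, diurnal_weights(s, m))
  d_exp <- expected_band_fractions(p)
  tv <- 0.5 * sum(abs(d_emp$fraction - d_exp$fraction))
  expect_lt(tv, 0.02)
  # average acceleration lands on the target base level
  expect_equal(average_acceleration(s, m, diurnal_weights(s, m)), 0.21,
               tolerance = 0.01)
})

test_that("generated MVPA matches its binomial expectation", {
  p <- subject_params("s", base_level = 0.2, tail_exponent = -1.5,
                      wear_days = 20)
  s <- generate_subject_series(p, seed = 13)
  m <- detect_nonwear(s)
  w <- diurnal_weights(s, m)
  expect_equal(mvpa_minutes(s, m, w), expected_mvpa(p), tolerance = 5)
})

test_that("cohort tables carry both strata with outcomes from the stated model", {
  co <- generate_cohort(8, 12, seed = 4)
  expect_equal(table(co$table$sex)[["female"]], 8)
  expect_equal(table(co$table$sex)[["male"]], 12)
  expect_false(anyNA(co$table))
  expect_true(all(co$table$avg_acc > 0))
  expect_true(all(co$table$intensity_gradient < 0))

  males <- generate_cohort(0, 10, seed = 4)
  expect_equal(nrow(males$table), 10)
  expect_error(fit_model_sequence(males, "tblh_bmc", sex = "female"),
               "empty stratum")
})

test_that("noise-free outcomes return the generating coefficients exactly", {
  co <- generate_cohort(40, 40, coeffs = default_outcome_coefficients(0),
                        seed = 8)
  for (sx in c("female", "male")) {
    # models 4-6 are rank-deficient by construction here: noise-free lean
    # and fat outcomes are exact linear combinations of the model-3 terms
    fit <- suppressWarnings(  # summary.lm flags the (intended) perfect fit
      fit_model_sequence(co, "tblh_bmc", "volume_intensity", sx, models = "3")
    )
    m3 <- fit$results
    truth <- co$coeffs$tblh_bmc
    got <- setNames(m3$beta, m3$term)
    expect_equal(got[["avg_acc"]], truth$volume, tolerance = 1e-8)
    expect_equal(got[["intensity_gradient"]], truth$intensity, tolerance = 1e-8)
    expect_equal(got[["avg_acc:intensity_gradient"]], truth$interaction,
                 tolerance = 1e-8)
    expect_equal(got[["age"]], truth$age, tolerance = 1e-8)
    expect_equal(got[["wear_time"]], truth$wear_time, tolerance = 1e-8)
  }
})

test_that("cohort metric scales resemble the target population", {
  co <- generate_cohort(250, 250, seed = 42)
  f <- co$table[co$table$sex == "female", ]
  m <- co$table[co$table$sex == "male", ]
  expect_lt(abs(mean(f$avg_acc) - 0.19), 0.02)
  expect_lt(abs(mean(m$avg_acc) - 0.22), 0.02)
  expect_lt(abs(mean(f$intensity_gradient) - -1.69), 0.08)
  expect_lt(abs(mean(m$intensity_gradient) - -1.65), 0.08)
  expect_gt(mean(m$mvpa), mean(f$mvpa))
})

test_that("recovered metrics track the generating parameters (7 days, n = 200)", {
  set.seed(55)
  n <- 200
  base <- runif(n, 0.12, 0.3)
  tail <- runif(n, -2.1, -1.2)
  truth <- t(vapply(seq_len(n), function(i) {
    p <- subject_params(sprintf("r%03d", i), base_level = base[i],
                        tail_exponent = tail[i], wear_days = 7)
    prof <- subject_profile(generate_subject_series(p, seed = 1000 + i))
    c(avg = prof$average_acceleration, ig = prof$ig$b1,
      ig_true = fit_intensity_gradient(expected_band_fractions(p))$b1)
  }, numeric(3)))
  expect_gt(cor(truth[, "avg"], base), 0.95)
  expect_gt(cor(truth[, "ig"], truth[, "ig_true"]), 0.95)
})
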