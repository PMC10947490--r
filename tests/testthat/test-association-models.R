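test_that("mean centring zeroes the mean and stores the centre", {
  x <- mean_centre(c(1, 2, 3))
  expect_equal(as.numeric(x), c(-1, 0, 1))
  expect_equal(attr(x, "centre"), 2)
  expect_equal(mean(x), 0)
  expect_error(mean_centre(numeric(0)), "empty stratum")
})

test_that("centring leaves every slope unchanged (only the intercept moves)", {
  tab <- make_table(60, seed = 3)
  tab$y <- 0.5 * tab$avg_acc - 0.3 * tab$intensity_gradient +
    0.2 * tab$avg_acc * tab$intensity_gradient + rnorm(60, 0, 0.1)
  cen <- within(tab, {
    avg_acc <- as.numeric(mean_centre(avg_acc))
    intensity_gradient <- as.numeric(mean_centre(intensity_gradient))
  })
  # slopes of the simple (no-interaction) fits are invariant to centring
  raw2 <- lm(y ~ avg_acc + intensity_gradient, data = tab)
  cen2 <- lm(y ~ avg_acc + intensity_gradient, data = cen)
  expect_equal(coef(raw2)[-1], coef(cen2)[-1], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(coef(raw2)[1], coef(cen2)[1])))
})

test_that("the model sequence follows the adjustment scheme per outcome", {
  tab <- make_table(80, seed = 5)
  seq_bmc <- fit_model_sequence(tab, "tblh_bmc", "volume_intensity", "female")
  models <- unique(seq_bmc$results$model)
  expect_identical(models, as.character(1:6))

  term_set <- function(m) {
    unique(seq_bmc$results$term[seq_bmc$results$model == m])
  }
  expect_true(all(term_set("2") %in% term_set("3")))
  expect_true(all(term_set("3") %in% term_set("4")))
  expect_true(all(term_set("3") %in% term_set("5")))
  expect_true(all(union(term_set("4"), term_set("5")) %in% term_set("6")))
  expect_true("lean_mass" %in% term_set("4"))
  expect_true("fat_mass" %in% term_set("5"))
  expect_true(all(c("lean_mass", "fat_mass") %in% term_set("6")))
  base_cov <- c("age", "stature", "pubertal", "wear_time")
  for (m in models) expect_true(all(base_cov %in% term_set(m)))

  # lean: 1-3 plus fat-adjusted final model 5; never adjusts for itself
  seq_lean <- fit_model_sequence(tab, "lean_mass", "volume_intensity", "female")
  expect_identical(unique(seq_lean$results$model), c("1", "2", "3", "5"))
  expect_false("lean_mass" %in% seq_lean$results$term)
  expect_true("fat_mass" %in%
                seq_lean$results$term[seq_lean$results$model == "5"])

  # fat: 1-3 plus lean-adjusted final model 4
  seq_fat <- fit_model_sequence(tab, "fat_mass", "volume_intensity", "female")
  expect_identical(unique(seq_fat$results$model), c("1", "2", "3", "4"))
  expect_true("lean_mass" %in%
                seq_fat$results$term[seq_fat$results$model == "4"])

  # MVPA runs without alternate-metric or interaction steps
  seq_mvpa <- fit_model_sequence(tab, "tblh_bmc", "mvpa", "female")
  expect_identical(unique(seq_mvpa$results$model), c("1", "4", "5", "6"))
  expect_false(any(grepl("intensity_gradient", seq_mvpa$results$term)))
  expect_false(any(grepl(":", seq_mvpa$results$term)))
})

test_that("model results carry coherent CIs, p-values and n", {
  tab <- make_table(70, seed = 9)
  res <- fit_model_sequence(tab, "tblh_bmc", "volume_intensity", "female")$results
  expect_true(all(res$ci_lo <= res$beta & res$beta <= res$ci_hi))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$n == 70))
  # CIs and p-values agree with the t distribution: |t| at p = 0.05
  # boundary corresponds to a CI endpoint at zero
  crossing <- res$ci_lo < 0 & res$ci_hi > 0
  expect_true(all((res$p > 0.05) == crossing))
})

test_that("rank deficiency is reported with the collinear term", {
  tab <- make_table(50, seed = 2)
  tab$intensity_gradient <- tab$avg_acc  # perfectly collinear
  expect_error(fit_model_sequence(tab, "tblh_bmc", "volume_intensity", "female"),
               "collinear")
})

test_that("missing values in modelled columns are refused", {
  tab <- make_table(30, seed = 6)
  tab$avg_acc[4] <- NA
  expect_error(fit_model_sequence(tab, "tblh_bmc", "volume_intensity", "female"),
               "complete cases")
})

test_that("volume/intensity groups split at the sex means with >= as high", {
  tab <- make_table(3, seed = 1)
  tab$avg_acc <- c(1, 2, 3)             # subject 2 exactly at the mean
  tab$intensity_gradient <- c(-2, -1.7, -1.4)
  g <- stratify_groups(tab, "female")
  expect_equal(as.character(g[2]), "high-vol/high-int")
  expect_equal(as.character(g[1]), "low-vol/low-int")
  expect_equal(as.character(g[3]), "high-vol/high-int")

  tab2 <- make_table(5, seed = 1)
  tab2$avg_acc <- rep(0.2, 5)
  tab2$intensity_gradient <- rep(-1.7, 5)
  g2 <- stratify_groups(tab2, "female")
  expect_true(all(g2 == "high-vol/high-int"))

  tab3 <- make_table(101, seed = 14)
  g3 <- stratify_groups(tab3, "female")
  expect_equal(sum(table(g3)), 101)  # partition
})

test_that("group MX summaries report means, SEMs and standardized profiles", {
  set.seed(33)
  n <- 24
  mx <- data.frame(subject_id = sprintf("T%03d", 1:n),
                   M2 = runif(n, 3, 5), M60 = runif(n, 1, 2),
                   M480 = runif(n, 0.1, 0.5))
  assign <- factor(rep(c("low-vol/low-int", "high-vol/high-int"), each = 12),
                   levels = c("low-vol/low-int", "low-vol/high-int",
                              "high-vol/low-int", "high-vol/high-int"))
  names(assign) <- mx$subject_id
  s <- group_mx_summary(mx, assign, sex = "female")
  expect_equal(sort(unique(s$group)),
               sort(c("low-vol/low-int", "high-vol/high-int")))  # empties absent
  low <- s[s$group == "low-vol/low-int" & s$X == 2, ]
  expect_equal(low$raw_mean, mean(mx$M2[1:12]))
  expect_equal(low$raw_sem, sd(mx$M2[1:12]) / sqrt(12))
  expect_equal(low$std_mean, mean(mx$M2[1:12]) / mean(mx$M2))

  # single-subject group: SEM undefined, reported missing
  assign1 <- assign
  assign1[1] <- "low-vol/high-int"
  s1 <- group_mx_summary(mx, assign1, sex = "female")
  one <- s1[s1$group == "low-vol/high-int", ]
  expect_true(all(one$n == 1))
  expect_true(all(is.na(one$raw_sem)))
  expect_equal(one$raw_mean[one$X == 2], mx$M2[1])
})

test_that("generator-built group structure shows volume dominance at large X", {
  co <- generate_cohort(120, 0, seed = 19)
  g <- stratify_groups(co, "female")
  prof <- lapply(names(g)[1:60], function(id) {
    subject_profile(subject_series(co, id), require_valid = FALSE)
  })
  tabm <- metrics_table(prof)
  s <- group_mx_summary(tabm[c("subject_id", grep("^M", names(tabm), value = TRUE))],
                        droplevels(g[1:60]), sex = "female")
  hv <- s[grepl("high-vol", s$group) & s$X == 480, "raw_mean"]
  lv <- s[grepl("low-vol", s$group) & s$X == 480, "raw_mean"]
  expect_gt(min(hv), max(lv) * 0.8)
  expect_gt(mean(hv), mean(lv))
})
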