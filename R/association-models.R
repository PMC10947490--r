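#' Mean-centre a vector within a stratum
#'
#' Activity exposures are mean-centred before model entry; interaction terms
#' are products of the centred scores.  Centring changes the intercept and
#' the interpretation of lower-order terms at "average activity", not the
#' slopes.
#'
#' @param values numeric vector.
#' @return `values - mean(values)`, with the removed mean in attribute
#'   `"centre"`.
#' @export
mean_centre <- function(values) {
  if (length(values) == 0L || all(is.na(values))) stop("empty stratum")
  m <- mean(values, na.rm = TRUE)
  structure(values - m, centre = m)
}

# covariates common to every model
.base_covariates <- c("age", "stature", "pubertal", "wear_time")

# model index -> extra body-composition adjustments
.body_comp_terms <- list(`4` = "lean_mass", `5` = "fat_mass",
                         `6` = c("lean_mass", "fat_mass"))

build_model_plan <- function(outcome, exposure_set) {
  bmc <- !(outcome %in% c("lean_mass", "fat_mass"))
  final <- if (bmc) 4:6 else if (outcome == "lean_mass") 5L else 4L
  if (exposure_set == "volume_intensity") {
    plan <- list(
      list(model = "1", exposures = "avg_acc"),
      list(model = "1", exposures = "intensity_gradient"),
      list(model = "2", exposures = c("avg_acc", "intensity_gradient")),
      list(model = "3", exposures = c("avg_acc", "intensity_gradient",
                                      "avg_acc:intensity_gradient"))
    )
    for (k in final) {
      plan <- c(plan, list(list(
        model = as.character(k),
        exposures = c("avg_acc", "intensity_gradient",
                      "avg_acc:intensity_gradient"),
        extra = setdiff(.body_comp_terms[[as.character(k)]], outcome))))
    }
  } else {
    plan <- list(list(model = "1", exposures = "mvpa"))
    for (k in final) {
      plan <- c(plan, list(list(
        model = as.character(k), exposures = "mvpa",
        extra = setdiff(.body_comp_terms[[as.character(k)]], outcome))))
    }
  }
  plan
}

fit_one_model <- function(dat, outcome, exposures, extra, model, sex, exposure_set) {
  terms <- c(exposures, .base_covariates, extra)
  fml <- stats::reformulate(terms, response = outcome)
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient model; collinear terms: ", paste(bad, collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  res <- data.frame(
    stratum = sex, outcome = outcome, exposure_set = exposure_set,
    model = model, term = rownames(cf),
    beta = cf[, "Estimate"], ci_lo = ci[, 1], ci_hi = ci[, 2],
    p = cf[, "Pr(>|t|)"], n = length(fit$residuals),
    row.names = NULL
  )
  structure(list(results = res, fit = fit), class = "pa_model")
}

#' Fit the sex-stratified model sequence
#'
#' Ordinary least squares within one sex stratum, following the sequential
#' adjustment scheme.  With the `volume_intensity` exposure set, Model 1
#' enters each activity metric alone (one fit per metric), Model 2 both
#' metrics together, Model 3 adds their interaction (product of centred
#' scores); the final models add body-composition adjustments -- Model 4
#' lean mass, Model 5 fat mass, Model 6 both.  Bone outcomes run models 1-6;
#' lean mass runs 1-3 plus the fat-adjusted Model 5; fat mass runs 1-3 plus
#' the lean-adjusted Model 4.  Every model adjusts for age, stature,
#' pubertal status and wear time.  With `exposure_set = "mvpa"` the same
#' scheme runs with MVPA as the single activity term and no
#' alternate-metric or interaction steps.  Activity exposures are
#' mean-centred within the stratum before entry; slopes are identical to the
#' uncentred fit.
#'
#' @param table cohort data frame with columns `sex`, `age`, `stature`,
#'   `pubertal`, `wear_time`, `avg_acc`, `intensity_gradient`, `mvpa` and the
#'   outcome columns (complete cases only; rows with missing modelled values
#'   are an error).
#' @param outcome outcome column, e.g. `"tblh_bmc"`, `"lean_mass"`,
#'   `"fat_mass"`.
#' @param exposure_set `"volume_intensity"` or `"mvpa"`.
#' @param sex stratum to fit, `"female"` or `"male"`.
#' @param models optional character vector restricting which model indices to
#'   fit (e.g. `"3"`); default fits the full sequence for the outcome.
#' @return object of class `pa_model_sequence`: list of `pa_model` fits plus
#'   a combined tidy `results` data frame (stratum, outcome, exposure_set,
#'   model, term, beta, ci_lo, ci_hi, p, n).
#' @export
fit_model_sequence <- function(table, outcome,
                               exposure_set = c("volume_intensity", "mvpa"),
                               sex = c("female", "male"), models = NULL) {
  exposure_set <- match.arg(exposure_set)
  sex <- match.arg(sex)
  if (inherits(table, "pa_cohort")) table <- table$table
  dat <- table[table$sex == sex, , drop = FALSE]
  if (nrow(dat) == 0L) stop("empty stratum: no ", sex, " subjects")
  modelled <- unique(c(outcome, .base_covariates, "avg_acc",
                       "intensity_gradient", "mvpa", "lean_mass", "fat_mass"))
  modelled <- intersect(modelled, names(dat))
  if (anyNA(dat[modelled])) {
    stop("missing values in modelled columns; supply complete cases")
  }
  for (v in c("avg_acc", "intensity_gradient", "mvpa")) {
    if (v %in% names(dat)) dat[[v]] <- as.numeric(mean_centre(dat[[v]]))
  }
  plan <- build_model_plan(outcome, exposure_set)
  if (!is.null(models)) {
    plan <- Filter(function(pl) pl$model %in% as.character(models), plan)
    if (length(plan) == 0L) stop("no such model index for this outcome")
  }
  fits <- lapply(plan, function(pl) {
    if (nrow(dat) <= length(c(pl$exposures, .base_covariates, pl$extra)) + 1L) {
      stop("stratum too small for model ", pl$model)
    }
    fit_one_model(dat, outcome, pl$exposures, pl$extra, pl$model, sex,
                  exposure_set)
  })
  results <- do.call(rbind, lapply(fits, `[[`, "results"))
  structure(list(fits = fits, results = results, outcome = outcome,
                 exposure_set = exposure_set, stratum = sex),
            class = "pa_model_sequence")
}

#' @export
print.pa_model_sequence <- function(x, digits = 3, ...) {
  cat(sprintf("<pa_model_sequence> %s ~ %s, %s stratum (n = %d)\n",
              x$outcome, x$exposure_set, x$stratum, x$results$n[1]))
  act <- x$results[x$results$term %in%
                     c("avg_acc", "intensity_gradient",
                       "avg_acc:intensity_gradient", "mvpa"), ]
  act$beta <- signif(act$beta, digits)
  act$ci <- sprintf("(%s to %s)", signif(act$ci_lo, digits), signif(act$ci_hi, digits))
  act$p <- signif(act$p, 2)
  print(act[c("model", "term", "beta", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.pa_model_sequence <- function(object, ...) object$results

#' @export
coef.pa_model_sequence <- function(object, model = NULL, ...) {
  r <- object$results
  if (!is.null(model)) r <- r[r$model == as.character(model), ]
  stats::setNames(r$beta, paste(r$model, r$term, sep = "/"))
}

#' Four volume-by-intensity groups
#'
#' Splits one sex stratum at the sex-specific means of average-acceleration
#' and intensity-gradient: below the mean is "low", at or above is "high".
#'
#' @param table cohort data frame (or `pa_cohort`).
#' @param sex stratum.
#' @return factor (levels `low-vol/low-int`, `low-vol/high-int`,
#'   `high-vol/low-int`, `high-vol/high-int`) named by subject id, with the
#'   two cut means in attribute `"means"`.
#' @export
stratify_groups <- function(table, sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (inherits(table, "pa_cohort")) table <- table$table
  dat <- table[table$sex == sex, , drop = FALSE]
  if (nrow(dat) == 0L) stop("empty stratum: no ", sex, " subjects")
  mv <- mean(dat$avg_acc)
  mi <- mean(dat$intensity_gradient)
  vol <- ifelse(dat$avg_acc < mv, "low-vol", "high-vol")
  int <- ifelse(dat$intensity_gradient < mi, "low-int", "high-int")
  g <- factor(paste(vol, int, sep = "/"),
              levels = c("low-vol/low-int", "low-vol/high-int",
                         "high-vol/low-int", "high-vol/high-int"))
  structure(stats::setNames(g, dat$subject_id), means = c(volume = mv, intensity = mi))
}

#' Group MX summaries for radar plots
#'
#' Mean and standard error of each MX metric per volume-by-intensity group,
#' raw and standardized by the sex-specific overall mean (see
#' [standardize_mx()]).  Groups of one subject have an undefined SEM
#' (reported `NA`); empty groups are absent from the output.
#'
#' @param mx_table data frame: one row per subject with `subject_id` and the
#'   MX columns (`M2`, `M5`, ...).
#' @param assignment group factor from [stratify_groups()], named by subject
#'   id.
#' @param sex label copied into the output.
#' @return data frame (sex, group, X, n, raw_mean, raw_sem, std_mean,
#'   std_sem), one row per group and X.
#' @export
group_mx_summary <- function(mx_table, assignment, sex = "") {
  mx_cols <- grep("^M[0-9]+$", names(mx_table), value = TRUE)
  stopifnot(length(mx_cols) > 0, "subject_id" %in% names(mx_table))
  idx <- match(names(assignment), mx_table$subject_id)
  if (anyNA(idx)) stop("assignment contains subjects missing from mx_table")
  dat <- mx_table[idx, , drop = FALSE]
  overall <- colMeans(dat[mx_cols])
  out <- list()
  for (g in levels(assignment)) {
    rows <- dat[assignment == g, mx_cols, drop = FALSE]
    n <- nrow(rows)
    if (n == 0L) next
    mu <- colMeans(rows)
    sem <- if (n > 1L) apply(rows, 2, stats::sd) / sqrt(n) else rep(NA_real_, length(mx_cols))
    out[[g]] <- data.frame(
      sex = sex, group = g, X = as.integer(sub("^M", "", mx_cols)), n = n,
      raw_mean = unname(mu), raw_sem = unname(sem),
      std_mean = unname(mu / overall), std_sem = unname(sem / overall),
      row.names = NULL
    )
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
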