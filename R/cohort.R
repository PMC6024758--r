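# Synthetic cohort generator. Emulates the joint structure the spot-to-24h
# analysis assumes: log-normal anthropometry and excretion, a spot sample
# sharing its day's dilution with the 24-h collection, and intra-individual
# log-normal noise — with hidden ground truth carried alongside so recovery
# can be verified.

#' Convert a coefficient of variation to a log-normal sdlog
#'
#' For a log-normal variable with multiplicative CV `cv`, the standard
#' deviation on the log scale is `sqrt(log(1 + cv^2))`.
#'
#' @param cv Coefficient of variation (>= 0).
#' @return The log-scale standard deviation.
#' @export
cv_to_sdlog <- function(cv) {
  if (any(cv < 0, na.rm = TRUE)) stop("CV must be non-negative", call. = FALSE)
  sqrt(log(1 + cv^2))
}

#' Log-normal sdlog matched to a median and interquartile range
#'
#' Solves IQR/median = 2 sinh(qnorm(0.75) sdlog) for sdlog, the log-scale
#' moment match used to set generator spreads from reported median (IQR)
#' summaries.
#'
#' @param median,iqr Median and interquartile range on the natural scale.
#' @return The log-scale standard deviation.
#' @export
sdlog_from_iqr <- function(median, iqr) {
  if (any(median <= 0) || any(iqr <= 0)) {
    stop("median and IQR must be positive", call. = FALSE)
  }
  asinh(iqr / (2 * median)) / stats::qnorm(0.75)
}

#' Configuration for the synthetic urine-biomarker cohort
#'
#' Defaults emulate the marginal structure of an older, mostly female South
#' African adult cohort: median age 52 y, 76% women, median spot UIC near
#' 130 ug/L, median 24-h volume 1400 mL, median measured 24-h iodine
#' excretion 124 ug/day, and intra-individual CVs of 38% for spot UIC and
#' 32% for 24-h UIE. Positive quantities are log-normal; all noise terms
#' have median 1 so configured medians are matched by construction.
#'
#' The spot sample shares a latent dilution factor with its day's urine
#' (`dilution_median`, `dilution_cv`), which is what keeps the spot
#' iodine-to-creatinine ratio partially informative about 24-h excretion;
#' `intake_day_cv` is the day-to-day deviation of the spot sample's iodine
#' content from the person's usual excretion, the dominant term weakening
#' the spot-to-24h rank correlation toward the ~0.4 seen in field data.
#'
#' @param n Number of participants (> 0).
#' @param seed Integer seed; fully determines the cohort.
#' @param frac_female Proportion of women.
#' @param age_median,age_iqr,age_range Age distribution (years): log-normal
#'   matched to median/IQR, truncated to `age_range`.
#' @param height_median_female,height_median_male Median heights (cm).
#' @param height_sdlog Log-scale sd of height.
#' @param bmi_median_female,bmi_median_male Median BMI (kg/m^2) by sex.
#' @param bmi_sdlog Log-scale sd of BMI.
#' @param muie_median Median usual 24-h urinary iodine excretion (ug/day).
#' @param muie_sdlog Log-scale sd of usual 24-h iodine excretion
#'   (between-person).
#' @param day24_cv Intra-individual CV of the measured 24-h UIE around the
#'   usual value.
#' @param volume_median Median 24-h urine volume (mL).
#' @param volume_sdlog Log-scale sd of 24-h volume.
#' @param spot_cv Intra-individual (measurement) CV of spot UIC.
#' @param intake_day_cv Day-to-day CV of the spot sample's iodine content
#'   relative to usual excretion.
#' @param cr_biol_cv CV of true daily creatinine around its anthropometric
#'   baseline.
#' @param cr24_meas_cv Measurement CV of the 24-h creatinine assay.
#' @param spot_cr_cv Measurement CV of the spot creatinine assay.
#' @param dilution_median Median concentration factor of the spot void
#'   relative to the day's average urine (> 1: morning voids are more
#'   concentrated).
#' @param dilution_cv CV of the spot dilution factor.
#' @param spot_cr_bias Multiplicative bias applied to the spot creatinine
#'   concentration (1 = unbiased); useful for bias-recovery experiments.
#' @param frac_black Probability of the ethnicity indicator being 1.
#' @param frac_missing_ethnicity Probability the ethnicity indicator is
#'   missing (missing completely at random).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n = 457,
                          seed = 1L,
                          frac_female = 0.76,
                          age_median = 52, age_iqr = 24,
                          age_range = c(18, 90),
                          height_median_female = 160,
                          height_median_male = 170,
                          height_sdlog = 0.04,
                          bmi_median_female = 30.3,
                          bmi_median_male = 25.7,
                          bmi_sdlog = 0.23,
                          muie_median = 124,
                          muie_sdlog = 0.55,
                          day24_cv = 0.32,
                          volume_median = 1400,
                          volume_sdlog = sdlog_from_iqr(1400, 1390),
                          spot_cv = 0.38,
                          intake_day_cv = 0.99,
                          cr_biol_cv = 0.25,
                          cr24_meas_cv = 0.10,
                          spot_cr_cv = 0.15,
                          dilution_median = 1.47,
                          dilution_cv = 0.35,
                          spot_cr_bias = 1,
                          frac_black = 0.73,
                          frac_missing_ethnicity = 26 / 455) {
  cfg <- as.list(environment())
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  for (nm in c("frac_female", "frac_black", "frac_missing_ethnicity")) {
    p <- cfg[[nm]]
    if (p < 0 || p > 1) stop("`", nm, "` must be in [0, 1]", call. = FALSE)
  }
  for (nm in c("age_median", "height_median_female", "height_median_male",
               "bmi_median_female", "bmi_median_male", "muie_median",
               "volume_median", "dilution_median", "spot_cr_bias")) {
    if (cfg[[nm]] <= 0) stop("`", nm, "` must be positive", call. = FALSE)
  }
  for (nm in c("day24_cv", "spot_cv", "intake_day_cv", "cr_biol_cv",
               "cr24_meas_cv", "spot_cr_cv", "dilution_cv",
               "height_sdlog", "bmi_sdlog", "muie_sdlog", "volume_sdlog")) {
    if (cfg[[nm]] < 0) stop("`", nm, "` must be non-negative", call. = FALSE)
  }
  if (length(cfg$age_range) != 2 || cfg$age_range[1] <= 0 ||
      diff(cfg$age_range) <= 0) {
    stop("`age_range` must be an increasing positive pair", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' Noise-free cohort configuration
#'
#' Convenience wrapper: all intra-individual noise terms set to zero and
#' the spot dilution factor fixed at 1, so every spot-derived quantity is a
#' deterministic function of the hidden truth. In this regime PrUIE built
#' from the true creatinine recovers measured UIE exactly, record by record.
#'
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
cohort_config_noise_free <- function(...) {
  cohort_config(day24_cv = 0, spot_cv = 0, intake_day_cv = 0,
                cr_biol_cv = 0, cr24_meas_cv = 0, spot_cr_cv = 0,
                dilution_median = 1, dilution_cv = 0, ...)
}

rlnorm_median <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

# median-1 multiplicative noise with a given CV
rnoise <- function(n, cv) {
  stats::rlnorm(n, meanlog = 0, sdlog = cv_to_sdlog(cv))
}

# truncated log-normal via inverse-CDF restriction (keeps determinism and
# avoids rejection loops)
rlnorm_trunc <- function(n, median, sdlog, lower, upper) {
  lo <- stats::plnorm(lower, log(median), sdlog)
  hi <- stats::plnorm(upper, log(median), sdlog)
  stats::qlnorm(stats::runif(n, lo, hi), log(median), sdlog)
}

#' Generate a synthetic urine-biomarker cohort
#'
#' Per participant: sex, age, height and BMI (hence weight) are drawn from
#' sex-specific log-normals; a usual 24-h iodine excretion (the hidden
#' truth) is drawn log-normal; the measured 24-h excretion is the truth
#' times a median-1 log-normal day factor; the 24-h iodine concentration is
#' excretion over volume; the true daily creatinine is a Kawasaki
#' anthropometric baseline times biological noise; and the spot sample's
#' iodine and creatinine concentrations both divide by the day's volume and
#' share one latent dilution factor, with their own intake-day and assay
#' noise on top.
#'
#' @param cfg A [cohort_config()].
#' @return A tibble with one row per participant: the pipeline-facing
#'   columns `id`, `sex`, `age_y`, `weight_kg`, `height_cm`, `bmi`,
#'   `ethnicity_black`, `spot_uic_ugL`, `spot_ucr_mgdL`, `vol24_mL`,
#'   `iodine24_ugL`, `ucr24_mmol`, plus hidden ground truth
#'   `true_uie_ugday`, `true_cr_mgday`, `true_intake_ugday` (not written to
#'   the pipeline CSV by [write_cohort()] unless asked). The generating
#'   config is attached as attribute `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 50, seed = 7))
#' median(cohort$spot_uic_ugL)
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n

  sex <- ifelse(stats::runif(n) < cfg$frac_female, "female", "male")
  age <- rlnorm_trunc(n, cfg$age_median, sdlog_from_iqr(cfg$age_median, cfg$age_iqr),
                      cfg$age_range[1], cfg$age_range[2])
  height <- rlnorm_median(n, ifelse(sex == "female",
                                    cfg$height_median_female,
                                    cfg$height_median_male),
                          cfg$height_sdlog)
  bmi <- rlnorm_median(n, ifelse(sex == "female",
                                 cfg$bmi_median_female,
                                 cfg$bmi_median_male),
                       cfg$bmi_sdlog)
  weight <- bmi * (height / 100)^2

  black <- stats::rbinom(n, 1, cfg$frac_black)
  black[stats::runif(n) < cfg$frac_missing_ethnicity] <- NA_integer_

  true_uie <- rlnorm_median(n, cfg$muie_median, cfg$muie_sdlog)
  true_cr <- predict_creatinine_kawasaki(sex, age, weight, height) *
    rnoise(n, cfg$cr_biol_cv)

  vol_ml <- rlnorm_median(n, cfg$volume_median, cfg$volume_sdlog)
  vol_l <- vol_ml / 1000

  muie_obs <- true_uie * rnoise(n, cfg$day24_cv)
  iodine24 <- muie_obs / vol_l
  ucr24_mmol <- creatinine_mg_to_mmol(true_cr) * rnoise(n, cfg$cr24_meas_cv)

  dilution <- cfg$dilution_median * rnoise(n, cfg$dilution_cv)
  spot_uic <- true_uie * rnoise(n, cfg$intake_day_cv) / vol_l * dilution *
    rnoise(n, cfg$spot_cv)
  # mg/day over mL/day is mg/mL = 100 mg/dL
  spot_ucr_mgdl <- true_cr / vol_ml * 100 * dilution *
    rnoise(n, cfg$spot_cr_cv) * cfg$spot_cr_bias

  out <- tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    sex = sex,
    age_y = age,
    weight_kg = weight,
    height_cm = height,
    bmi = bmi,
    ethnicity_black = black,
    spot_uic_ugL = spot_uic,
    spot_ucr_mgdL = spot_ucr_mgdl,
    vol24_mL = vol_ml,
    iodine24_ugL = iodine24,
    ucr24_mmol = ucr24_mmol,
    true_uie_ugday = true_uie,
    true_cr_mgday = true_cr,
    true_intake_ugday = intake_from_excretion(true_uie)
  )
  attr(out, "config") <- cfg
  out
}

TRUTH_COLUMNS <- c("true_uie_ugday", "true_cr_mgday", "true_intake_ugday")

#' Write a synthetic cohort to CSV
#'
#' The pipeline-facing CSV carries only the observable column dictionary;
#' the hidden ground truth goes to a separate CSV keyed by `id` when
#' `truth_path` is given. Missing values are written as empty cells.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param path Output path for the observable cohort CSV.
#' @param truth_path Optional output path for the ground-truth CSV.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  obs <- cohort[, setdiff(names(cohort), TRUTH_COLUMNS)]
  utils::write.csv(obs, path, row.names = FALSE, na = "")
  if (!is.null(truth_path)) {
    truth <- cohort[, c("id", intersect(TRUTH_COLUMNS, names(cohort)))]
    utils::write.csv(truth, truth_path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a cohort CSV
#'
#' Reads a delimited cohort file using the documented column dictionary
#' (empty cells become `NA`) and validates that the required columns are
#' present.
#'
#' @param path Path to the cohort CSV.
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"),
                        stringsAsFactors = FALSE)
  required <- c("id", "sex", "age_y", "weight_kg", "height_cm",
                "spot_uic_ugL", "spot_ucr_mgdL", "vol24_mL",
                "iodine24_ugL", "ucr24_mmol")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Ground-truth recovery metrics for a synthetic cohort
#'
#' Runs the spot-to-24h pipeline on a generated cohort and compares its
#' outputs with the hidden truth: the estimated percentage below the EAR
#' (from measured 24-h excretion) against the true P(intake < EAR), the
#' Spearman correlation between predicted and measured excretion, and the
#' Bland-Altman geometric-mean ratio.
#'
#' @param cohort A [generate_cohort()] tibble (must carry the truth
#'   columns).
#' @param equation Creatinine equation for the prediction:
#'   `"tanaka"`, `"kawasaki"` or `"mage"`.
#' @param use_true_creatinine If `TRUE`, scale the spot ratio by the hidden
#'   true creatinine instead of an equation estimate (isolates the
#'   spot-sampling noise from the equation error).
#' @param ear EAR threshold in ug/day.
#' @param bioavailability Fraction of dietary iodine absorbed.
#' @return A list: `n`, `pct_below_ear_est`, `pct_below_ear_true`,
#'   `spearman_rho`, `mean_ratio_pct`.
#' @export
recovery_report <- function(cohort, equation = "kawasaki",
                            use_true_creatinine = FALSE,
                            ear = EAR_IODINE_UG_DAY,
                            bioavailability = 0.92) {
  if (!all(TRUTH_COLUMNS %in% names(cohort))) {
    stop("`cohort` must carry the ground-truth columns", call. = FALSE)
  }
  prcr <- if (use_true_creatinine) {
    cohort$true_cr_mgday
  } else {
    switch(equation,
      tanaka = predict_creatinine_tanaka(cohort$age_y, cohort$weight_kg,
                                         cohort$height_cm),
      kawasaki = predict_creatinine_kawasaki(cohort$sex, cohort$age_y,
                                             cohort$weight_kg,
                                             cohort$height_cm),
      mage = predict_creatinine_mage(cohort$sex, cohort$age_y,
                                     cohort$weight_kg, cohort$height_cm,
                                     cohort$ethnicity_black, cohort$bmi),
      stop("unknown equation: ", equation, call. = FALSE)
    )
  }
  pruie <- predict_uie(cohort$spot_uic_ugL, cohort$spot_ucr_mgdL, prcr)
  muie <- measured_uie(cohort$vol24_mL, cohort$iodine24_ugL)
  keep <- !is.na(pruie)
  est_classes <- classify_ear(
    intake_from_excretion(muie, bioavailability), ear
  )
  ba <- bland_altman_log(pruie[keep], muie[keep])
  list(
    n = sum(keep),
    pct_below_ear_est = pct_below_ear(est_classes),
    pct_below_ear_true = 100 * mean(cohort$true_intake_ugday < ear),
    spearman_rho = stats::cor(pruie[keep], muie[keep], method = "spearman"),
    mean_ratio_pct = ba$mean_ratio_pct
  )
}
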