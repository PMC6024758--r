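# End-to-end orchestration: completeness screening, per-equation derivation,
# adequacy classification, agreement statistics and report/export writing.

EQUATIONS <- c("tanaka", "kawasaki", "mage")

#' Derive per-participant excretion and intake quantities
#'
#' Adds to a cohort table: the completeness flag for the 24-h collection,
#' predicted 24-h creatinine (mg/day) per requested equation, predicted
#' 24-h iodine excretion (ug/day) per equation, measured 24-h iodine
#' excretion, intake estimates (EAR cut-point convention, excretion divided
#' by bioavailability) for the measured and each predicted excretion, and
#' the IOM weight-based intake. Rows are not filtered here; see
#' [run_pipeline()] for the screened analysis.
#'
#' @param data Cohort tibble using the documented column dictionary (see
#'   [read_cohort()]).
#' @param equations Subset of `c("tanaka", "kawasaki", "mage")`.
#' @param bioavailability Fraction of dietary iodine absorbed.
#' @param ucr_unit Unit of the spot creatinine column.
#' @param volume_min,creat_min_female,creat_min_male Completeness
#'   thresholds, passed to [is_complete_collection()].
#' @return The input tibble with derived columns appended:
#'   `complete_collection`, `prcr_<eq>_mgday`, `pruie_<eq>_ugday`,
#'   `muie_ugday`, `intake_muie_ugday`, `intake_<eq>_ugday`,
#'   `intake_iom_ugday`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 20, seed = 3))
#' derived <- derive_records(cohort)
#' derived[, c("id", "prcr_tanaka_mgday", "pruie_tanaka_ugday", "muie_ugday")]
#' @export
derive_records <- function(data,
                           equations = EQUATIONS,
                           bioavailability = 0.92,
                           ucr_unit = "mg_dl",
                           volume_min = 300,
                           creat_min_female = 4,
                           creat_min_male = 6) {
  equations <- match.arg(equations, EQUATIONS, several.ok = TRUE)
  data <- tibble::as_tibble(data)
  data$complete_collection <- is_complete_collection(
    data$vol24_mL, data$ucr24_mmol, data$sex,
    volume_min = volume_min,
    creat_min_female = creat_min_female,
    creat_min_male = creat_min_male
  )
  for (eq in equations) {
    prcr <- switch(eq,
      tanaka = predict_creatinine_tanaka(data$age_y, data$weight_kg,
                                         data$height_cm),
      kawasaki = predict_creatinine_kawasaki(data$sex, data$age_y,
                                             data$weight_kg, data$height_cm),
      mage = predict_creatinine_mage(
        data$sex, data$age_y, data$weight_kg, data$height_cm,
        data$ethnicity_black,
        if ("bmi" %in% names(data)) data$bmi else NULL
      )
    )
    data[[paste0("prcr_", eq, "_mgday")]] <- prcr
    data[[paste0("pruie_", eq, "_ugday")]] <-
      predict_uie(data$spot_uic_ugL, data$spot_ucr_mgdL, prcr,
                  ucr_unit = ucr_unit)
    data[[paste0("intake_", eq, "_ugday")]] <-
      intake_from_excretion(data[[paste0("pruie_", eq, "_ugday")]],
                            bioavailability)
  }
  data$muie_ugday <- measured_uie(data$vol24_mL, data$iodine24_ugL)
  data$intake_muie_ugday <- intake_from_excretion(data$muie_ugday,
                                                  bioavailability)
  data$intake_iom_ugday <- iom_intake(data$spot_uic_ugL, data$weight_kg,
                                      bioavailability)
  data
}

summarise_equation <- function(derived, eq, ear, loa_z) {
  pruie <- derived[[paste0("pruie_", eq, "_ugday")]]
  muie <- derived$muie_ugday
  pred_class <- classify_ear(derived[[paste0("intake_", eq, "_ugday")]], ear)
  meas_class <- classify_ear(derived$intake_muie_ugday, ear)
  tab <- cross_tabulate(pred_class, meas_class)
  ss <- sensitivity_specificity(tab)
  keep <- !is.na(pruie)
  list(
    equation = eq,
    n = tab$n,
    n_dropped_missing = attr(tab, "n_dropped"),
    table = list(a = tab$a, b = tab$b, c = tab$c, d = tab$d),
    kappa = cohens_kappa(tab),
    sensitivity_pct = ss$sens,
    specificity_pct = ss$spec,
    pct_below_ear_pred = pct_below_ear(pred_class),
    pct_below_ear_meas = pct_below_ear(meas_class[keep]),
    paired = paired_summary(pruie[keep], muie[keep]),
    bland_altman = bland_altman_log(pruie[keep], muie[keep], z = loa_z)
  )
}

#' Run the full iodine-status assessment pipeline
#'
#' Reads (or accepts) a cohort table, excludes incomplete 24-h collections,
#' derives predicted and measured excretion and intakes, and assembles the
#' population report: one block per creatinine equation (2x2 EAR agreement
#' table, Cohen's kappa, sensitivity/specificity, percent below EAR on both
#' margins, paired distribution summary, log-scale Bland-Altman agreement),
#' an MUIC block from the spot UICs, and the IOM weight-based percent below
#' EAR. Exclusion and missingness counts are kept in the report so the
#' varying per-analysis n is always accounted for.
#'
#' @param input A cohort tibble/data.frame, or a path to a cohort CSV.
#' @param output_dir Optional directory; when given, the derived records
#'   CSV, JSON report, per-pair Bland-Altman CSVs and a run log are written
#'   there (see [write_report()]).
#' @param equations Creatinine equations to run.
#' @param ear EAR in ug/day.
#' @param bioavailability Fraction of dietary iodine absorbed.
#' @param muic_cutoff Population MUIC deficiency cut-off in ug/L.
#' @param ucr_unit Unit of the spot creatinine column.
#' @param volume_min,creat_min_female,creat_min_male Completeness
#'   thresholds.
#' @param loa_z Limits-of-agreement multiplier.
#' @return An object of class `iodine_report`: a list with `n_input`,
#'   `n_excluded_incomplete`, `n_analysed`, `equations` (named list of
#'   per-equation blocks), `muic` (see [population_muic()]),
#'   `pct_below_ear_iom`, `derived` (the screened derived tibble) and
#'   `params`.
#' @examples
#' report <- run_pipeline(generate_cohort(cohort_config(n = 120, seed = 9)))
#' report$equations$tanaka$kappa
#' @export
run_pipeline <- function(input,
                         output_dir = NULL,
                         equations = EQUATIONS,
                         ear = EAR_IODINE_UG_DAY,
                         bioavailability = 0.92,
                         muic_cutoff = MUIC_DEFICIENCY_CUTOFF,
                         ucr_unit = "mg_dl",
                         volume_min = 300,
                         creat_min_female = 4,
                         creat_min_male = 6,
                         loa_z = 1.96) {
  data <- if (is.character(input)) read_cohort(input) else
    tibble::as_tibble(input)
  equations <- match.arg(equations, EQUATIONS, several.ok = TRUE)

  derived_all <- derive_records(
    data, equations = equations, bioavailability = bioavailability,
    ucr_unit = ucr_unit, volume_min = volume_min,
    creat_min_female = creat_min_female, creat_min_male = creat_min_male
  )
  derived <- derived_all[derived_all$complete_collection, ]
  n_excluded <- nrow(derived_all) - nrow(derived)
  if (nrow(derived) == 0) {
    stop("all records were excluded by the completeness screen; ",
         "no analysable collections remain", call. = FALSE)
  }

  eq_blocks <- lapply(equations, function(eq) {
    summarise_equation(derived, eq, ear = ear, loa_z = loa_z)
  })
  names(eq_blocks) <- equations

  iom_classes <- classify_ear(derived$intake_iom_ugday, ear)

  report <- structure(
    list(
      n_input = nrow(derived_all),
      n_excluded_incomplete = n_excluded,
      n_analysed = nrow(derived),
      equations = eq_blocks,
      muic = population_muic(derived$spot_uic_ugL,
                             deficiency_cutoff = muic_cutoff),
      pct_below_ear_iom = pct_below_ear(iom_classes),
      derived = derived,
      params = list(
        ear = ear, bioavailability = bioavailability,
        muic_cutoff = muic_cutoff, ucr_unit = ucr_unit,
        volume_min = volume_min, creat_min_female = creat_min_female,
        creat_min_male = creat_min_male, loa_z = loa_z
      )
    ),
    class = "iodine_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.iodine_report <- function(x, ...) {
  cat("Iodine status report\n")
  cat("  records: ", x$n_input, " in, ", x$n_excluded_incomplete,
      " excluded as incomplete, ", x$n_analysed, " analysed\n", sep = "")
  cat(sprintf("  MUIC: %.1f ug/L (%s); %.1f%% < 100 ug/L, %.1f%% < 50 ug/L\n",
              x$muic$muic,
              if (x$muic$deficient) "population deficient" else "sufficient",
              x$muic$pct_lt100, x$muic$pct_lt50))
  cat(sprintf("  %% below EAR (measured 24-h UIE): %.1f%%; IOM equation: %.1f%%\n",
              x$equations[[1]]$pct_below_ear_meas, x$pct_below_ear_iom))
  for (eq in names(x$equations)) {
    b <- x$equations[[eq]]
    cat(sprintf(
      "  %-8s n=%d kappa=%.3f sens=%.1f%% spec=%.1f%% %%<EAR=%.1f%% ratio=%.0f%% (LOA %.0f-%.0f%%)\n",
      eq, b$n, b$kappa, b$sensitivity_pct, b$specificity_pct,
      b$pct_below_ear_pred, b$bland_altman$mean_ratio_pct,
      b$bland_altman$loa_low_pct, b$bland_altman$loa_high_pct))
  }
  invisible(x)
}

report_to_list <- function(report) {
  eqs <- lapply(report$equations, function(b) {
    list(
      n = b$n,
      n_dropped_missing = b$n_dropped_missing,
      table = b$table,
      kappa = b$kappa,
      sensitivity_pct = b$sensitivity_pct,
      specificity_pct = b$specificity_pct,
      pct_below_ear_pred = b$pct_below_ear_pred,
      pct_below_ear_meas = b$pct_below_ear_meas,
      median_pruie = b$paired$median_pred,
      iqr_pruie = b$paired$iqr_pred,
      median_muie = b$paired$median_meas,
      iqr_muie = b$paired$iqr_meas,
      median_difference = b$paired$median_difference,
      rank_test_p = b$paired$rank_test_p,
      spearman_rho = b$paired$spearman_rho,
      bland_altman = list(
        mean_ratio_pct = b$bland_altman$mean_ratio_pct,
        loa_low_pct = b$bland_altman$loa_low_pct,
        loa_high_pct = b$bland_altman$loa_high_pct,
        mean_diff_ln = b$bland_altman$mean_diff_ln,
        sd_diff_ln = b$bland_altman$sd_diff_ln,
        n = b$bland_altman$n
      )
    )
  })
  list(
    n_input = report$n_input,
    n_excluded_incomplete = report$n_excluded_incomplete,
    n_analysed = report$n_analysed,
    muic = report$muic,
    pct_below_ear_iom = report$pct_below_ear_iom,
    equations = eqs,
    params = report$params
  )
}

#' Write a pipeline report bundle to disk
#'
#' Writes `derived_records.csv` (screened records with all derived
#' columns), `agreement_report.json` (the full numeric report),
#' `bland_altman_<equation>.csv` per-pair plotting exports (x = mean of ln
#' values, y = ln difference) and `run_log.txt` with exclusion and
#' missingness counts.
#'
#' @param report An [run_pipeline()] result.
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  stopifnot(inherits(report, "iodine_report"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$derived,
                   file.path(output_dir, "derived_records.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(report_to_list(report),
                       file.path(output_dir, "agreement_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (eq in names(report$equations)) {
    ba <- report$equations[[eq]]$bland_altman
    utils::write.csv(ba$per_pair,
                     file.path(output_dir,
                               paste0("bland_altman_", eq, ".csv")),
                     row.names = FALSE)
  }
  log_lines <- c(
    sprintf("records in: %d", report$n_input),
    sprintf("excluded incomplete 24-h collections: %d",
            report$n_excluded_incomplete),
    sprintf("records analysed: %d", report$n_analysed),
    vapply(names(report$equations), function(eq) {
      b <- report$equations[[eq]]
      sprintf("%s: n = %d (pairs dropped for missing values: %d)",
              eq, b$n, b$n_dropped_missing)
    }, character(1))
  )
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}
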