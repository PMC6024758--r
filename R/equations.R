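# Prediction equations for 24-h urinary creatinine excretion (PrCr) and the
# spot-to-24h extrapolation of urinary iodine excretion. All functions are
# vectorised over their numeric arguments and return quantities in the units
# stated in their titles.

MG_PER_MMOL_CREATININE <- 113.12

check_sex <- function(sex) {
  sex <- as.character(sex)
  if (anyNA(sex)) {
    stop("`sex` must be \"male\" or \"female\" with no missing values",
         call. = FALSE)
  }
  bad <- !sex %in% c("male", "female")
  if (any(bad)) {
    stop("`sex` must be \"male\" or \"female\"; got: ",
         paste(unique(sex[bad]), collapse = ", "), call. = FALSE)
  }
  sex
}

check_anthropometry <- function(age, weight, height) {
  for (nm in c("age", "weight", "height")) {
    x <- get(nm)
    if (anyNA(x) || any(x <= 0)) {
      stop("`", nm, "` must be present and strictly positive", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Predict 24-h urinary creatinine excretion (Tanaka equation)
#'
#' Sex-independent linear equation developed in Japanese adults:
#' PrCr (mg/day) = -2.04 age + 14.89 weight + 16.14 height - 2244.45.
#'
#' @param age Age in years (> 0).
#' @param weight Body weight in kg (> 0).
#' @param height Standing height in cm (> 0).
#' @return Predicted 24-h creatinine excretion in mg/day.
#' @examples
#' predict_creatinine_tanaka(age = 50, weight = 70, height = 165)
#' @seealso [predict_creatinine_kawasaki()], [predict_creatinine_mage()]
#' @export
predict_creatinine_tanaka <- function(age, weight, height) {
  check_anthropometry(age, weight, height)
  prcr <- -2.04 * age + 14.89 * weight + 16.14 * height - 2244.45
  if (any(prcr <= 0)) {
    stop("Tanaka equation returned a non-positive creatinine excretion; ",
         "inputs are outside the physiologically plausible range",
         call. = FALSE)
  }
  prcr
}

#' Predict 24-h urinary creatinine excretion (Kawasaki equation)
#'
#' Sex-specific linear equations developed for second-morning-void
#' extrapolation:
#' men: 12.63 age + 15.12 weight + 7.39 height - 79.9;
#' women: -4.72 age + 8.58 weight + 5.09 height - 74.5.
#'
#' @param sex `"male"` or `"female"` (vectorised, recycled against the
#'   anthropometry).
#' @inheritParams predict_creatinine_tanaka
#' @return Predicted 24-h creatinine excretion in mg/day.
#' @examples
#' predict_creatinine_kawasaki("female", age = 50, weight = 70, height = 160)
#' @export
predict_creatinine_kawasaki <- function(sex, age, weight, height) {
  sex <- check_sex(sex)
  check_anthropometry(age, weight, height)
  prcr <- ifelse(
    sex == "male",
    12.63 * age + 15.12 * weight + 7.39 * height - 79.9,
    -4.72 * age + 8.58 * weight + 5.09 * height - 74.5
  )
  if (any(prcr <= 0)) {
    stop("Kawasaki equation returned a non-positive creatinine excretion; ",
         "inputs are outside the physiologically plausible range",
         call. = FALSE)
  }
  prcr
}

#' Predict 24-h urinary creatinine excretion (Mage equation)
#'
#' Multiplicative equation with a race/BMI correction term:
#' men: 0.00179 (140 - age) (weight^1.5 height^0.5)
#'   (1 + 0.18 A (1.366 - 0.0159 BMI));
#' women: 0.00163 (140 - age) (weight^1.5 height^0.5)
#'   (1 + 0.18 A (1.429 - 0.0198 BMI)),
#' where A is 1 for black/African ancestry and 0 otherwise. When A = 0 the
#' bracketed correction collapses to 1 and BMI drops out.
#'
#' A missing ethnicity indicator yields `NA` rather than an error: the
#' equation cannot be applied without it, and downstream analyses drop those
#' records listwise for this equation only.
#'
#' @inheritParams predict_creatinine_kawasaki
#' @param black Ethnicity indicator A (0, 1 or `NA`).
#' @param bmi Body mass index in kg/m^2; recomputed as
#'   `weight / (height/100)^2` when `NULL` or missing. A supplied BMI that
#'   disagrees with the derived one by more than 0.5 kg/m^2 triggers a
#'   warning and the supplied value is used.
#' @return Predicted 24-h creatinine excretion in mg/day; `NA` where `black`
#'   is missing.
#' @examples
#' predict_creatinine_mage("male", age = 25, weight = 70, height = 175, black = 0)
#' @export
predict_creatinine_mage <- function(sex, age, weight, height, black,
                                    bmi = NULL) {
  sex <- check_sex(sex)
  check_anthropometry(age, weight, height)
  if (any(age >= 140)) {
    stop("Mage equation is undefined for age >= 140 years", call. = FALSE)
  }
  if (!all(black %in% c(0, 1, NA))) {
    stop("`black` must be 0, 1 or NA", call. = FALSE)
  }
  derived_bmi <- weight / (height / 100)^2
  if (is.null(bmi)) {
    bmi <- derived_bmi
  } else {
    bmi <- ifelse(is.na(bmi), derived_bmi, bmi)
    off <- abs(bmi - derived_bmi) > 0.5
    if (any(off, na.rm = TRUE)) {
      warning("supplied BMI differs from weight/height-derived BMI by more ",
              "than 0.5 kg/m^2 for ", sum(off, na.rm = TRUE), " record(s); ",
              "using the supplied value", call. = FALSE)
    }
  }
  coef_lead <- ifelse(sex == "male", 0.00179, 0.00163)
  bracket <- ifelse(sex == "male",
                    1.366 - 0.0159 * bmi,
                    1.429 - 0.0198 * bmi)
  prcr <- coef_lead * (140 - age) * (weight^1.5 * height^0.5) *
    (1 + 0.18 * black * bracket)
  if (any(prcr <= 0, na.rm = TRUE)) {
    stop("Mage equation returned a non-positive creatinine excretion; ",
         "inputs are outside the physiologically plausible range",
         call. = FALSE)
  }
  prcr
}

#' Predicted 24-h urinary iodine excretion from a spot sample
#'
#' Extrapolates the spot iodine-to-creatinine ratio to 24 h using a
#' predicted creatinine excretion:
#' PrUIE (ug/day) = spot UIC (ug/L) / spot creatinine (mg/L) x PrCr (mg/day).
#' Creatinine concentration serves as the surrogate for the dilution state
#' of the spot sample, so the units cancel to ug/day.
#'
#' @param uic Spot urinary iodine concentration in ug/L (>= 0).
#' @param ucr Spot urinary creatinine concentration, in the unit declared by
#'   `ucr_unit` (strictly positive where non-missing).
#' @param prcr Predicted (or true) 24-h creatinine excretion in mg/day.
#' @param ucr_unit Unit of `ucr`: `"mg_dl"` (default, common clinical unit)
#'   or `"mg_l"`.
#' @return Predicted 24-h urinary iodine excretion in ug/day; `NA`
#'   propagates from any missing input.
#' @examples
#' predict_uie(uic = 130, ucr = 80, prcr = 1358.95)
#' @export
predict_uie <- function(uic, ucr, prcr, ucr_unit = c("mg_dl", "mg_l")) {
  ucr_unit <- match.arg(ucr_unit)
  if (any(uic < 0, na.rm = TRUE)) {
    stop("spot UIC must be non-negative", call. = FALSE)
  }
  if (any(ucr <= 0, na.rm = TRUE)) {
    stop("spot creatinine concentration must be strictly positive ",
         "(it is a denominator)", call. = FALSE)
  }
  ucr_mg_l <- if (ucr_unit == "mg_dl") ucr * 10 else ucr
  uic / ucr_mg_l * prcr
}

#' Measured 24-h urinary iodine excretion
#'
#' mUIE (ug/day) = 24-h volume (L) x iodine concentration of the 24-h pool
#' (ug/L). With a volume of exactly 1 L the excretion equals the
#' concentration numerically — the equivalence underlying school-age UIC
#' cut-offs.
#'
#' @param volume_ml 24-h urine volume in mL (>= 0).
#' @param iodine_ug_l Iodine concentration of the 24-h pool in ug/L (>= 0).
#' @return Measured 24-h iodine excretion in ug/day.
#' @examples
#' measured_uie(volume_ml = 1400, iodine_ug_l = 88.6)
#' @export
measured_uie <- function(volume_ml, iodine_ug_l) {
  if (any(volume_ml < 0, na.rm = TRUE) || any(iodine_ug_l < 0, na.rm = TRUE)) {
    stop("volume and iodine concentration must be non-negative", call. = FALSE)
  }
  volume_ml / 1000 * iodine_ug_l
}

#' Estimated daily iodine intake from urinary excretion
#'
#' Divides excretion by the fraction of dietary iodine absorbed (92% by
#' default), the standard bioavailability correction of the EAR cut-point
#' method.
#'
#' @param uie Urinary iodine excretion in ug/day (>= 0).
#' @param bioavailability Fraction of dietary iodine absorbed, in (0, 1].
#' @return Estimated intake in ug/day.
#' @examples
#' intake_from_excretion(124)
#' @export
intake_from_excretion <- function(uie, bioavailability = 0.92) {
  if (any(uie < 0, na.rm = TRUE)) {
    stop("excretion must be non-negative", call. = FALSE)
  }
  if (length(bioavailability) != 1 || is.na(bioavailability) ||
      bioavailability <= 0 || bioavailability > 1) {
    stop("`bioavailability` must be a single value in (0, 1]", call. = FALSE)
  }
  uie / bioavailability
}

#' IOM weight-based estimate of daily iodine intake
#'
#' Intake (ug/day) = (UIC / 0.92) x (0.0009 L/h/kg x 24 x weight), where
#' 0.0009 L per hour per kg is the urine output rate from studies in
#' children and 0.92 the iodine bioavailability.
#'
#' @param uic Spot urinary iodine concentration in ug/L (>= 0).
#' @param weight Body weight in kg (> 0).
#' @param bioavailability Fraction of dietary iodine absorbed.
#' @return Estimated intake in ug/day.
#' @examples
#' iom_intake(uic = 130, weight = 70)
#' @export
iom_intake <- function(uic, weight, bioavailability = 0.92) {
  if (any(uic < 0, na.rm = TRUE)) {
    stop("UIC must be non-negative", call. = FALSE)
  }
  if (any(weight <= 0, na.rm = TRUE)) {
    stop("weight must be strictly positive", call. = FALSE)
  }
  (uic / bioavailability) * (0.0009 * 24 * weight)
}

#' Screen 24-h collections for completeness
#'
#' A 24-h collection is assumed incomplete when total volume is <= 300 mL,
#' or creatinine excretion is <= 4 mmol/day for women or <= 6 mmol/day for
#' men. Thresholds are inclusive exclusions.
#'
#' @param volume_ml 24-h urine volume in mL.
#' @param creatinine_mmol 24-h creatinine excretion in mmol/day.
#' @param sex `"male"` or `"female"`.
#' @param volume_min Volume exclusion threshold in mL.
#' @param creat_min_female,creat_min_male Sex-specific creatinine exclusion
#'   thresholds in mmol/day.
#' @return Logical: `TRUE` for collections passing all completeness checks.
#' @examples
#' is_complete_collection(1400, 9, "male")
#' is_complete_collection(300, 10, "male")   # volume at threshold: excluded
#' @export
is_complete_collection <- function(volume_ml, creatinine_mmol, sex,
                                   volume_min = 300,
                                   creat_min_female = 4,
                                   creat_min_male = 6) {
  sex <- check_sex(sex)
  creat_min <- ifelse(sex == "female", creat_min_female, creat_min_male)
  !(volume_ml <= volume_min | creatinine_mmol <= creat_min)
}

#' Convert creatinine mass to molar amount
#'
#' mg/day to mmol/day using the molar mass of creatinine (113.12 mg/mmol);
#' needed to compare equation output (mg/day) against the completeness
#' thresholds (mmol/day).
#'
#' @param x Creatinine in mg/day (`creatinine_mg_to_mmol`) or mmol/day
#'   (`creatinine_mmol_to_mg`); non-negative.
#' @return The converted amount.
#' @examples
#' creatinine_mg_to_mmol(1131.2)
#' @export
creatinine_mg_to_mmol <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("creatinine must be non-negative", call. = FALSE)
  x / MG_PER_MMOL_CREATININE
}

#' @rdname creatinine_mg_to_mmol
#' @export
creatinine_mmol_to_mg <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("creatinine must be non-negative", call. = FALSE)
  x * MG_PER_MMOL_CREATININE
}
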