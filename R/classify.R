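# Adequacy classification against the EAR and population MUIC cut-offs, and
# 2x2 agreement between predicted and measured adequacy.

EAR_IODINE_UG_DAY <- 95
MUIC_DEFICIENCY_CUTOFF <- 100

#' Classify an estimated iodine intake against the EAR
#'
#' EAR cut-point classification: intakes strictly below the Estimated
#' Average Requirement (95 ug/day for adults) are `below_ear`; an intake of
#' exactly 95 counts as `at_or_above_ear`.
#'
#' @param intake Estimated daily iodine intake in ug/day (>= 0).
#' @param ear Estimated Average Requirement in ug/day.
#' @return Factor with levels `below_ear`, `at_or_above_ear`; `NA` intakes
#'   propagate.
#' @examples
#' classify_ear(c(94.99, 95, 134.8))
#' @export
classify_ear <- function(intake, ear = EAR_IODINE_UG_DAY) {
  if (any(intake < 0, na.rm = TRUE)) {
    stop("intake must be non-negative", call. = FALSE)
  }
  factor(ifelse(intake < ear, "below_ear", "at_or_above_ear"),
         levels = c("below_ear", "at_or_above_ear"))
}

#' Population iodine status from spot urinary iodine concentrations
#'
#' Summarises a population sample of spot UICs: the median (MUIC), the
#' population deficiency flag (MUIC < 100 ug/L for non-pregnant adults) and
#' the cumulative proportions below 100 and 50 ug/L (the WHO criteria also
#' require no more than 20% below 50 ug/L).
#'
#' @param uic Numeric vector of spot UICs in ug/L; `NA`s are dropped.
#' @param deficiency_cutoff Population MUIC cut-off in ug/L.
#' @param low_cutoff Lower tail cut-off in ug/L.
#' @return A list with `muic` (ug/L), `deficient` (logical), `pct_lt100`,
#'   `pct_lt50` (percentages) and `n`.
#' @examples
#' population_muic(c(40, 60, 120))
#' @export
population_muic <- function(uic, deficiency_cutoff = MUIC_DEFICIENCY_CUTOFF,
                            low_cutoff = 50) {
  uic <- uic[!is.na(uic)]
  if (length(uic) == 0) {
    stop("`uic` must contain at least one non-missing value", call. = FALSE)
  }
  muic <- stats::median(uic)
  list(
    muic = muic,
    deficient = muic < deficiency_cutoff,
    pct_lt100 = 100 * mean(uic < deficiency_cutoff),
    pct_lt50 = 100 * mean(uic < low_cutoff),
    n = length(uic)
  )
}

#' Construct a 2x2 adequacy agreement table
#'
#' Cell layout (predicted status in rows, measured status in columns):
#' `a` both below EAR, `b` predicted below / measured at-or-above,
#' `c` predicted at-or-above / measured below, `d` both at-or-above.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `agreement_table`.
#' @examples
#' agreement_table(112, 67, 75, 201)
#' @export
agreement_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(
    list(a = a, b = b, c = c, d = d, n = a + b + c + d),
    class = "agreement_table"
  )
}

#' @export
print.agreement_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
              dimnames = list(
                predicted = c("below_ear", "at_or_above_ear"),
                measured = c("below_ear", "at_or_above_ear")
              ))
  cat("2x2 EAR adequacy agreement (n = ", x$n, ")\n", sep = "")
  print(m)
  invisible(x)
}

#' Cross-tabulate predicted vs measured EAR adequacy
#'
#' Pairs with a missing classification on either side are dropped (this is
#' how records lacking the ethnicity indicator leave the Mage table only).
#'
#' @param pred,meas Equal-length vectors of classifications as returned by
#'   [classify_ear()].
#' @return An [agreement_table()]; the number of dropped pairs is attached
#'   as attribute `n_dropped`.
#' @examples
#' pred <- classify_ear(c(80, 80, 120, 120))
#' meas <- classify_ear(c(80, 120, 80, 120))
#' cross_tabulate(pred, meas)
#' @export
cross_tabulate <- function(pred, meas) {
  if (length(pred) != length(meas)) {
    stop("`pred` and `meas` must have the same length", call. = FALSE)
  }
  keep <- !is.na(pred) & !is.na(meas)
  pred <- as.character(pred)[keep]
  meas <- as.character(meas)[keep]
  tab <- agreement_table(
    a = sum(pred == "below_ear" & meas == "below_ear"),
    b = sum(pred == "below_ear" & meas == "at_or_above_ear"),
    c = sum(pred == "at_or_above_ear" & meas == "below_ear"),
    d = sum(pred == "at_or_above_ear" & meas == "at_or_above_ear")
  )
  attr(tab, "n_dropped") <- sum(!keep)
  tab
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' kappa = (po - pe) / (1 - pe), with observed agreement po = (a + d)/n and
#' chance agreement pe = ((a+b)(a+c) + (c+d)(b+d)) / n^2. Values near 1
#' indicate agreement well beyond chance; values near 0, chance-level
#' agreement.
#'
#' @param t An [agreement_table()].
#' @return Kappa in [-1, 1].
#' @examples
#' cohens_kappa(agreement_table(112, 67, 75, 201))
#' @export
cohens_kappa <- function(t) {
  stopifnot(inherits(t, "agreement_table"))
  if (t$n == 0) stop("empty table: kappa undefined", call. = FALSE)
  po <- (t$a + t$d) / t$n
  pe <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / t$n^2
  if (pe == 1) {
    stop("degenerate single-category table: chance agreement is 1, ",
         "kappa undefined", call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Sensitivity and specificity of predicted below-EAR status
#'
#' Treats measured status as the reference: sensitivity is the percentage of
#' measured below-EAR individuals the prediction also places below the EAR,
#' a/(a+c) x 100; specificity is d/(b+d) x 100.
#'
#' @param t An [agreement_table()].
#' @return A list with `sens` and `spec` in percent.
#' @examples
#' sensitivity_specificity(agreement_table(112, 67, 75, 201))
#' @export
sensitivity_specificity <- function(t) {
  stopifnot(inherits(t, "agreement_table"))
  if (t$a + t$c == 0) {
    stop("no measured below-EAR individuals: sensitivity undefined",
         call. = FALSE)
  }
  if (t$b + t$d == 0) {
    stop("no measured at-or-above-EAR individuals: specificity undefined",
         call. = FALSE)
  }
  list(
    sens = 100 * t$a / (t$a + t$c),
    spec = 100 * t$d / (t$b + t$d)
  )
}

#' Percentage of classifications below the EAR
#'
#' @param classes Vector of classifications as returned by [classify_ear()];
#'   `NA`s are dropped.
#' @return Percentage in [0, 100].
#' @examples
#' pct_below_ear(classify_ear(c(50, 90, 100, 200)))
#' @export
pct_below_ear <- function(classes) {
  classes <- classes[!is.na(classes)]
  if (length(classes) == 0) {
    stop("`classes` must contain at least one non-missing value",
         call. = FALSE)
  }
  100 * mean(as.character(classes) == "below_ear")
}
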