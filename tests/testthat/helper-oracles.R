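# Independent longhand oracles: straight-line arithmetic written separately
# from the package implementation, used to pin the closed-form operations.

oracle_tanaka <- function(age, weight, height) {
  (-2.04 * age) + (14.89 * weight) + (16.14 * height) - 2244.45
}

oracle_kawasaki <- function(sex, age, weight, height) {
  if (sex == "male") {
    (12.63 * age) + (15.12 * weight) + (7.39 * height) - 79.9
  } else {
    (-4.72 * age) + (8.58 * weight) + (5.09 * height) - 74.5
  }
}

oracle_mage <- function(sex, age, weight, height, black,
                        bmi = weight / (height / 100)^2) {
  lead <- if (sex == "male") 0.00179 else 0.00163
  brk <- if (sex == "male") 1.366 - 0.0159 * bmi else 1.429 - 0.0198 * bmi
  lead * (140 - age) * (weight^1.5 * sqrt(height)) * (1 + 0.18 * black * brk)
}

oracle_pruie <- function(uic, ucr_mg_dl, prcr) {
  (uic / (ucr_mg_dl * 10)) * prcr
}

oracle_iom <- function(uic, weight) {
  (uic / 0.92) * (0.0009 * 24 * weight)
}

oracle_intake <- function(uie) uie / 0.92

# Bland-Altman oracle: direct arithmetic on the ln vector.
oracle_bland_altman <- function(pred, meas, z = 1.96) {
  d <- log(pred) - log(meas)
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  list(mean_pct = exp(m) * 100,
       lo_pct = exp(m - z * s) * 100,
       hi_pct = exp(m + z * s) * 100)
}

# Random participants on the physiologically plausible adult grid.
random_participants <- function(n, seed = 1234) {
  set.seed(seed)
  data.frame(
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = runif(n, 18, 90),
    weight = runif(n, 40, 150),
    height = runif(n, 140, 200),
    black = sample(0:1, n, replace = TRUE)
  )
}

# Numeric view of a pipeline report for determinism comparisons.
report_list_strip <- function(r) iodstatus:::report_to_list(r)
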