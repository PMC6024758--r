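# Synthetic cohort generator: determinism, calibration and recovery.

test_that("config validation catches invalid settings", {
  expect_error(cohort_config(n = 0), "positive integer")
  expect_error(cohort_config(frac_female = 1.2), "frac_female")
  expect_error(cohort_config(muie_median = -5), "muie_median")
  expect_error(cohort_config(spot_cv = -0.1), "spot_cv")
  expect_error(cohort_config(age_range = c(50, 20)), "age_range")
})

test_that("the seed fully determines the cohort, including its CSV form", {
  c1 <- generate_cohort(cohort_config(n = 80, seed = 123))
  c2 <- generate_cohort(cohort_config(n = 80, seed = 123))
  expect_identical(c1, c2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(c1, f1)
  write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  c3 <- generate_cohort(cohort_config(n = 80, seed = 124))
  expect_false(identical(c1$spot_uic_ugL, c3$spot_uic_ugL))
})

test_that("cohort CSV round-trips through the documented column dictionary", {
  co <- generate_cohort(cohort_config(n = 40, seed = 6))
  f <- tempfile(fileext = ".csv")
  ft <- tempfile(fileext = ".csv")
  write_cohort(co, f, truth_path = ft)
  back <- read_cohort(f)
  expect_false(any(c("true_uie_ugday", "true_cr_mgday") %in% names(back)))
  expect_equal(back$spot_uic_ugL, co$spot_uic_ugL, tolerance = 1e-9)
  truth <- utils::read.csv(ft)
  expect_equal(truth$true_uie_ugday, co$true_uie_ugday, tolerance = 1e-9)
  # a file missing required columns is refused by name
  bad <- co[, c("id", "sex")]
  fb <- tempfile(fileext = ".csv")
  utils::write.csv(bad, fb, row.names = FALSE)
  expect_error(read_cohort(fb), "missing required column")
})

test_that("default cohort reproduces the target marginal medians", {
  co <- generate_cohort(cohort_config(n = 457, seed = 20180607))
  muie <- measured_uie(co$vol24_mL, co$iodine24_ugL)
  expect_lt(abs(median(co$spot_uic_ugL) - 130) / 130, 0.10)
  expect_lt(abs(median(muie) - 124) / 124, 0.10)
  expect_lt(abs(median(co$vol24_mL) - 1400) / 1400, 0.10)
  expect_gt(mean(co$sex == "female"), 0.68)
  expect_lt(mean(co$sex == "female"), 0.84)
  expect_true(all(co$age_y >= 18 & co$age_y <= 90))
  expect_gt(sum(is.na(co$ethnicity_black)), 0)
})

test_that("configured medians are recovered within 3% at large n", {
  co <- generate_cohort(cohort_config(n = 1e5, seed = 55))
  expect_lt(abs(median(co$true_uie_ugday) - 124) / 124, 0.03)
  expect_lt(abs(median(co$vol24_mL) - 1400) / 1400, 0.03)
  muie <- measured_uie(co$vol24_mL, co$iodine24_ugL)
  expect_lt(abs(median(muie) - 124) / 124, 0.03)
  expect_lt(abs(median(co$spot_uic_ugL) - 130) / 130, 0.03)
})

test_that("noise-free generation collapses to exact identities", {
  co <- generate_cohort(cohort_config_noise_free(n = 150, seed = 9))
  muie <- measured_uie(co$vol24_mL, co$iodine24_ugL)
  expect_equal(muie, co$true_uie_ugday, tolerance = 1e-12)
  # spot ratio scaled by the true creatinine recovers measured UIE per record
  pruie_true_cr <- predict_uie(co$spot_uic_ugL, co$spot_ucr_mgdL,
                               co$true_cr_mgday)
  expect_equal(pruie_true_cr, muie, tolerance = 1e-12)
  rr <- recovery_report(co, use_true_creatinine = TRUE)
  expect_equal(rr$pct_below_ear_est, rr$pct_below_ear_true)
  expect_equal(rr$spearman_rho, 1)
  expect_equal(rr$mean_ratio_pct, 100, tolerance = 1e-9)
})

test_that("shrinking the spot noise drives the rank correlation toward 1", {
  cfg_lo <- cohort_config(n = 400, seed = 13, spot_cv = 0.02,
                          intake_day_cv = 0.02, spot_cr_cv = 0.02,
                          day24_cv = 0.02)
  rr_lo <- recovery_report(generate_cohort(cfg_lo), use_true_creatinine = TRUE)
  rr_def <- recovery_report(generate_cohort(cohort_config(n = 400, seed = 13)),
                            use_true_creatinine = TRUE)
  expect_gt(rr_lo$spearman_rho, 0.98)
  expect_gt(rr_lo$spearman_rho, rr_def$spearman_rho)
})

test_that("default cohort lands in the observed spot-vs-24h correlation band", {
  rr <- recovery_report(generate_cohort(cohort_config(n = 457, seed = 101)))
  expect_gte(rr$spearman_rho, 0.3)
  expect_lte(rr$spearman_rho, 0.55)
})

test_that("a configured spot-creatinine bias surfaces as the analytic ratio bias", {
  # spot creatinine scaled by 0.8 inflates PrUIE by 1/0.8 = 125% on average
  co <- generate_cohort(cohort_config(n = 10000, seed = 17,
                                      spot_cr_bias = 0.8))
  rr <- recovery_report(co, equation = "kawasaki")
  expect_equal(rr$mean_ratio_pct, 125, tolerance = 0.02 * 125)
})

test_that("widened volume/creatinine tails raise the exclusion fraction", {
  base <- generate_cohort(cohort_config(n = 3000, seed = 21))
  wide <- generate_cohort(cohort_config(n = 3000, seed = 21,
                                        volume_sdlog = 1.4))
  frac_base <- mean(!is_complete_collection(base$vol24_mL, base$ucr24_mmol,
                                            base$sex))
  frac_wide <- mean(!is_complete_collection(wide$vol24_mL, wide$ucr24_mmol,
                                            wide$sex))
  expect_gt(frac_wide, frac_base)
  expect_gt(frac_wide, 0.05)
})
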