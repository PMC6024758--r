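# Closed-form creatinine and iodine excretion equations.

test_that("Tanaka equation matches longhand evaluation and is linear in age", {
  expect_equal(predict_creatinine_tanaka(50, 70, 165), 1358.95)
  expect_equal(predict_creatinine_tanaka(20, 80, 180), 1811.15)
  # one extra year of age lowers the prediction by exactly the age coefficient
  expect_equal(
    predict_creatinine_tanaka(50, 70, 165) -
      predict_creatinine_tanaka(51, 70, 165),
    2.04
  )
})

test_that("Kawasaki equation applies the sex-specific formula", {
  expect_equal(predict_creatinine_kawasaki("male", 50, 70, 175), 2903.25)
  expect_equal(predict_creatinine_kawasaki("female", 50, 70, 160), 1104.5)
  expect_error(predict_creatinine_kawasaki(NA, 50, 70, 160), "sex")
})

test_that("Kawasaki male prediction exceeds female on identical anthropometry", {
  grid <- expand.grid(age = seq(18, 90, by = 8),
                      weight = seq(40, 150, by = 10),
                      height = seq(140, 200, by = 10))
  m <- predict_creatinine_kawasaki(rep("male", nrow(grid)),
                                   grid$age, grid$weight, grid$height)
  f <- predict_creatinine_kawasaki(rep("female", nrow(grid)),
                                   grid$age, grid$weight, grid$height)
  expect_true(all(m > f))
})

test_that("Mage equation: multiplicative form, ethnicity handling, BMI bracket", {
  expect_equal(predict_creatinine_mage("male", 25, 70, 175, black = 0),
               0.00179 * 115 * 70^1.5 * sqrt(175))
  # frozen longhand value for a woman with the ethnicity correction active
  expect_equal(
    predict_creatinine_mage("female", 52, 75, 160, black = 1, bmi = 29.3),
    oracle_mage("female", 52, 75, 160, black = 1, bmi = 29.3),
    tolerance = 1e-12
  )
  expect_equal(
    round(predict_creatinine_mage("female", 52, 75, 160, black = 1,
                                  bmi = 29.3), 2),
    1358.55
  )
  # at bmi = 1.366/0.0159 the men's bracket vanishes: A has no effect
  bmi0 <- 1.366 / 0.0159
  w <- bmi0 * (1.8)^2
  expect_equal(predict_creatinine_mage("male", 40, w, 180, black = 1),
               predict_creatinine_mage("male", 40, w, 180, black = 0))
  # missing ethnicity propagates missing; age >= 140 is an error
  expect_true(is.na(predict_creatinine_mage("male", 25, 70, 175,
                                            black = NA)))
  expect_error(predict_creatinine_mage("male", 141, 70, 175, black = 0),
               "age")
  expect_warning(
    predict_creatinine_mage("female", 52, 75, 160, black = 1, bmi = 35),
    "BMI"
  )
})

test_that("all equations are strictly positive over the plausible adult grid", {
  grid <- expand.grid(age = seq(18, 90, by = 6),
                      weight = seq(40, 150, by = 10),
                      height = seq(140, 200, by = 6))
  sexes <- rep(c("male", "female"), length.out = nrow(grid))
  expect_true(all(predict_creatinine_tanaka(grid$age, grid$weight,
                                            grid$height) > 0))
  expect_true(all(predict_creatinine_kawasaki(sexes, grid$age, grid$weight,
                                              grid$height) > 0))
  expect_true(all(predict_creatinine_mage(sexes, grid$age, grid$weight,
                                          grid$height,
                                          black = rep(0:1, length.out = nrow(grid))) > 0))
})

test_that("anthropometry validation rejects missing or non-positive inputs", {
  expect_error(predict_creatinine_tanaka(NA, 70, 165), "age")
  expect_error(predict_creatinine_tanaka(50, -70, 165), "weight")
  expect_error(predict_creatinine_tanaka(50, 70, 0), "height")
})

test_that("spot-to-24h iodine extrapolation cancels units correctly", {
  expect_equal(predict_uie(uic = 100, ucr = 100, prcr = 1000), 100)
  expect_equal(predict_uie(uic = 130, ucr = 80, prcr = 1358.95),
               130 / 800 * 1358.95)
  # doubling the creatinine scale doubles PrUIE at a fixed spot ratio
  expect_equal(predict_uie(130, 80, 2 * 1358.95),
               2 * predict_uie(130, 80, 1358.95))
  # declared-unit invariance: mg/dL input x10 equals mg/L input
  expect_equal(predict_uie(130, 80, 1358.95, ucr_unit = "mg_dl"),
               predict_uie(130, 800, 1358.95, ucr_unit = "mg_l"))
  expect_error(predict_uie(130, 0, 1000), "creatinine")
})

test_that("measured 24-h excretion is volume (L) times concentration", {
  expect_equal(measured_uie(1400, 88.6), 124.04)
  # at exactly 1 L the excretion equals the concentration numerically
  expect_equal(measured_uie(1000, 77.3), 77.3)
  expect_equal(measured_uie(0, 500), 0)
})

test_that("intake conversions follow the bioavailability correction", {
  expect_equal(intake_from_excretion(92), 100)
  expect_equal(intake_from_excretion(0), 0)
  expect_equal(round(intake_from_excretion(124), 2), 134.78)
  # dividing by bioavailability then multiplying back is the identity
  expect_equal(intake_from_excretion(124) * 0.92, 124)
  expect_error(intake_from_excretion(-1), "non-negative")
  expect_error(intake_from_excretion(100, bioavailability = 0), "bioavailability")
})

test_that("IOM weight-based intake matches longhand evaluation", {
  expect_equal(round(iom_intake(130, 70), 2), 213.65)
  expect_equal(iom_intake(0, 80), 0)
  expect_equal(iom_intake(92, 1000 / 21.6), 100)
  expect_error(iom_intake(100, 0), "weight")
})

test_that("completeness screen applies inclusive exclusion thresholds", {
  expect_false(is_complete_collection(300, 10, "male"))
  expect_false(is_complete_collection(1400, 4.0, "female"))
  expect_false(is_complete_collection(1400, 6.0, "male"))
  expect_true(is_complete_collection(1400, 9, "male"))
  expect_true(is_complete_collection(1400, 4.5, "female"))
  expect_false(is_complete_collection(1400, 4.5, "male"))
  expect_error(is_complete_collection(1400, 9, NA), "sex")
})

test_that("creatinine mass/molar conversion round-trips", {
  expect_equal(creatinine_mg_to_mmol(113.12), 1)
  expect_equal(creatinine_mg_to_mmol(1131.2), 10)
  x <- c(0.3, 87, 1500, 2903.25)
  expect_equal(creatinine_mmol_to_mg(creatinine_mg_to_mmol(x)), x,
               tolerance = 1e-12)
  expect_error(creatinine_mg_to_mmol(-1), "non-negative")
})

test_that("equations agree with independent longhand oracles on random inputs", {
  p <- random_participants(100, seed = 7)
  for (i in seq_len(nrow(p))) {
    expect_equal(predict_creatinine_tanaka(p$age[i], p$weight[i], p$height[i]),
                 oracle_tanaka(p$age[i], p$weight[i], p$height[i]),
                 tolerance = 1e-9)
    expect_equal(
      predict_creatinine_kawasaki(p$sex[i], p$age[i], p$weight[i], p$height[i]),
      oracle_kawasaki(p$sex[i], p$age[i], p$weight[i], p$height[i]),
      tolerance = 1e-9
    )
    expect_equal(
      predict_creatinine_mage(p$sex[i], p$age[i], p$weight[i], p$height[i],
                              black = p$black[i]),
      oracle_mage(p$sex[i], p$age[i], p$weight[i], p$height[i], p$black[i]),
      tolerance = 1e-9
    )
  }
})
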