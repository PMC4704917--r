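test_that("BMI follows weight over squared height", {
  expect_equal(round(bmi(60, 170), 2), 20.76)
  expect_equal(bmi(55, 100), 55)           # 1 m tall: BMI equals weight
  expect_equal(bmi(120, 170), 2 * bmi(60, 170))
  expect_error(bmi(0, 170), class = "dietsense_argument_error")
  expect_error(bmi(60, -1), class = "dietsense_argument_error")
})

test_that("Schofield BMR matches hand-applied coefficients", {
  # 10-17 y girl: 0.056 MJ/kg * 57.4 kg + 2.898 MJ = 6112.4 kJ/day
  expect_equal(schofield_bmr("female", 15.5, 57.4), 6112.4)
  # 10-17 y boy: 0.074 * 66.1 + 2.754 MJ = 7645.4 kJ/day
  expect_equal(schofield_bmr("male", 15.0, 66.1), 7645.4)
  # determinism and monotonicity in weight
  expect_identical(schofield_bmr("female", 15.5, 57.4),
                   schofield_bmr("female", 15.5, 57.4))
  expect_gt(schofield_bmr("male", 15, 70), schofield_bmr("male", 15, 60))
  # band boundary is lower-inclusive: exactly 18 y uses the adult band
  expect_equal(schofield_bmr("female", 18, 60), 62 * 60 + 2036)
  expect_equal(schofield_bmr("female", 17.99, 60), 56 * 60 + 2898)
  expect_error(schofield_bmr("female", -1, 60),
               class = "dietsense_range_error")
})

test_that("Schofield BMR agrees with an independent table lookup", {
  # independently written lookup (kJ/day), not sharing package code
  oracle <- function(sex, age, w) {
    co <- if (sex == "male") {
      if (age < 3) c(249, -127) else if (age < 10) c(95, 2110)
      else if (age < 18) c(74, 2754) else if (age < 30) c(63, 2896)
      else if (age < 60) c(48, 3653) else c(49, 2459)
    } else {
      if (age < 3) c(244, -130) else if (age < 10) c(85, 2033)
      else if (age < 18) c(56, 2898) else if (age < 30) c(62, 2036)
      else if (age < 60) c(34, 3538) else c(38, 2755)
    }
    co[1] * w + co[2]
  }
  withr::with_seed(42, {
    for (i in 1:20) {
      sex <- sample(c("female", "male"), 1)
      age <- runif(1, 1, 75)
      w <- runif(1, 10, 110)
      expect_equal(schofield_bmr(sex, age, w), oracle(sex, age, w))
    }
  })
})

test_that("PAL lookups match the sex-specific five-level table", {
  expect_equal(pal_value("female", "very_light"), 1.3)
  expect_equal(pal_value("male", "very_heavy"), 2.2)
  expect_equal(pal_value("female", "moderate"), 1.7)
  tab <- pal_table()
  expect_equal(nrow(tab), 10)
  girls <- tab$pal[tab$gender == "female"]
  boys <- tab$pal[tab$gender == "male"]
  expect_equal(boys - girls, rep(0.1, 5))
  # strictly increasing across the ordered levels for each sex
  ord <- match(tab$level, activity_levels())
  for (g in c("female", "male")) {
    expect_true(all(diff(tab$pal[tab$gender == g][order(ord[tab$gender == g])]) > 0))
  }
  expect_error(pal_value("female", "extreme"),
               class = "dietsense_argument_error")
})

test_that("app TEE is BMR times the reported PAL", {
  expect_equal(tee_app("female", 15.5, 57.4, "moderate"), 6112.4 * 1.7)
  expect_gt(tee_app("male", 15, 60, "heavy"), tee_app("male", 15, 60, "light"))
  # equal-BMR girl and boy at very light differ by the PAL ratio 1.4/1.3
  b <- schofield_bmr("female", 15, 55)
  expect_equal(tee_app("male", 15, (b - 2754) / 74, "very_light") /
                 tee_app("female", 15, 55, "very_light"), 1.4 / 1.3)
})

test_that("LMS z-scores and weight status follow the reference table", {
  ref <- load_lms_reference()
  # at the median of the reference, z = 0 and status is normal
  m15 <- ref$M[ref$sex == "female" & ref$age_years == 15]
  expect_equal(bmi_zscore(m15, 15, "female", ref), 0)
  expect_equal(as.character(weight_status(m15, 15, "female", ref)),
               "normal")
  # hand-applied LMS transform at the female age-15 row
  # (L = -1.3, M = 19.77, S = 0.112): BMI 25 gives
  # ((25/19.77)^-1.3 - 1)/(-1.3 * 0.112) = 1.8062
  expect_equal(bmi_zscore(25, 15, "female", ref), 1.8062, tolerance = 1e-4)
  # inverse transform round-trips
  expect_equal(bmi_from_zscore(1.5, 15.25, "male", ref) |>
                 bmi_zscore(15.25, "male", ref), 1.5)
  # cutoffs are inclusive toward the extreme category
  ow <- ref$cutoff_overweight[ref$sex == "male" & ref$age_years == 15]
  expect_equal(as.character(weight_status(ow, 15, "male", ref)),
               "overweight")
  expect_equal(as.character(weight_status(ow - 0.01, 15, "male", ref)),
               "normal")
  th1 <- ref$cutoff_thin1[ref$sex == "female" & ref$age_years == 16]
  expect_equal(as.character(weight_status(th1, 16, "female", ref)),
               "thinness_grade_1")
  expect_error(bmi_zscore(20, 25, "female", ref),
               class = "dietsense_range_error")
  # partition: every BMI gets exactly one category
  withr::with_seed(5, {
    ws <- weight_status(runif(50, 12, 40), runif(50, 14, 17),
                        sample(c("female", "male"), 50, TRUE), ref)
    expect_true(!anyNA(ws))
  })
})

test_that("wear time counts on-body minutes", {
  expect_equal(wear_hours(tiny_swa()), 24)
  expect_equal(wear_hours(tiny_swa(off = 1:300)), 19)
  expect_equal(wear_hours(tiny_swa(off = 1:1440)), 0)
})

test_that("armband TEE imputes off-body minutes at basal rate", {
  bmr <- 6000
  full <- tiny_swa(rate_kj = 6)
  expect_equal(tee_swa(full, bmr), 6 * 1440)
  # one off-body hour with zero recorded energy adds bmr/24
  gap <- tiny_swa(rate_kj = 6, off = 601:660)
  gap$ee_kj[601:660] <- 0
  expect_equal(tee_swa(gap, bmr), 6 * 1380 + bmr / 24)
  allday_off <- tiny_swa(off = 1:1440)
  expect_equal(tee_swa(allday_off, bmr), bmr)
  # tee_swa is never below the on-body sum, equality iff fully worn
  expect_gt(tee_swa(gap, bmr), sum(gap$ee_kj[gap$on_body]))
  expect_equal(tee_swa(full, bmr), sum(full$ee_kj))
})

test_that("vectorised armband summaries match the per-record route", {
  recs <- list(tiny_swa(6), tiny_swa(7, off = 201:420))
  recs[[2]]$date <- as.Date("2013-03-07")
  trace <- purrr::map_dfr(recs, function(r) {
    tibble::tibble(participant_id = r$participant_id, date = r$date,
                   minute = 0:1439, ee_kj = r$ee_kj, on_body = r$on_body)
  })
  participants <- tibble::tibble(participant_id = "P1", bmr_kj = 6200)
  days <- tee_swa_days(trace, participants)
  expect_equal(days$tee_swa_kj,
               vapply(recs, tee_swa, numeric(1), bmr_kj = 6200))
  expect_equal(days$wear_hours, vapply(recs, wear_hours, numeric(1)))
  expect_error(tee_swa_days(trace[-1, ], participants),
               class = "dietsense_schema_error")
})
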