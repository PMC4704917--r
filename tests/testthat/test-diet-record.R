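test_that("meal summaries scale linearly and add over items", {
  db <- tiny_db()
  # 200 g of milk at 190 kJ/100 g
  m <- meal_of("2013-03-06", list(food_id = "f_milk", unit_name = "gram",
                                  amount = 200))
  s <- compute_meal_summary(m, db)
  expect_equal(s$energy_kj, 380)
  expect_equal(unname(s$nutrients["protein_g"]), 6.8)

  # two 100 g items of the same food equal one 200 g item
  m2 <- meal_of("2013-03-06", list(food_id = c("f_milk", "f_milk"),
                                   unit_name = "gram", amount = c(100, 100)))
  expect_equal(compute_meal_summary(m2, db), s)

  empty <- meal_of("2013-03-06", NULL)
  s0 <- compute_meal_summary(empty, db)
  expect_equal(s0$energy_kj, 0)
  expect_true(all(s0$nutrients == 0))

  bad <- meal_of("2013-03-06", list(food_id = "nope", unit_name = "gram",
                                    amount = 1))
  expect_error(compute_meal_summary(bad, db),
               class = "dietsense_lookup_error")
})

test_that("day intake sums meals and groups grams by food group", {
  db <- tiny_db()
  mk <- function(fid, amt, type, time) {
    meal_of("2013-03-06", list(food_id = fid, unit_name = "gram",
                               amount = amt), type, time)
  }
  day <- diet_day("P1", "2013-03-06", list(
    mk("f_milk", 200, "breakfast", "07:30"),
    mk("f_apple", 120, "lunch", "12:00"),
    mk("f_apple", 80, "snack", "15:00")))
  s <- compute_day_intake(day, db)
  expect_equal(s$energy_kj, 200 / 100 * 190 + 200 / 100 * 220)
  expect_equal(s$energy_kj, sum(s$per_meal_energy_kj))
  expect_equal(s$food_group_grams[["Fruit"]], 200)
  expect_named(s$per_meal_energy_kj,
               c("1_breakfast", "2_lunch", "3_snack"))

  # permuting meals leaves the totals unchanged
  day_rev <- diet_day("P1", "2013-03-06", rev(day$meals))
  s_rev <- compute_day_intake(day_rev, db)
  expect_equal(s_rev$energy_kj, s$energy_kj)
  expect_equal(s_rev$nutrients, s$nutrients)
  expect_equal(s_rev$food_group_grams, s$food_group_grams)
})

test_that("day energy is invariant under re-partitioning items over meals", {
  db <- tiny_db()
  items <- tibble::tibble(food_id = c("f_milk", "f_shake", "f_apple"),
                          unit_name = c("gram", "deciliter", "piece"),
                          amount = c(150, 2, 1))
  one_meal <- diet_day("P1", "2013-03-06",
                       list(meal_of("2013-03-06", items)))
  split_up <- diet_day("P1", "2013-03-06", list(
    meal_of("2013-03-06", items[1, ], "breakfast", "08:00"),
    meal_of("2013-03-06", items[2:3, ], "dinner", "19:00")))
  e1 <- compute_day_intake(one_meal, db)
  e2 <- compute_day_intake(split_up, db)
  expect_equal(e1$energy_kj, e2$energy_kj)
  expect_equal(e1$nutrients, e2$nutrients)
  expect_true(all(e1$nutrients >= 0) && is.finite(e1$energy_kj))
})

test_that("feedback reports intake relative to recommendations", {
  db <- tiny_db()
  s <- compute_day_intake(tiny_day(), db)
  rec <- c(energy_kj = s$energy_kj, protein_g = s$nutrients[["protein_g"]])
  fb <- feedback_report(s, rec)
  expect_equal(unname(fb$ratios), c(1, 1))
  expect_equal(sum(fb$per_meal_energy_pct), 100)

  fb2 <- feedback_report(list(energy_kj = 2000, nutrients = numeric(0),
                              per_meal_energy_kj = c(`1_lunch` = 2000)),
                         c(energy_kj = 10000))
  expect_equal(unname(fb2$per_meal_energy_pct), 20)
  expect_equal(unname(fb2$ratios["energy_kj"]), 0.2)
  expect_error(feedback_report(s, c(energy_kj = 0)),
               class = "dietsense_argument_error")
})

test_that("edits return new days and invert cleanly", {
  db <- tiny_db()
  day <- tiny_day()
  e0 <- compute_day_intake(day, db)$energy_kj
  added <- edit_day(day, "add", meal = 1,
                    item = list(food_id = "f_milk", unit_name = "gram",
                                amount = 100))
  expect_equal(compute_day_intake(added, db)$energy_kj, e0 + 190)
  back <- edit_day(added, "delete", meal = 1,
                   item = nrow(added$meals[[1]]$items))
  expect_equal(back, day)

  upd <- edit_day(day, "update", meal = 1, item = 1, amount = 300)
  expect_equal(compute_day_intake(upd, db)$energy_kj, e0 + 190)

  expect_error(edit_day(day, "delete", meal = 2, item = 1),
               class = "dietsense_index_error")
  empty_meal_day <- diet_day("P1", "2013-03-06",
                             list(meal_of("2013-03-06", NULL)))
  expect_error(edit_day(empty_meal_day, "delete", meal = 1, item = 1),
               class = "dietsense_index_error")
})

test_that("long-format records round-trip and match the per-day route", {
  db <- tiny_db()
  records <- tibble::tibble(
    participant_id = c("P1", "P1", "P2"),
    date = as.Date(c("2013-03-06", "2013-03-06", "2013-03-09")),
    time = c("07:30", "12:00", "12:00"),
    meal_type = c("breakfast", "lunch", "lunch"),
    food_id = c("f_milk", "f_apple", "f_shake"),
    unit_name = c("gram", "piece", "deciliter"),
    amount = c(200, 1, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_diet_records(records, path)
  expect_equal(read_diet_records(path), records)

  days <- compute_intake_days(records, db)
  expect_equal(nrow(days), 2)
  # cross-check the vectorised route against the object route
  object_route <- vapply(records_to_days(records), function(d) {
    compute_day_intake(d, db)$energy_kj
  }, numeric(1))
  expect_equal(sort(days$ei_kj), sort(unname(object_route)))
  # 2013-03-09 was a Saturday
  expect_equal(days$is_weekend[days$participant_id == "P2"], TRUE)
  expect_equal(days$is_weekend[days$participant_id == "P1"], FALSE)

  expect_error(compute_intake_days(
    dplyr::mutate(records, food_id = "ghost"), db),
    class = "dietsense_lookup_error")
})
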