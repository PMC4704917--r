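# Hand-built fixtures shared across the test files.

tiny_db <- function() {
  food_db(
    items = tibble::tibble(
      food_id = c("f_milk", "f_shake", "f_oat", "f_apple"),
      name = c("Milk", "Milkshake", "Oat milk", "Apple"),
      food_group = c("Dairy", "Dairy", "Dairy", "Fruit"),
      energy_kj_per_100g = c(190, 340, 160, 220),
      protein_g = c(3.4, 3.1, 1.0, 0.3),
      fat_g = c(1.5, 3.8, 1.5, 0.2)),
    units = tibble::tibble(
      food_id = c("f_milk", "f_shake", "f_apple", "f_apple"),
      unit_name = c("deciliter", "deciliter", "piece", "tablespoon"),
      gram_weight = c(103, 105, 150, 15)),
    version = "test-1")
}

meal_of <- function(date, items, meal_type = "lunch", time = "12:00") {
  meal_record(date, time, meal_type,
              if (is.null(items)) NULL else tibble::as_tibble(items))
}

# one participant-day: 200 g milk + 1 apple piece for lunch
tiny_day <- function() {
  diet_day("P1", "2013-03-06", list(
    meal_of("2013-03-06", list(food_id = c("f_milk", "f_apple"),
                               unit_name = c("gram", "piece"),
                               amount = c(200, 1)))))
}

# armband day with a known gap: minutes 600-659 off-body
tiny_swa <- function(rate_kj = 6, off = integer(0)) {
  on_body <- rep(TRUE, 1440)
  on_body[off] <- FALSE
  swa_day("P1", "2013-03-06", rep(rate_kj, 1440), on_body)
}

complete_questionnaire <- function(n = 4, seed = 99) {
  withr::with_seed(seed, {
    cfg <- instrument_config()
    out <- tibble::tibble(participant_id = sprintf("Q%02d", seq_len(n)))
    for (nm in names(cfg$instruments)) {
      ins <- cfg$instruments[[nm]]
      for (it in unlist(ins$items)) {
        out[[it]] <- sample(ins$scale_min:ins$scale_max, n, TRUE)
      }
    }
    out$frs_current <- sample(1:9, n, TRUE)
    out$frs_ideal <- sample(1:9, n, TRUE)
    out$breakfast_days <- sample(0:7, n, TRUE)
    out$school_lunch_days <- sample(0:5, n, TRUE)
    for (f in unlist(cfg$attitude$items)) {
      out[[f]] <- sample(c("yes", "somewhat", "no"), n, TRUE)
    }
    out
  })
}

small_study <- function(seed = 11, n = 12) {
  generate_study(sim_config(seed = seed, n_participants = n))
}
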