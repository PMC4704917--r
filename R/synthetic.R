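#' Configuration for the synthetic-study generator
#'
#' Defaults describe an adolescent validation cohort: 81 participants
#' (50 girls / 31 boys), ages around 15.5 y, about three recording days
#' each with weekend days oversampled to ~40 %, a group-level reporting
#' ratio (EI over measured TEE) of 0.71, and app TEE inflated 1.19-fold
#' relative to the armband. Anthropometry is drawn per sex around the
#' cohort medians (girls ~165 cm, boys ~176 cm; BMI z centred near 0.4).
#'
#' @param seed Integer seed fixing every draw.
#' @param n_participants Cohort size.
#' @param prop_girls Proportion of girls.
#' @param n_day_probs Probabilities for 1-6 recording days (mode 3).
#' @param prop_weekend_days Target share of weekend recording days.
#' @param underreport_ratio Group-level target median EI/TEE.
#' @param bmi_z_bias_slope Change in relative reporting accuracy per BMI
#'   z-score unit (0 = off; applied centred, so the cohort-level ratio
#'   target is untouched).
#' @param weekend_bias Additive kJ/day accuracy shift for participants
#'   whose record contains a weekend day (0 = off; applied centred).
#' @param ratio_between_sd Between-participant SD of the log reporting
#'   ratio.
#' @param ei_day_cv Within-participant day-to-day CV of reported intake.
#' @param tee_day_cv Day-to-day CV of true TEE around BMR x true PAL.
#' @param swa_noise_cv CV of the armband's multiplicative day-level
#'   measurement noise.
#' @param true_pal_mean,true_pal_sd True physical-activity-level
#'   distribution (truncated to `[1.25, 1.9]`).
#' @param pal_overstatement Target cohort ratio of app TEE to armband TEE;
#'   reported activity answers are drawn to hit it.
#' @param pal_jitter_prob Probability a reported activity answer moves one
#'   level away from its target (symmetric).
#' @param wear_gap Off-body model: `mean`, `sd`, `max` minutes of the usual
#'   daily gap plus `long_prob` chance of a long (5-11 h) gap that fails
#'   the wear filter.
#' @param missing_rate Questionnaire missingness: a single per-cell
#'   probability (default gives roughly a fifth of participants >= 1
#'   missing answer over the 53 items), or a named list of per-field rates
#'   with a `default` entry.
#' @param n_foods,n_schools Food-database and school-count settings.
#' @param start_date First Monday of the fieldwork calendar.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_participants = 81L,
                       prop_girls = 50 / 81,
                       n_day_probs = c(0.12, 0.14, 0.67, 0.05, 0.015, 0.005),
                       prop_weekend_days = 0.4,
                       underreport_ratio = 0.71,
                       bmi_z_bias_slope = 0,
                       weekend_bias = 0,
                       ratio_between_sd = 0.35,
                       ei_day_cv = 0.25,
                       tee_day_cv = 0.07,
                       swa_noise_cv = 0.10,
                       true_pal_mean = 1.48,
                       true_pal_sd = 0.12,
                       pal_overstatement = 1.19,
                       pal_jitter_prob = 0.15,
                       wear_gap = list(mean = 60, sd = 45, max = 300,
                                       long_prob = 0.05),
                       missing_rate = 0.004,
                       n_foods = 60L,
                       n_schools = 12L,
                       start_date = as.Date("2013-01-07")) {
  cfg <- as.list(environment())
  stopifnot(cfg$underreport_ratio > 0, cfg$pal_overstatement > 0,
            cfg$prop_girls >= 0, cfg$prop_girls <= 1,
            abs(sum(cfg$n_day_probs) - 1) < 1e-8)
  structure(cfg, class = "sim_config")
}

rlnorm_med1 <- function(n, sdlog) exp(rnorm(n, 0, sdlog))
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic food-composition database
#'
#' At least 50 foods across at least 10 groups. Energy is consistent with
#' the macronutrient content through the generator's energy factors
#' (17 kJ/g protein and carbohydrate, 37 kJ/g fat); every food carries a
#' `gram` unit plus group-typical portion units.
#'
#' @param config A [sim_config()] (only `n_foods` is used); the caller is
#'   responsible for seeding.
#' @return A [food_db()].
#' @export
generate_food_db <- function(config = sim_config()) {
  groups <- tibble::tribble(
    ~food_group, ~p_g, ~c_g, ~f_g, ~extra_unit, ~gw_lo, ~gw_hi,
    "Bread", 9, 45, 4, "piece", 25, 60,
    "Breakfast cereals", 10, 60, 6, "deciliter", 30, 50,
    "Milk and yogurt", 3.5, 5, 2.5, "deciliter", 98, 105,
    "Cheese and eggs", 20, 2, 22, "piece", 15, 60,
    "Fruit", 0.8, 12, 0.3, "piece", 80, 180,
    "Vegetables", 2, 5, 0.4, "piece", 50, 150,
    "Meat and poultry", 20, 2, 12, "piece", 60, 150,
    "Fish and seafood", 19, 1, 8, "piece", 60, 150,
    "Potatoes pasta rice", 3, 22, 1, "deciliter", 60, 90,
    "Sweets and snacks", 5, 55, 22, "piece", 10, 40,
    "Soft drinks and juice", 0.2, 9, 0.1, "deciliter", 100, 104,
    "Sauces and fats", 2, 6, 35, "tablespoon", 12, 18)
  n <- max(config$n_foods, 50L)
  idx <- rep(seq_len(nrow(groups)), length.out = n)
  g <- groups[idx, ]
  jitter <- function(x) x * runif(n, 0.7, 1.3)
  protein <- round(jitter(g$p_g), 1)
  carb <- round(jitter(g$c_g), 1)
  fat <- round(jitter(g$f_g), 1)
  items <- tibble::tibble(
    food_id = sprintf("F%03d", seq_len(n)),
    name = paste(g$food_group, "item", sprintf("%02d", seq_len(n))),
    food_group = g$food_group,
    energy_kj_per_100g = round(17 * protein + 17 * carb + 37 * fat, 1),
    protein_g = protein, carbohydrate_g = carb, fat_g = fat,
    fiber_g = round(runif(n, 0, 6), 1),
    calcium_mg = round(runif(n, 5, 250)),
    iron_mg = round(runif(n, 0.1, 6), 2),
    vitamin_c_mg = round(runif(n, 0, 60), 1),
    vitamin_d_ug = round(runif(n, 0, 8), 2),
    folate_ug = round(runif(n, 2, 120)))
  units <- tibble::tibble(
    food_id = items$food_id, unit_name = g$extra_unit,
    gram_weight = round(runif(n, g$gw_lo, g$gw_hi)))
  food_db(items, units, version = "synthetic-1")
}

#' Generate a complete synthetic study
#'
#' Draws a cohort with anthropometrics, per-day true energy expenditure
#' (Schofield BMR x a true PAL with day-to-day variation), minute-level
#' armband traces with off-body gaps, reported activity answers calibrated
#' so cohort app TEE / armband TEE targets `pal_overstatement`, and diet
#' records whose computed intake matches the biased reported intake
#' (`true TEE x reporting ratio`) to within meal-composition rounding.
#' Reporting bias is multiplicative log-normal per participant with median
#' `underreport_ratio`; optional BMI-z and weekend-record accuracy effects
#' are applied centred so they leave the cohort target unchanged.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_study` list: `food_db`, `participants`,
#'   `diet_records`, `daily_questions`, `swa_trace`, `questionnaire`,
#'   `truth`, `config`.
#' @export
generate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  db <- generate_food_db(config)
  ref <- load_lms_reference()

  n <- config$n_participants
  profile_date <- config$start_date + 120
  gender <- ifelse(seq_len(n) <= round(n * config$prop_girls),
                   "female", "male")
  age <- clamp(rnorm(n, 15.5, 0.35), 14.05, 16.0)
  height <- ifelse(gender == "female",
                   clamp(rnorm(n, 165, 10), 148, 185),
                   clamp(rnorm(n, 176.5, 8.9), 155, 200))
  z_true <- clamp(rnorm(n, 0.44, 0.62), -2.5, 3)
  bmi_v <- bmi_from_zscore(z_true, age, gender, ref)
  weight <- round(bmi_v * (height / 100)^2, 1)
  height <- round(height, 1)
  participants <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    gender = gender,
    birth_date = profile_date - round(age * 365.25),
    weight_kg = weight, height_cm = height,
    parental_education = sample(c("low", "medium", "high"), n, TRUE,
                                prob = c(0.19, 0.32, 0.49)),
    born_outside_sweden = sample(
      c("none", "only_parents", "only_participant", "participant_and_parents"),
      n, TRUE, prob = c(0.72, 0.25, 0.01, 0.02)),
    school = sample(sprintf("school_%02d", seq_len(config$n_schools)), n,
                    TRUE),
    special_diet = ifelse(runif(n) < 0.06,
                          sample(c("lactose_free", "gluten_free",
                                   "vegetarian"), n, TRUE), NA_character_))
  participants$age_years <- age_years(participants$birth_date, profile_date)
  participants$bmr_kj <- schofield_bmr(gender, participants$age_years,
                                       weight)
  true_pal <- clamp(rnorm(n, config$true_pal_mean, config$true_pal_sd),
                    1.25, 1.9)

  # recording windows: start weekday weighted toward Thu-Sun so ~40 % of
  # recorded days are weekend days
  n_days <- sample(1:6, n, TRUE, prob = config$n_day_probs)
  wd_start <- sample(1:7, n, TRUE,
                     prob = c(0.08, 0.08, 0.08, 0.16, 0.22, 0.22, 0.16))
  week <- sample(0:44, n, TRUE)
  start <- config$start_date + week * 7 + (wd_start - 1)

  day_tbl <- tibble::tibble(
    participant_id = rep(participants$participant_id, n_days),
    gender = rep(gender, n_days),
    bmr_kj = rep(participants$bmr_kj, n_days),
    true_pal = rep(true_pal, n_days),
    date = as.Date(unlist(purrr::map2(start, n_days,
                                      ~.x + seq_len(.y) - 1)),
                   origin = "1970-01-01"))
  day_tbl$is_weekend <- is_weekend(day_tbl$date)
  nd <- nrow(day_tbl)

  # true and measured expenditure
  day_tbl$tee_true <- day_tbl$bmr_kj * day_tbl$true_pal *
    rlnorm_med1(nd, cv_to_sdlog(config$tee_day_cv))
  day_tbl$tee_measured <- day_tbl$tee_true *
    rlnorm_med1(nd, cv_to_sdlog(config$swa_noise_cv))

  # off-body gaps: a usual short gap plus rare long non-wear
  gap <- round(clamp(rnorm(nd, config$wear_gap$mean, config$wear_gap$sd),
                     0, config$wear_gap$max))
  long <- runif(nd) < config$wear_gap$long_prob
  gap[long] <- round(runif(sum(long), 310, 660))
  day_tbl$off_minutes <- gap

  # reported activity answers: nearest level to the overstated true PAL.
  # Off-body minutes sit in the daytime part of the trace and are imputed
  # at basal rate downstream, shrinking the armband day total by
  # off/1440 * (day_weight - 1/PAL); the calibration applies the same
  # factor so the cohort app/armband ratio targets pal_overstatement.
  day_weight <- trace_day_weight()
  shrink <- 1 - day_tbl$off_minutes *
    (day_weight - 1 / day_tbl$true_pal) / 1440
  pal_target <- day_tbl$true_pal * config$pal_overstatement * shrink
  grid <- vapply(day_tbl$gender, function(g) pal_value(g, activity_levels()),
                 numeric(5))
  lev_idx <- apply(abs(t(grid) - pal_target), 1, which.min)
  jit <- sample(c(-1L, 0L, 1L), nd, TRUE,
                prob = c(config$pal_jitter_prob / 2,
                         1 - config$pal_jitter_prob,
                         config$pal_jitter_prob / 2))
  lev_idx <- clamp(lev_idx + jit, 1L, 5L)
  day_tbl$activity_level <- activity_levels()[lev_idx]
  day_tbl$pal_reported <- pal_value(day_tbl$gender, day_tbl$activity_level)
  day_tbl$tee_app_kj <- day_tbl$bmr_kj * day_tbl$pal_reported

  # reporting ratio: per-participant log-normal (median underreport_ratio),
  # with optional centred BMI-z and weekend-record accuracy effects
  ratio_i <- pmax(
    config$underreport_ratio * rlnorm_med1(n, config$ratio_between_sd) +
      config$bmi_z_bias_slope * (z_true - mean(z_true)),
    0.2)
  has_wk <- vapply(split(day_tbl$is_weekend, day_tbl$participant_id), any,
                   logical(1))[participants$participant_id]
  wk_shift <- config$weekend_bias * (as.numeric(has_wk) - mean(has_wk))
  pid_idx <- match(day_tbl$participant_id, participants$participant_id)
  sd_day <- cv_to_sdlog(config$ei_day_cv)
  day_tbl$ei_target <- pmax(
    day_tbl$tee_true * ratio_i[pid_idx] *
      exp(rnorm(nd, -sd_day^2 / 2, sd_day)) + wk_shift[pid_idx],
    600)

  swa_trace <- build_swa_trace(day_tbl)
  diet_records <- build_diet_records(day_tbl, db)
  daily_questions <- tibble::tibble(
    participant_id = day_tbl$participant_id, date = day_tbl$date,
    activity_level = day_tbl$activity_level,
    fraction_recorded = sample(c("95 to 100%", "75 to 94%", "50 to 74%",
                                 "below 50%"), nd, TRUE,
                               prob = c(0.76, 0.16, 0.06, 0.02)),
    supplements = ifelse(runif(nd) < 0.1, "multivitamin", ""),
    tried_change_weight = runif(nd) < 0.15,
    diet_higher_lower_than_usual = sample(c("lower", "as_usual", "higher"),
                                          nd, TRUE, c(0.2, 0.6, 0.2)),
    activity_higher_lower_than_usual = sample(
      c("lower", "as_usual", "higher"), nd, TRUE, c(0.2, 0.6, 0.2)),
    felt_stressed = runif(nd) < 0.4,
    felt_anxious = runif(nd) < 0.4)
  questionnaire <- generate_questionnaires(
    dplyr::mutate(participants, bmi_z = z_true), config)

  truth <- tibble::tibble(
    participant_id = participants$participant_id,
    true_pal = true_pal, bmi_z = z_true,
    reporting_ratio = ratio_i,
    has_weekend_day = unname(has_wk),
    mean_true_tee_kj = vapply(split(day_tbl$tee_true,
                                    day_tbl$participant_id),
                              mean, numeric(1))[participants$participant_id])

  structure(list(food_db = db, participants = participants,
                 diet_records = diet_records,
                 daily_questions = daily_questions,
                 swa_trace = swa_trace, questionnaire = questionnaire,
                 truth = truth, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> seed %d: %d participants, %d diet days, %d armband days\n",
    x$config$seed, nrow(x$participants),
    nrow(dplyr::distinct(x$diet_records, .data$participant_id, .data$date)),
    nrow(x$swa_trace) / 1440))
  invisible(x)
}

# diurnal profile shared by the trace builder and the PAL calibration:
# flat low night rate (minutes 0-419), higher day rate
trace_profile <- function() c(rep(0.6, 420), rep(1.164, 1020))

trace_day_weight <- function() {
  base <- trace_profile()
  base[421] / mean(base)
}

# minute-level traces: low flat night rate, higher day rate with jitter,
# normalised so on-body + imputed-at-device minutes carry tee_measured
build_swa_trace <- function(day_tbl) {
  nd <- nrow(day_tbl)
  n_min <- 1440L
  base <- trace_profile()
  purrr::map_dfr(seq_len(nd), function(i) {
    w <- base * runif(n_min, 0.85, 1.15)
    ee <- day_tbl$tee_measured[i] * w / sum(w)
    on_body <- rep(TRUE, n_min)
    gap <- day_tbl$off_minutes[i]
    if (gap > 0) {
      s <- sample(421:(n_min - gap), 1)
      on_body[s:(s + gap - 1)] <- FALSE
      # the device reports basal rate while off the body
      ee[!on_body] <- day_tbl$bmr_kj[i] / n_min
    }
    tibble::tibble(participant_id = day_tbl$participant_id[i],
                   date = day_tbl$date[i], minute = 0:(n_min - 1),
                   ee_kj = ee, on_body = on_body)
  })
}

# greedy meal composition: split the day's energy target over four meals
# and pick foods whose gram amounts reproduce each share
build_diet_records <- function(day_tbl, db) {
  meal_types <- c("breakfast", "lunch", "snack", "dinner")
  meal_times <- c("07:30", "12:00", "15:30", "18:30")
  shares <- c(0.22, 0.30, 0.15, 0.33)
  items <- db$items
  purrr::map_dfr(seq_len(nrow(day_tbl)), function(i) {
    e_day <- day_tbl$ei_target[i]
    sh <- shares * runif(4, 0.8, 1.2)
    sh <- sh / sum(sh)
    purrr::map_dfr(1:4, function(m) {
      e_meal <- e_day * sh[m]
      k <- sample(2:4, 1)
      rows <- items[sample.int(nrow(items), k), ]
      alloc <- runif(k, 0.5, 1.5)
      alloc <- e_meal * alloc / sum(alloc)
      grams <- 100 * alloc / rows$energy_kj_per_100g
      # record most items in grams, some in the food's portion unit
      unit_name <- rep("gram", k)
      amount <- round(grams, 1)
      alt <- db$units[db$units$food_id %in% rows$food_id &
                        db$units$unit_name != "gram", ]
      use_alt <- runif(k) < 0.35 & rows$food_id %in% alt$food_id
      for (j in which(use_alt)) {
        u <- alt[alt$food_id == rows$food_id[j], ][1, ]
        unit_name[j] <- u$unit_name
        amount[j] <- round(grams[j] / u$gram_weight, 2)
      }
      keep <- amount > 0
      tibble::tibble(participant_id = day_tbl$participant_id[i],
                     date = day_tbl$date[i], time = meal_times[m],
                     meal_type = meal_types[m],
                     food_id = rows$food_id[keep],
                     unit_name = unit_name[keep], amount = amount[keep])
    })
  })
}

#' Generate questionnaire responses with configurable missingness
#'
#' Item responses are drawn around person-level latent traits; the current
#' body-size figure tracks BMI z-score. Each cell is independently blanked
#' with probability `config$missing_rate` (about a fifth of respondents end
#' up with at least one missing answer at the default).
#'
#' @param participants Participant tibble; a `bmi_z` column, if present,
#'   drives the figure ratings.
#' @param config A [sim_config()]; the caller is responsible for seeding.
#' @return Wide response tibble for [impute_missing()] /
#'   [score_questionnaire()].
#' @export
generate_questionnaires <- function(participants, config = sim_config()) {
  n <- nrow(participants)
  cfg <- instrument_config()
  z <- if ("bmi_z" %in% names(participants)) participants$bmi_z else
    rnorm(n, 0.4, 0.6)
  out <- tibble::tibble(participant_id = participants$participant_id)
  for (nm in names(cfg$instruments)) {
    ins <- cfg$instruments[[nm]]
    trait <- rnorm(n)
    span <- ins$scale_max - ins$scale_min
    mid <- (ins$scale_min + ins$scale_max) / 2
    for (it in unlist(ins$items)) {
      raw <- mid + trait * span / 4 + rnorm(n, 0, span / 4)
      v <- clamp(round(raw), ins$scale_min, ins$scale_max)
      if (it %in% unlist(ins$reversed)) {
        v <- ins$scale_max + ins$scale_min - v
      }
      out[[it]] <- v
    }
  }
  out$frs_current <- clamp(round(5 + 1.2 * z + rnorm(n, 0, 0.8)), 1, 9)
  out$frs_ideal <- clamp(round(out$frs_current - 0.6 - 0.5 * z +
                                 rnorm(n, 0, 0.8)), 1, 9)
  out$breakfast_days <- sample(0:7, n, TRUE,
                               prob = c(rep(0.02, 4), 0.05, 0.08, 0.12,
                                        0.67))
  out$school_lunch_days <- sample(0:5, n, TRUE,
                                  prob = c(0.02, 0.03, 0.05, 0.08, 0.13,
                                           0.69))
  for (f in unlist(cfg$attitude$items)) {
    out[[f]] <- sample(c("yes", "somewhat", "no"), n, TRUE,
                       prob = c(0.55, 0.37, 0.08))
  }
  rates <- config$missing_rate
  default_rate <- if (is.list(rates)) rates$default %||% 0 else rates
  for (cl in setdiff(names(out), "participant_id")) {
    r <- if (is.list(rates)) rates[[cl]] %||% default_rate else default_rate
    if (r > 0) out[[cl]][runif(n) < r] <- NA
  }
  out
}

#' Run the evaluation pipeline over a synthetic study
#'
#' Computes daily intake from the diet records and food database, armband
#' day summaries from the minute traces, app TEE from the reported daily
#' activity answers, applies the inclusion filters, and evaluates every
#' participant.
#'
#' @param study A [generate_study()] result (or an equivalent list of
#'   tables).
#' @param ... Threshold overrides passed to [evaluate_cohort()].
#' @return The [evaluate_cohort()] result list, plus `ei_days`, `swa_days`
#'   and `app_days` tables.
#' @export
run_pipeline <- function(study, ...) {
  ei_days <- compute_intake_days(study$diet_records, study$food_db)
  swa_days <- tee_swa_days(study$swa_trace, study$participants)
  app_days <- dplyr::left_join(
    study$daily_questions[, c("participant_id", "date", "activity_level")],
    study$participants[, c("participant_id", "gender", "age_years",
                           "weight_kg")],
    by = "participant_id")
  app_days$tee_app_kj <- tee_app(app_days$gender, app_days$age_years,
                                 app_days$weight_kg,
                                 app_days$activity_level)
  res <- evaluate_cohort(ei_days, swa_days,
                         app_days[, c("participant_id", "date",
                                      "tee_app_kj")],
                         study$participants, ...)
  res$ei_days <- ei_days
  res$swa_days <- swa_days
  res$app_days <- app_days
  res
}

#' Write a synthetic study to disk
#'
#' Writes the CSV/JSON dialects used by the loaders plus a `truth.csv`
#' with the generating parameters per participant.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_food_db(study$food_db, file.path(dir, "food_db.json"))
  readr::write_csv(study$participants, file.path(dir, "participants.csv"),
                   progress = FALSE)
  write_diet_records(study$diet_records, file.path(dir, "diet_records.csv"))
  readr::write_csv(study$daily_questions,
                   file.path(dir, "daily_questions.csv"), progress = FALSE)
  write_swa_trace(study$swa_trace, file.path(dir, "swa_trace.csv"))
  readr::write_csv(study$questionnaire, file.path(dir, "questionnaire.csv"),
                   progress = FALSE)
  readr::write_csv(study$truth, file.path(dir, "truth.csv"),
                   progress = FALSE)
  invisible(dir)
}
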