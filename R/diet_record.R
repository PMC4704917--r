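#' Meal and day records
#'
#' A `meal_record` is one eating occasion: date, clock time, meal type
#' (breakfast, lunch, dinner or snack) and a table of recorded items
#' (`food_id`, `unit_name`, `amount`). A `diet_day` bundles all meals of one
#' participant-day with the optional evening questions.
#'
#' @param date Calendar date of the meal.
#' @param time Clock time as `"HH:MM"`.
#' @param meal_type One of `"breakfast"`, `"lunch"`, `"dinner"`, `"snack"`.
#' @param items Data frame with columns `food_id`, `unit_name`, `amount`
#'   (amounts must be non-negative).
#' @param photo_ref Optional free-text photo reference (inert metadata).
#' @return A `meal_record` object.
#' @export
meal_record <- function(date, time = "12:00",
                        meal_type = c("breakfast", "lunch", "dinner", "snack"),
                        items = NULL, photo_ref = NA_character_) {
  meal_type <- match.arg(meal_type)
  if (is.null(items)) {
    items <- tibble::tibble(food_id = character(), unit_name = character(),
                            amount = numeric())
  }
  items <- tibble::as_tibble(items)
  stopifnot(all(c("food_id", "unit_name", "amount") %in% names(items)))
  if (any(items$amount < 0 | !is.finite(items$amount))) {
    abort("Item amounts must be non-negative and finite.",
          class = "dietsense_argument_error")
  }
  structure(list(date = as.Date(date), time = time, meal_type = meal_type,
                 items = items, photo_ref = photo_ref),
            class = "meal_record")
}

#' @param participant_id Participant identifier.
#' @param meals List of [meal_record()] objects sharing `date`.
#' @param questions Optional named list of evening-question answers
#'   (`supplements`, `fraction_recorded`, `tried_change_weight`,
#'   `activity_level`, `diet_higher_lower_than_usual`,
#'   `activity_higher_lower_than_usual`, `felt_stressed`, `felt_anxious`).
#' @rdname meal_record
#' @export
diet_day <- function(participant_id, date, meals = list(), questions = NULL) {
  date <- as.Date(date)
  for (m in meals) {
    stopifnot(inherits(m, "meal_record"))
    if (m$date != date) {
      abort("All meals of a diet_day must share the day's date.",
            class = "dietsense_argument_error")
    }
  }
  if (!is.null(questions) && !is.null(questions$activity_level)) {
    stopifnot(questions$activity_level %in% activity_levels())
  }
  structure(list(participant_id = participant_id, date = date,
                 meals = meals, questions = questions),
            class = "diet_day")
}

#' @export
print.diet_day <- function(x, ...) {
  cat(sprintf("<diet_day> %s on %s: %d meal(s), %d item(s)\n",
              x$participant_id, format(x$date), length(x$meals),
              sum(vapply(x$meals, function(m) nrow(m$items), integer(1)))))
  invisible(x)
}

#' Energy and nutrients of one meal
#'
#' Each item contributes `grams / 100 * per-100g composition`; the meal is
#' the sum over items. Supplements recorded in the evening questions never
#' enter these totals.
#'
#' @param meal A [meal_record()].
#' @param db A [food_db()].
#' @return List with `energy_kj`, `nutrients` (named numeric),
#'   `grams_by_food_group` (named numeric).
#' @export
compute_meal_summary <- function(meal, db) {
  stopifnot(inherits(meal, "meal_record"), inherits(db, "food_db"))
  energy <- 0
  nutrients <- setNames(numeric(length(db$nutrients)), db$nutrients)
  groups <- numeric(0)
  for (i in seq_len(nrow(meal$items))) {
    it <- meal$items[i, ]
    food <- get_food(db, it$food_id)
    g <- to_grams(food, it$unit_name, it$amount)
    energy <- energy + g / 100 * food$energy_kj_per_100g
    if (length(db$nutrients) > 0) {
      nutrients <- nutrients + g / 100 * food$nutrients_per_100g[db$nutrients]
    }
    groups[food$food_group] <- zero_if_empty(groups[food$food_group]) + g
  }
  list(energy_kj = energy, nutrients = nutrients,
       grams_by_food_group = groups)
}

zero_if_empty <- function(x) {
  if (length(x) == 0 || is.na(x)) 0 else as.numeric(x)
}

#' Daily intake summary
#'
#' @param day A [diet_day()].
#' @param db A [food_db()].
#' @return List with `energy_kj` (kJ/day), `nutrients` (named daily
#'   amounts), `per_meal_energy_kj` (named by `"<position>_<meal_type>"`),
#'   and `food_group_grams`.
#' @export
compute_day_intake <- function(day, db) {
  stopifnot(inherits(day, "diet_day"))
  per_meal <- numeric(0)
  nutrients <- setNames(numeric(length(db$nutrients)), db$nutrients)
  groups <- numeric(0)
  for (i in seq_along(day$meals)) {
    ms <- compute_meal_summary(day$meals[[i]], db)
    per_meal[paste0(i, "_", day$meals[[i]]$meal_type)] <- ms$energy_kj
    nutrients <- nutrients + ms$nutrients
    for (gname in names(ms$grams_by_food_group)) {
      groups[gname] <- zero_if_empty(groups[gname]) +
        ms$grams_by_food_group[[gname]]
    }
  }
  list(energy_kj = sum(per_meal), nutrients = nutrients,
       per_meal_energy_kj = per_meal,
       food_group_grams = groups[order(names(groups))])
}

#' Intake relative to recommended daily amounts
#'
#' @param summary Output of [compute_day_intake()].
#' @param recommendations Named numeric vector of recommended daily amounts;
#'   must include `energy_kj` for the per-meal energy percentages. All
#'   entries must be positive.
#' @return List with `ratios` (intake / recommendation per shared nutrient,
#'   plus `energy_kj`) and `per_meal_energy_pct` (meal kJ as a percentage of
#'   recommended daily kJ).
#' @export
feedback_report <- function(summary, recommendations) {
  if (any(recommendations <= 0 | !is.finite(recommendations))) {
    abort("Recommended amounts must be positive.",
          class = "dietsense_argument_error")
  }
  keys <- intersect(names(recommendations),
                    c("energy_kj", names(summary$nutrients)))
  intake <- c(energy_kj = summary$energy_kj, summary$nutrients)[keys]
  ratios <- intake / recommendations[keys]
  pct <- NULL
  if ("energy_kj" %in% names(recommendations)) {
    pct <- summary$per_meal_energy_kj / recommendations[["energy_kj"]] * 100
  }
  list(ratios = ratios, per_meal_energy_pct = pct)
}

#' Edit a saved day
#'
#' Returns a new `diet_day`; the input is never modified. Adding an item and
#' then deleting it restores the original day.
#'
#' @param day A [diet_day()].
#' @param action `"add"`, `"delete"` or `"update"`.
#' @param meal Index of the target meal.
#' @param item For `"add"`: a one-row data frame / list with `food_id`,
#'   `unit_name`, `amount`. For `"delete"`/`"update"`: the item row index.
#' @param amount New amount for `"update"`.
#' @return The edited [diet_day()].
#' @export
edit_day <- function(day, action = c("add", "delete", "update"),
                     meal, item = NULL, amount = NULL) {
  stopifnot(inherits(day, "diet_day"))
  action <- match.arg(action)
  if (meal < 1 || meal > length(day$meals)) {
    abort("No such meal in this day.", class = "dietsense_index_error")
  }
  m <- day$meals[[meal]]
  if (action == "add") {
    m$items <- dplyr::bind_rows(m$items, tibble::as_tibble(item))
  } else {
    if (is.null(item) || item < 1 || item > nrow(m$items)) {
      abort("No such item in this meal.", class = "dietsense_index_error")
    }
    if (action == "delete") {
      m$items <- m$items[-item, ]
    } else {
      if (is.null(amount) || amount < 0) {
        abort("`amount` must be a non-negative number.",
              class = "dietsense_argument_error")
      }
      m$items$amount[item] <- amount
    }
  }
  day$meals[[meal]] <- m
  day
}

#' Read / write long-format diet records
#'
#' Long CSV layout: one row per recorded item with columns
#' `participant_id, date, time, meal_type, food_id, unit_name, amount`.
#'
#' @param path CSV path.
#' @return A tibble of item rows.
#' @export
read_diet_records <- function(path) {
  req <- c("participant_id", "date", "time", "meal_type", "food_id",
           "unit_name", "amount")
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         participant_id = readr::col_character(),
                         food_id = readr::col_character(),
                         time = readr::col_character(),
                         .default = readr::col_guess()))
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Diet-record file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "dietsense_schema_error")
  }
  x$date <- as.Date(x$date)
  x
}

#' @param records Tibble of item rows as returned by [read_diet_records()].
#' @rdname read_diet_records
#' @export
write_diet_records <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Assemble diet_day objects from long-format records
#'
#' Meals are formed by unique (time, meal_type) within a participant-day,
#' ordered by time.
#'
#' @param records Long-format item rows.
#' @return List of [diet_day()] objects.
#' @export
records_to_days <- function(records) {
  records <- dplyr::arrange(records, .data$participant_id, .data$date,
                            .data$time)
  keys <- dplyr::distinct(records, .data$participant_id, .data$date)
  purrr::pmap(keys, function(participant_id, date) {
    sub <- records[records$participant_id == participant_id &
                     records$date == date, ]
    mk <- dplyr::distinct(sub, .data$time, .data$meal_type)
    meals <- purrr::pmap(mk, function(time, meal_type) {
      its <- sub[sub$time == time & sub$meal_type == meal_type,
                 c("food_id", "unit_name", "amount")]
      meal_record(date, time, meal_type, its)
    })
    diet_day(participant_id, date, meals)
  })
}

#' Daily energy intake table for a whole study
#'
#' Vectorised pipeline version of [compute_day_intake()]: joins the item
#' rows against the food database and sums energy per participant-day.
#'
#' @param records Long-format item rows (see [read_diet_records()]).
#' @param db A [food_db()].
#' @return Tibble `participant_id, date, ei_kj, is_weekend` with one row per
#'   participant-day.
#' @export
compute_intake_days <- function(records, db) {
  stopifnot(inherits(db, "food_db"))
  unknown <- setdiff(unique(records$food_id), db$items$food_id)
  if (length(unknown) > 0) {
    abort(paste0("Unknown food_id in records: ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "dietsense_lookup_error")
  }
  joined <- dplyr::left_join(records, db$units,
                             by = c("food_id", "unit_name"))
  if (any(is.na(joined$gram_weight))) {
    bad <- joined[is.na(joined$gram_weight), ]
    abort(sprintf("Unit '%s' is not defined for food '%s'.",
                  bad$unit_name[1], bad$food_id[1]),
          class = "dietsense_lookup_error")
  }
  joined <- dplyr::left_join(
    joined, db$items[, c("food_id", "energy_kj_per_100g")], by = "food_id")
  joined$item_kj <- joined$amount * joined$gram_weight / 100 *
    joined$energy_kj_per_100g
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$participant_id, .data$date),
    ei_kj = sum(.data$item_kj), .groups = "drop")
  out$is_weekend <- is_weekend(out$date)
  out
}

#' Weekend test for dates
#' @param date A `Date` vector.
#' @return Logical: `TRUE` for Saturdays and Sundays.
#' @export
is_weekend <- function(date) {
  format(as.Date(date), "%u") %in% c("6", "7")
}
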