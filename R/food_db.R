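#' Food-composition databases
#'
#' A `food_db` holds foods and dishes with per-100 g energy (kJ) and an open
#' vocabulary of nutrient columns, plus the portion units (gram, deciliter,
#' tablespoon, ...) each food can be recorded in, with their gram weights.
#' Every food always carries a `gram` unit of weight 1 g.
#'
#' @param items Data frame with columns `food_id`, `name`, `food_group`,
#'   `energy_kj_per_100g`, and one numeric column per nutrient (per 100 g).
#' @param units Data frame with columns `food_id`, `unit_name`,
#'   `gram_weight` (g per 1 unit). A `gram` unit is added automatically for
#'   foods that lack one.
#' @param version Free-text version tag.
#' @return An object of class `food_db` with elements `items`, `units`,
#'   `nutrients` (nutrient column names) and `version`.
#' @examples
#' db <- food_db(
#'   items = tibble::tibble(
#'     food_id = "f1", name = "Milk", food_group = "Dairy",
#'     energy_kj_per_100g = 190, protein_g = 3.4),
#'   units = tibble::tibble(food_id = "f1", unit_name = "deciliter",
#'                          gram_weight = 103))
#' to_grams(get_food(db, "f1"), "deciliter", 2)
#' @export
food_db <- function(items, units = NULL, version = "unversioned") {
  items <- tibble::as_tibble(items)
  required <- c("food_id", "name", "food_group", "energy_kj_per_100g")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("Food table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "dietsense_schema_error")
  }
  items$food_id <- as.character(items$food_id)
  if (anyDuplicated(items$food_id)) {
    dup <- unique(items$food_id[duplicated(items$food_id)])
    abort(paste0("Duplicate food_id: ", paste(dup, collapse = ", ")),
          class = "dietsense_duplicate_key_error")
  }
  nutrients <- setdiff(names(items), required)
  nutrients <- nutrients[vapply(items[nutrients], is.numeric, logical(1))]
  if (any(items$energy_kj_per_100g < 0, na.rm = FALSE) ||
      any(!is.finite(items$energy_kj_per_100g))) {
    abort("energy_kj_per_100g must be non-negative and finite.",
          class = "dietsense_schema_error")
  }
  for (nc in nutrients) {
    if (any(items[[nc]] < 0, na.rm = TRUE)) {
      abort(sprintf("Nutrient column '%s' has negative values.", nc),
            class = "dietsense_schema_error")
    }
  }
  if (is.null(units)) {
    units <- tibble::tibble(food_id = character(), unit_name = character(),
                            gram_weight = numeric())
  }
  units <- tibble::as_tibble(units)
  units$food_id <- as.character(units$food_id)
  if (nrow(units) > 0) {
    if (any(units$gram_weight <= 0 | !is.finite(units$gram_weight))) {
      abort("Portion-unit gram weights must be positive.",
            class = "dietsense_schema_error")
    }
    stray <- setdiff(units$food_id, items$food_id)
    if (length(stray) > 0) {
      abort(paste0("Units reference unknown food_id: ",
                   paste(head(stray, 5), collapse = ", ")),
            class = "dietsense_schema_error")
    }
  }
  # every food records in grams; enforce the invariant here
  need_gram <- setdiff(items$food_id,
                       units$food_id[units$unit_name == "gram"])
  if (length(need_gram) > 0) {
    units <- dplyr::bind_rows(
      units,
      tibble::tibble(food_id = need_gram, unit_name = "gram",
                     gram_weight = 1))
  }
  units <- dplyr::arrange(units, .data$food_id, .data$unit_name)
  structure(
    list(items = items, units = units, nutrients = nutrients,
         version = as.character(version)),
    class = "food_db")
}

#' @export
print.food_db <- function(x, ...) {
  cat(sprintf("<food_db> %d foods, %d nutrient columns, version '%s'\n",
              nrow(x$items), length(x$nutrients), x$version))
  cat("food groups:", paste(sort(unique(x$items$food_group)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Load a food-composition database from CSV or JSON
#'
#' CSV layout: `food_id,name,food_group,energy_kj_per_100g`, one column per
#' nutrient, and portion units encoded as `unit:<name>` columns holding the
#' gram weight (empty where a food lacks the unit). JSON holds an object
#' with `version` and an `items` array of nested food records.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return A [food_db].
#' @export
load_food_db <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    abort(paste0("Food database file not found: ", path),
          class = "dietsense_schema_error")
  }
  if (format == "csv") {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    unit_cols <- grep("^unit:", names(raw), value = TRUE)
    items <- raw[setdiff(names(raw), unit_cols)]
    units <- NULL
    if (length(unit_cols) > 0) {
      units <- tidyr::pivot_longer(
        raw[c("food_id", unit_cols)], cols = dplyr::all_of(unit_cols),
        names_to = "unit_name", names_prefix = "unit:",
        values_to = "gram_weight", values_drop_na = TRUE)
    }
    version <- "unversioned"
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    version <- obj$version %||% "unversioned"
    items <- purrr::map_dfr(obj$items, function(it) {
      base <- tibble::tibble(
        food_id = it$food_id, name = it$name, food_group = it$food_group,
        energy_kj_per_100g = it$energy_kj_per_100g)
      for (nm in names(it$nutrients_per_100g)) {
        base[[nm]] <- it$nutrients_per_100g[[nm]]
      }
      base
    })
    units <- purrr::map_dfr(obj$items, function(it) {
      purrr::map_dfr(it$units, function(u) {
        tibble::tibble(food_id = it$food_id, unit_name = u$name,
                       gram_weight = u$gram_weight)
      })
    })
  }
  food_db(items, units, version = version)
}

#' Save a food-composition database
#'
#' JSON output round-trips through [load_food_db()] to an identical
#' database.
#'
#' @param db A [food_db].
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @export
save_food_db <- function(db, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(db, "food_db"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    wide_units <- tidyr::pivot_wider(
      db$units, names_from = "unit_name", values_from = "gram_weight",
      names_prefix = "unit:")
    out <- dplyr::left_join(db$items, wide_units, by = "food_id")
    readr::write_csv(out, path, progress = FALSE)
  } else {
    items <- purrr::pmap(db$items, function(...) {
      row <- list(...)
      nut <- row[db$nutrients]
      uns <- db$units[db$units$food_id == row$food_id, ]
      list(food_id = row$food_id, name = row$name,
           food_group = row$food_group,
           energy_kj_per_100g = row$energy_kj_per_100g,
           nutrients_per_100g = nut,
           units = purrr::map2(uns$unit_name, uns$gram_weight,
                               ~list(name = .x, gram_weight = .y)))
    })
    jsonlite::write_json(list(version = db$version, items = items), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Free-text food search
#'
#' Case-insensitive substring match on food names, ordered by match
#' position (earlier is better) and then alphabetically.
#'
#' @param query Non-empty search string.
#' @param db A [food_db].
#' @param limit Maximum number of results.
#' @return The matching rows of `db$items`, best match first.
#' @export
search_foods <- function(query, db, limit = 20L) {
  stopifnot(inherits(db, "food_db"))
  query <- trimws(query)
  if (!is.character(query) || length(query) != 1 || nchar(query) == 0) {
    abort("`query` must be a single non-empty string.",
          class = "dietsense_argument_error")
  }
  pos <- regexpr(tolower(query), tolower(db$items$name), fixed = TRUE)
  hit <- pos > 0
  res <- db$items[hit, ]
  res <- res[order(pos[hit], res$name), ]
  head(res, limit)
}

#' Look up one food by id
#'
#' @param db A [food_db].
#' @param food_id Food identifier.
#' @return A list with `food_id`, `name`, `food_group`,
#'   `energy_kj_per_100g`, `nutrients_per_100g` (named numeric) and `units`
#'   (named numeric of gram weights).
#' @export
get_food <- function(db, food_id) {
  stopifnot(inherits(db, "food_db"))
  i <- match(as.character(food_id), db$items$food_id)
  if (is.na(i)) {
    abort(paste0("Unknown food_id: ", food_id),
          class = "dietsense_lookup_error")
  }
  row <- db$items[i, ]
  uns <- db$units[db$units$food_id == row$food_id, ]
  list(food_id = row$food_id, name = row$name, food_group = row$food_group,
       energy_kj_per_100g = row$energy_kj_per_100g,
       nutrients_per_100g = unlist(row[db$nutrients]) %||%
         setNames(numeric(0), character(0)),
       units = setNames(uns$gram_weight, uns$unit_name))
}

#' Convert a recorded portion to grams
#'
#' @param food A food record from [get_food()].
#' @param unit_name One of the food's portion units.
#' @param amount Non-negative number of units.
#' @return Mass in grams (`amount * gram_weight`).
#' @export
to_grams <- function(food, unit_name, amount) {
  if (!is.numeric(amount) || length(amount) != 1 || !is.finite(amount) ||
      amount < 0) {
    abort("`amount` must be a single non-negative number.",
          class = "dietsense_argument_error")
  }
  gw <- unname(food$units[match(unit_name, names(food$units))])
  if (length(gw) != 1 || is.na(gw)) {
    abort(sprintf("Food '%s' has no unit '%s'; available: %s",
                  food$name, unit_name,
                  paste(names(food$units), collapse = ", ")),
          class = "dietsense_lookup_error")
  }
  amount * gw
}

`%||%` <- function(a, b) if (is.null(a)) b else a
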