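#' Minute-level armband day record
#'
#' One participant-day of armband output: exactly 1440 minute slots with
#' the energy expended that minute (kJ) and an on-body flag.
#'
#' @param participant_id Participant identifier.
#' @param date Calendar date.
#' @param ee_kj Numeric vector of length 1440, kJ per minute, non-negative.
#' @param on_body Logical vector of length 1440.
#' @return An object of class `swa_day`.
#' @export
swa_day <- function(participant_id, date, ee_kj, on_body) {
  if (length(ee_kj) != 1440 || length(on_body) != 1440) {
    abort("An armband day needs exactly 1440 minute slots.",
          class = "dietsense_argument_error")
  }
  if (any(ee_kj < 0 | !is.finite(ee_kj))) {
    abort("Minute energy expenditure must be non-negative.",
          class = "dietsense_argument_error")
  }
  structure(list(participant_id = participant_id, date = as.Date(date),
                 ee_kj = as.numeric(ee_kj), on_body = as.logical(on_body)),
            class = "swa_day")
}

#' @export
print.swa_day <- function(x, ...) {
  cat(sprintf("<swa_day> %s on %s: %.1f h worn, %.0f kJ recorded on-body\n",
              x$participant_id, format(x$date), wear_hours(x),
              sum(x$ee_kj[x$on_body])))
  invisible(x)
}

#' Hours the armband was worn
#'
#' @param rec A [swa_day()].
#' @return On-body minutes / 60, in `[0, 24]`.
#' @export
wear_hours <- function(rec) {
  stopifnot(inherits(rec, "swa_day"))
  sum(rec$on_body) / 60
}

#' Daily reference TEE from an armband trace
#'
#' Sums the on-body minute values; minutes the device was off the body are
#' imputed at the basal rate, `bmr_kj / 1440` per minute, mirroring the
#' device's own off-body behaviour.
#'
#' @param rec A [swa_day()].
#' @param bmr_kj The participant's BMR in kJ/day (see [schofield_bmr()]).
#' @return TEE in kJ/day.
#' @export
tee_swa <- function(rec, bmr_kj) {
  stopifnot(inherits(rec, "swa_day"))
  check_positive(bmr_kj, "bmr_kj")
  sum(rec$ee_kj[rec$on_body]) + sum(!rec$on_body) * bmr_kj / 1440
}

#' Vectorised armband day summaries
#'
#' @param trace Long tibble with columns `participant_id`, `date`,
#'   `minute` (0-1439), `ee_kj`, `on_body` (logical or 0/1).
#' @param participants Tibble with `participant_id` and `bmr_kj` used for
#'   off-body imputation.
#' @return Tibble `participant_id, date, tee_swa_kj, wear_hours,
#'   is_weekend`, one row per participant-day.
#' @export
tee_swa_days <- function(trace, participants) {
  stopifnot(all(c("participant_id", "date", "minute", "ee_kj", "on_body")
                %in% names(trace)),
            all(c("participant_id", "bmr_kj") %in% names(participants)))
  counts <- dplyr::count(trace, .data$participant_id, .data$date)
  if (any(counts$n != 1440)) {
    abort("Every armband day must have exactly 1440 minute rows.",
          class = "dietsense_schema_error")
  }
  trace$on_body <- as.logical(trace$on_body)
  day <- dplyr::summarise(
    dplyr::group_by(trace, .data$participant_id, .data$date),
    on_kj = sum(.data$ee_kj[.data$on_body]),
    off_minutes = sum(!.data$on_body), .groups = "drop")
  day <- dplyr::left_join(day,
                          participants[, c("participant_id", "bmr_kj")],
                          by = "participant_id")
  if (any(is.na(day$bmr_kj))) {
    abort("Armband trace contains participants without a BMR.",
          class = "dietsense_schema_error")
  }
  tibble::tibble(
    participant_id = day$participant_id, date = day$date,
    tee_swa_kj = day$on_kj + day$off_minutes * day$bmr_kj / 1440,
    wear_hours = (1440 - day$off_minutes) / 60,
    is_weekend = is_weekend(day$date))
}

#' Read / write a minute-level armband trace CSV
#'
#' Columns: `participant_id, date, minute, ee_kj, on_body` (0/1).
#'
#' @param path CSV path.
#' @return Tibble of minute rows with logical `on_body`.
#' @export
read_swa_trace <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         participant_id = readr::col_character(),
                         .default = readr::col_guess()))
  req <- c("participant_id", "date", "minute", "ee_kj", "on_body")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Armband trace is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "dietsense_schema_error")
  }
  x$date <- as.Date(x$date)
  x$on_body <- as.logical(x$on_body)
  x
}

#' @param trace Minute rows as read by [read_swa_trace()].
#' @rdname read_swa_trace
#' @export
write_swa_trace <- function(trace, path) {
  trace$on_body <- as.integer(trace$on_body)
  readr::write_csv(trace, path, progress = FALSE)
  invisible(path)
}
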