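# Schofield weight-based BMR coefficient table.
#
# Predicted BMR = a * weight_kg + b, in kJ/day (original coefficients are
# MJ/day; stored here multiplied by 1000). Weight-only variant; age bands in
# years are lower-inclusive, i.e. [age_min, age_max). An exact band boundary
# (e.g. age 18.0) therefore falls in the older band. Sanity anchor: a
# 10-17 y girl of 57.4 kg gives 0.056*57.4 + 2.898 = 6.1124 MJ = 6112 kJ/day.
schofield_table <- tibble::tibble(
  gender  = rep(c("male", "female"), each = 6),
  age_min = rep(c(0, 3, 10, 18, 30, 60), 2),
  age_max = rep(c(3, 10, 18, 30, 60, Inf), 2),
  a = c(249, 95, 74, 63, 48, 49,
        244, 85, 56, 62, 34, 38),
  b = c(-127, 2110, 2754, 2896, 3653, 2459,
        -130, 2033, 2898, 2036, 3538, 2755))

#' Schofield coefficient table
#'
#' The weight-only Schofield prediction coefficients used by
#' [schofield_bmr()], in kJ/day (`BMR = a * weight_kg + b`). Age bands are
#' lower-inclusive (`[age_min, age_max)`).
#'
#' @return A tibble with columns `gender`, `age_min`, `age_max`, `a`, `b`.
#' @export
schofield_coefficients <- function() schofield_table

#' Basal metabolic rate by Schofield's weight-based equations
#'
#' @param gender `"female"` or `"male"` (vectorised).
#' @param age_years Age in years.
#' @param weight_kg Body weight in kg.
#' @return BMR in kJ/day; strictly increasing in weight within a band.
#' @examples
#' schofield_bmr("female", 15.5, 57.4)  # 6112.4 kJ/day
#' @export
schofield_bmr <- function(gender, age_years, weight_kg) {
  gender <- match_gender(gender)
  check_positive(weight_kg, "weight_kg")
  n <- max(length(gender), length(age_years), length(weight_kg))
  gender <- rep_len(gender, n)
  age_years <- rep_len(age_years, n)
  weight_kg <- rep_len(weight_kg, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    row <- schofield_table[schofield_table$gender == gender[i] &
                             schofield_table$age_min <= age_years[i] &
                             age_years[i] < schofield_table$age_max, ]
    if (nrow(row) != 1 || age_years[i] < 0) {
      abort(sprintf("Age %.2f y is outside the coefficient table.",
                    age_years[i]),
            class = "dietsense_range_error")
    }
    out[i] <- row$a * weight_kg[i] + row$b
  }
  out
}

match_gender <- function(gender) {
  g <- tolower(as.character(gender))
  bad <- !g %in% c("female", "male")
  if (any(bad)) {
    abort("`gender` must be \"female\" or \"male\".",
          class = "dietsense_argument_error")
  }
  g
}
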