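#' The five self-reported activity levels
#'
#' Ordered from `very_light` (sedentary most of the day) to `very_heavy`
#' (standing/walking most of the day plus an hour of strenuous sport).
#'
#' @return Character vector of the five levels in increasing order.
#' @export
activity_levels <- function() {
  c("very_light", "light", "moderate", "heavy", "very_heavy")
}

# girl values; boys are +0.1 at every level
pal_girl <- c(very_light = 1.3, light = 1.5, moderate = 1.7, heavy = 1.9,
              very_heavy = 2.1)

#' Physical activity level multiplier
#'
#' Sex-specific PAL multipliers for the five-level daily activity question:
#' girls 1.3 / 1.5 / 1.7 / 1.9 / 2.1 and boys 1.4 / 1.6 / 1.8 / 2.0 / 2.2
#' for very light through very heavy.
#'
#' @param gender `"female"` or `"male"` (vectorised).
#' @param level One of [activity_levels()] (vectorised).
#' @return Dimensionless PAL multiplier.
#' @examples
#' pal_value("female", "moderate")  # 1.7
#' @export
pal_value <- function(gender, level) {
  gender <- match_gender(gender)
  bad <- !level %in% activity_levels()
  if (any(bad)) {
    abort(paste0("Unknown activity level: ",
                 paste(unique(level[bad]), collapse = ", ")),
          class = "dietsense_argument_error")
  }
  unname(pal_girl[level] + ifelse(gender == "male", 0.1, 0))
}

#' Full PAL lookup table
#' @return Tibble with `gender`, `level`, `pal` for all ten combinations.
#' @export
pal_table <- function() {
  tidyr::expand_grid(gender = c("female", "male"),
                     level = activity_levels()) |>
    dplyr::mutate(pal = pal_value(.data$gender, .data$level))
}

#' App-style total energy expenditure
#'
#' `TEE = Schofield BMR x PAL` for the reported daily activity level.
#'
#' @inheritParams schofield_bmr
#' @inheritParams pal_value
#' @return TEE in kJ/day.
#' @export
tee_app <- function(gender, age_years, weight_kg, level) {
  schofield_bmr(gender, age_years, weight_kg) * pal_value(gender, level)
}

#' Body mass index
#'
#' @param weight_kg Weight in kg (> 0).
#' @param height_cm Height in cm (> 0).
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_cm) {
  check_positive(weight_kg, "weight_kg")
  check_positive(height_cm, "height_cm")
  weight_kg / (height_cm / 100)^2
}

#' Load an LMS growth reference with weight-status cutoffs
#'
#' Expected CSV columns: `sex` (`female`/`male`), `age_years`, `L`, `M`,
#' `S`, `cutoff_thin2`, `cutoff_thin1`, `cutoff_overweight`,
#' `cutoff_obese` (cutoffs as BMI values). The packaged default
#' (`bmi_reference_synthetic.csv`) is a synthetic stand-in constructed with
#' the LMS structure of standard growth references and cutoff curves
#' anchored at adult BMI 17 / 18.5 / 25 / 30; substitute a published table
#' for real analyses.
#'
#' @param path CSV path; defaults to the packaged synthetic reference.
#' @return Tibble of reference rows.
#' @export
load_lms_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bmi_reference_synthetic.csv",
                        package = "dietsense", mustWork = TRUE)
  }
  ref <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sex", "age_years", "L", "M", "S", "cutoff_thin2", "cutoff_thin1",
           "cutoff_overweight", "cutoff_obese")
  missing_cols <- setdiff(req, names(ref))
  if (length(missing_cols) > 0) {
    abort(paste0("LMS reference is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "dietsense_schema_error")
  }
  ref
}

interp_ref <- function(ref, sex, age, cols) {
  sub <- ref[ref$sex == sex, ]
  sub <- sub[order(sub$age_years), ]
  if (nrow(sub) < 2 || age < min(sub$age_years) || age > max(sub$age_years)) {
    abort(sprintf("Age %.2f y is outside the reference table (%s).",
                  age, sex),
          class = "dietsense_range_error")
  }
  vapply(cols, function(cl) {
    stats::approx(sub$age_years, sub[[cl]], xout = age)$y
  }, numeric(1))
}

#' BMI z-score via the LMS transform
#'
#' `z = ((bmi/M)^L - 1) / (L * S)` with L, M, S linearly interpolated in
#' age within sex.
#'
#' @param bmi_value BMI in kg/m^2.
#' @param age_years Age in years (must be covered by the reference).
#' @param gender `"female"` or `"male"`.
#' @param ref Reference table from [load_lms_reference()].
#' @return Standard-deviation score (all arguments except `ref` vectorised).
#' @export
bmi_zscore <- function(bmi_value, age_years, gender, ref = load_lms_reference()) {
  gender <- match_gender(gender)
  n <- max(length(bmi_value), length(age_years), length(gender))
  bmi_value <- rep_len(bmi_value, n)
  age_years <- rep_len(age_years, n)
  gender <- rep_len(gender, n)
  vapply(seq_len(n), function(i) {
    lms <- interp_ref(ref, gender[i], age_years[i], c("L", "M", "S"))
    ((bmi_value[i] / lms[["M"]])^lms[["L"]] - 1) / (lms[["L"]] * lms[["S"]])
  }, numeric(1))
}

#' Invert the LMS transform: BMI at a given z-score
#' @inheritParams bmi_zscore
#' @param z Standard-deviation score.
#' @return BMI in kg/m^2.
#' @export
bmi_from_zscore <- function(z, age_years, gender, ref = load_lms_reference()) {
  gender <- match_gender(gender)
  n <- max(length(z), length(age_years), length(gender))
  z <- rep_len(z, n); age_years <- rep_len(age_years, n)
  gender <- rep_len(gender, n)
  vapply(seq_len(n), function(i) {
    lms <- interp_ref(ref, gender[i], age_years[i], c("L", "M", "S"))
    lms[["M"]] * (1 + lms[["L"]] * lms[["S"]] * z[i])^(1 / lms[["L"]])
  }, numeric(1))
}

#' Weight status from age/sex cutoff curves
#'
#' Compares BMI with the interpolated thinness grade 2 / grade 1 /
#' overweight / obesity cutoff curves. Boundaries are inclusive toward the
#' more extreme category: a BMI exactly at the overweight cutoff is
#' `overweight`, exactly at the thinness grade 1 cutoff is
#' `thinness_grade_1`.
#'
#' @inheritParams bmi_zscore
#' @return Factor with levels `thinness_grade_2`, `thinness_grade_1`,
#'   `normal`, `overweight`, `obese`.
#' @export
weight_status <- function(bmi_value, age_years, gender,
                          ref = load_lms_reference()) {
  gender <- match_gender(gender)
  n <- max(length(bmi_value), length(age_years), length(gender))
  bmi_value <- rep_len(bmi_value, n)
  age_years <- rep_len(age_years, n)
  gender <- rep_len(gender, n)
  lv <- c("thinness_grade_2", "thinness_grade_1", "normal", "overweight",
          "obese")
  out <- vapply(seq_len(n), function(i) {
    cut <- interp_ref(ref, gender[i], age_years[i],
                      c("cutoff_thin2", "cutoff_thin1", "cutoff_overweight",
                        "cutoff_obese"))
    b <- bmi_value[i]
    if (b <= cut[["cutoff_thin2"]]) "thinness_grade_2"
    else if (b <= cut[["cutoff_thin1"]]) "thinness_grade_1"
    else if (b >= cut[["cutoff_obese"]]) "obese"
    else if (b >= cut[["cutoff_overweight"]]) "overweight"
    else "normal"
  }, character(1))
  factor(out, levels = lv)
}
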