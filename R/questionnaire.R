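#' Questionnaire instrument configuration
#'
#' The questionnaire bundles 53 items: 15 conscientiousness items, 5
#' fear-of-negative-evaluation items, 7 social-desirability items, the
#' 18-item three-factor eating questionnaire (TFEQ-R18), current and ideal
#' body-size figures, breakfast and school-lunch frequency, and four
#' yes/somewhat/no attitude questions. Item ids, scale ranges, reverse-keyed
#' items and the R18 subscale partition (9 uncontrolled-eating, 6
#' cognitive-restraint, 3 emotional-eating items) are declared in a JSON
#' config shipped with the package rather than hard-coded, so alternative
#' keys can be supplied.
#'
#' @param path Optional path to a JSON config; defaults to the packaged one.
#' @return Named list of instrument descriptors (`items`, `scale_min`,
#'   `scale_max`, `reversed`) plus `frs`, `frequency` and `attitude` blocks.
#' @export
instrument_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "instrument_config.json",
                        package = "dietsense", mustWork = TRUE)
  }
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Score an ordinal item set onto a 0-100 index
#'
#' Linear min-max transform: reverse-keyed items are flipped
#' (`item' = max + min - item`), then
#' `100 * sum(item - min) / (n * (max - min))`. All items at the scale
#' minimum give 0; all at the maximum give 100.
#'
#' @param items Numeric vector of one respondent's item responses.
#' @param item_min,item_max Scale anchors (`item_max > item_min`).
#' @param reversed Logical vector (recycled) flagging reverse-keyed items.
#' @return Index in `[0, 100]`.
#' @export
score_index <- function(items, item_min, item_max, reversed = FALSE) {
  if (anyNA(items)) {
    abort("Items contain missing values; run impute_missing() first.",
          class = "dietsense_missing_data_error")
  }
  stopifnot(item_max > item_min)
  reversed <- rep_len(reversed, length(items))
  items[reversed] <- item_max + item_min - items[reversed]
  if (any(items < item_min | items > item_max)) {
    abort("Item responses outside the declared scale range.",
          class = "dietsense_argument_error")
  }
  100 * sum(items - item_min) / (length(items) * (item_max - item_min))
}

#' TFEQ-R18 subscale indices
#'
#' Scores the three eating-behaviour subscales (cognitive restraint,
#' uncontrolled eating, emotional eating) with [score_index()] over the
#' subscale partition declared in the config.
#'
#' @param tfeq_items Named numeric vector of the 18 item responses (names
#'   as in the config).
#' @param config An [instrument_config()].
#' @return Named numeric: `cognitive_restraint`, `uncontrolled_eating`,
#'   `emotional_eating`, each in `[0, 100]`.
#' @export
tfeq_r18_scores <- function(tfeq_items, config = instrument_config()) {
  subs <- c("cognitive_restraint", "uncontrolled_eating", "emotional_eating")
  vapply(subs, function(s) {
    ins <- config$instruments[[s]]
    score_index(unlist(tfeq_items[unlist(ins$items)]),
                ins$scale_min, ins$scale_max,
                unlist(ins$items) %in% unlist(ins$reversed))
  }, numeric(1))
}

#' Figure-rating-scale discrepancy
#'
#' @param current,ideal Figure indices (current and ideal body size).
#' @return Factor: `no_discrepancy` (equal), `prefer_smaller`
#'   (current > ideal), `prefer_larger` (current < ideal). Vectorised.
#' @export
frs_discrepancy <- function(current, ideal) {
  if (anyNA(current) || anyNA(ideal)) {
    abort("Figure ratings contain missing values; impute first.",
          class = "dietsense_missing_data_error")
  }
  out <- ifelse(current == ideal, "no_discrepancy",
                ifelse(current > ideal, "prefer_smaller", "prefer_larger"))
  factor(out, levels = c("no_discrepancy", "prefer_smaller", "prefer_larger"))
}

#' Impute missing questionnaire responses
#'
#' Applies the declared rules: a missing figure rating becomes *no
#' discrepancy* (both figures set to the scale midpoint); missing breakfast
#' frequency becomes 7 days/week and missing school-lunch frequency 5
#' days/week; missing conscientiousness items take the scale midpoint (the
#' neutral alternative); missing social-desirability, uncontrolled-eating
#' and cognitive-restraint items take the per-item median over the other
#' respondents. The same median rule is extended to the remaining ordinal
#' instruments, and missing attitude answers take the modal answer, so that
#' scoring after imputation is always total.
#'
#' @param responses Wide tibble, one row per respondent, columns
#'   `participant_id` plus the item columns named in the config.
#' @param config An [instrument_config()].
#' @return List with `responses` (completed tibble) and `log` (tibble
#'   `participant_id, field, value, rule`, one row per imputed cell).
#' @export
impute_missing <- function(responses, config = instrument_config()) {
  responses <- tibble::as_tibble(responses)
  log <- list()
  note <- function(pid, field, value, rule) {
    log[[length(log) + 1]] <<- tibble::tibble(
      participant_id = pid, field = field, value = as.character(value),
      rule = rule)
  }

  # figure rating scale: missing -> no discrepancy
  frs_mid <- round((config$frs$scale_min + config$frs$scale_max) / 2)
  frs_na <- is.na(responses$frs_current) | is.na(responses$frs_ideal)
  for (i in which(frs_na)) {
    for (f in c("frs_current", "frs_ideal")) {
      if (is.na(responses[[f]][i])) {
        note(responses$participant_id[i], f, frs_mid, "frs_no_discrepancy")
      }
    }
    responses$frs_current[i] <- frs_mid
    responses$frs_ideal[i] <- frs_mid
  }

  # frequency questions: missing -> every day
  for (spec in list(list(f = "breakfast_days", v = 7, r = "breakfast_7"),
                    list(f = "school_lunch_days", v = 5, r = "lunch_5"))) {
    idx <- which(is.na(responses[[spec$f]]))
    for (i in idx) {
      note(responses$participant_id[i], spec$f, spec$v, spec$r)
      responses[[spec$f]][i] <- spec$v
    }
  }

  # instrument items
  for (nm in names(config$instruments)) {
    ins <- config$instruments[[nm]]
    rule <- if (identical(ins$impute, "midpoint")) "midpoint" else "item_median"
    for (it in unlist(ins$items)) {
      idx <- which(is.na(responses[[it]]))
      if (length(idx) == 0) next
      if (rule == "midpoint") {
        v <- (ins$scale_min + ins$scale_max) / 2
      } else {
        obs <- responses[[it]][!is.na(responses[[it]])]
        if (length(obs) == 0) {
          abort(sprintf(
            "Cannot median-impute item '%s': no non-missing respondents.", it),
            class = "dietsense_imputation_error")
        }
        v <- median(obs)
      }
      for (i in idx) note(responses$participant_id[i], it, v, rule)
      responses[[it]][idx] <- v
    }
  }

  # attitude questions: missing -> modal answer
  for (f in unlist(config$attitude$items)) {
    idx <- which(is.na(responses[[f]]))
    if (length(idx) == 0) next
    obs <- responses[[f]][!is.na(responses[[f]])]
    if (length(obs) == 0) {
      abort(sprintf("Cannot mode-impute '%s': all respondents missing.", f),
            class = "dietsense_imputation_error")
    }
    v <- names(sort(table(obs), decreasing = TRUE))[1]
    for (i in idx) note(responses$participant_id[i], f, v, "mode")
    responses[[f]][idx] <- v
  }

  list(responses = responses,
       log = if (length(log)) dplyr::bind_rows(log) else
         tibble::tibble(participant_id = character(), field = character(),
                        value = character(), rule = character()))
}

#' Dichotomise frequency and attitude answers
#'
#' Breakfast is split at 7 vs fewer days/week, school lunch at 5 vs fewer
#' days/week, and each yes/somewhat/no question at *yes* vs *somewhat/no*.
#'
#' @param responses Completed wide response tibble (post-imputation).
#' @return Tibble `participant_id` plus logical columns `breakfast_7`,
#'   `lunch_5`, `eat_important_yes`, `comprehensible_yes`, `manageable_yes`,
#'   `meaningful_yes`.
#' @export
dichotomize <- function(responses) {
  tibble::tibble(
    participant_id = responses$participant_id,
    breakfast_7 = responses$breakfast_days >= 7,
    lunch_5 = responses$school_lunch_days >= 5,
    eat_important_yes = responses$eat_important == "yes",
    comprehensible_yes = responses$comprehensible == "yes",
    manageable_yes = responses$manageable == "yes",
    meaningful_yes = responses$meaningful == "yes")
}

#' Score a whole questionnaire table
#'
#' @param responses Completed wide response tibble (run [impute_missing()]
#'   first if any cells are missing).
#' @param config An [instrument_config()].
#' @return Tibble with one row per respondent: the six 0-100 indices,
#'   `frs_discrepancy`, and the dichotomies from [dichotomize()].
#' @export
score_questionnaire <- function(responses, config = instrument_config()) {
  idx <- purrr::map_dfr(seq_len(nrow(responses)), function(i) {
    row <- responses[i, ]
    vals <- vapply(names(config$instruments), function(nm) {
      ins <- config$instruments[[nm]]
      score_index(unlist(row[unlist(ins$items)]), ins$scale_min,
                  ins$scale_max,
                  unlist(ins$items) %in% unlist(ins$reversed))
    }, numeric(1))
    tibble::as_tibble(as.list(vals))
  })
  dplyr::bind_cols(
    tibble::tibble(participant_id = responses$participant_id),
    idx,
    tibble::tibble(frs_discrepancy = frs_discrepancy(responses$frs_current,
                                                     responses$frs_ideal)),
    dichotomize(responses)[, -1])
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))` with
#' sample (n-1) variances.
#'
#' @param items Numeric matrix or data frame, respondents in rows, items in
#'   columns (>= 2 items, >= 2 respondents).
#' @return Alpha (can be negative for inconsistent scales).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (ncol(m) < 2 || nrow(m) < 2 || anyNA(m)) {
    abort("Need a complete matrix with >= 2 items and >= 2 respondents.",
          class = "dietsense_argument_error")
  }
  total_var <- var(rowSums(m))
  if (total_var == 0) {
    abort("Total-score variance is zero; alpha is undefined.",
          class = "dietsense_undefined_alpha_error")
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}
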