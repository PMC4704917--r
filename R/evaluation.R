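#' Exclude implausibly low intake days
#'
#' Keeps days with reported energy intake of at least 2092 kJ (500 kcal);
#' days strictly below the threshold are excluded. Idempotent.
#'
#' @param days Tibble with at least `participant_id`, `date`, `ei_kj`.
#' @param min_ei_kj Exclusion threshold in kJ (default 2092).
#' @return List with `included` (kept rows) and `excluded` (the exclusion
#'   log: dropped rows).
#' @export
filter_ei_days <- function(days, min_ei_kj = 2092) {
  keep <- days$ei_kj >= min_ei_kj
  list(included = days[keep, ], excluded = days[!keep, ])
}

#' Exclude insufficient armband wear days
#'
#' Keeps days on which the armband was worn at least `min_wear_hours`
#' (default 19 h, 80 % of the day); inclusive at the threshold.
#'
#' @param days Tibble with at least `participant_id`, `date`, `wear_hours`.
#' @param min_wear_hours Minimum wear time in hours.
#' @return List with `included` and `excluded` tibbles.
#' @export
filter_swa_days <- function(days, min_wear_hours = 19) {
  keep <- days$wear_hours >= min_wear_hours
  list(included = days[keep, ], excluded = days[!keep, ])
}

#' Classify reporting accuracy against a plausibility band
#'
#' Reported intake within +/-5 % of measured expenditure is `plausible`
#' (band boundaries inclusive); below the band is `under`, above is `over`.
#'
#' @param ei Reported energy intake, kJ/day.
#' @param tee Measured total energy expenditure, kJ/day (> 0).
#' @param band Half-width of the plausibility band (default 0.05).
#' @return Factor with levels `under`, `plausible`, `over` (vectorised).
#' @export
classify_reporting <- function(ei, tee, band = 0.05) {
  if (any(tee <= 0 | !is.finite(tee))) {
    abort("`tee` must be positive.", class = "dietsense_argument_error")
  }
  r <- ei / tee
  out <- ifelse(r < 1 - band, "under",
                ifelse(r > 1 + band, "over", "plausible"))
  factor(out, levels = c("under", "plausible", "over"))
}

#' Per-participant evaluation metrics
#'
#' Aggregates each participant's included days by the mean, separately for
#' intake and expenditure day sets (the day sets need not match), and
#' derives the accuracy metrics: EI - TEE, EI/TEE, (EI-TEE)/TEE, EI/BMR,
#' TEE/BMR, the app-vs-reference TEE difference and ratio, and the
#' under/plausible/over classification.
#'
#' @param ei_days Included intake days: `participant_id, date, ei_kj`
#'   (optionally `is_weekend`).
#' @param swa_days Included armband days: `participant_id, date,
#'   tee_swa_kj`.
#' @param app_tee_days App TEE days: `participant_id, date, tee_app_kj`
#'   (may be empty; the app columns are then `NA`).
#' @param participant One-row tibble / list with `participant_id` and
#'   `bmr_kj`.
#' @param band Plausibility band half-width for [classify_reporting()].
#' @return One-row tibble of `participant_evaluation` metrics.
#' @export
evaluate_participant <- function(ei_days, swa_days, app_tee_days = NULL,
                                 participant, band = 0.05) {
  if (nrow(ei_days) < 1 || nrow(swa_days) < 1) {
    abort("Need at least one included intake day and one armband day.",
          class = "dietsense_insufficient_data_error")
  }
  ei <- mean(ei_days$ei_kj)
  tee <- mean(swa_days$tee_swa_kj)
  app <- if (!is.null(app_tee_days) && nrow(app_tee_days) > 0) {
    mean(app_tee_days$tee_app_kj)
  } else NA_real_
  bmr <- participant$bmr_kj
  wk <- if ("is_weekend" %in% names(ei_days)) any(ei_days$is_weekend) else
    any(is_weekend(ei_days$date))
  tibble::tibble(
    participant_id = participant$participant_id,
    n_ei_days = nrow(ei_days), n_swa_days = nrow(swa_days),
    has_weekend_ei_day = wk,
    ei_kj = ei, tee_swa_kj = tee, tee_app_kj = app, bmr_kj = bmr,
    ei_minus_tee = ei - tee, ei_over_tee = ei / tee,
    rel_accuracy = (ei - tee) / tee,
    ei_over_bmr = ei / bmr, tee_over_bmr = tee / bmr,
    teeapp_minus_teeswa = app - tee, teeapp_over_teeswa = app / tee,
    reporting_class = classify_reporting(ei, tee, band))
}

#' Evaluate a whole cohort
#'
#' Applies the day-level inclusion filters and computes
#' [evaluate_participant()] for everyone with at least one included day on
#' each side; participants failing that are listed in `dropped`.
#'
#' @param ei_days All intake days (`participant_id, date, ei_kj`).
#' @param swa_days All armband days (`participant_id, date, tee_swa_kj,
#'   wear_hours`).
#' @param app_tee_days Optional app TEE days (`participant_id, date,
#'   tee_app_kj`).
#' @param participants Tibble with `participant_id`, `bmr_kj` (extra
#'   columns are carried through to the output).
#' @param min_ei_kj,min_wear_hours,band Threshold overrides; defaults are
#'   the standard 2092 kJ, 19 h and +/-5 %.
#' @return List: `evaluations` (one row per evaluated participant, joined
#'   with `participants` columns), `dropped` (ids without enough included
#'   days), `excluded_ei_days`, `excluded_swa_days`.
#' @export
evaluate_cohort <- function(ei_days, swa_days, app_tee_days = NULL,
                            participants, min_ei_kj = 2092,
                            min_wear_hours = 19, band = 0.05) {
  fe <- filter_ei_days(ei_days, min_ei_kj)
  fs <- filter_swa_days(swa_days, min_wear_hours)
  evals <- list()
  dropped <- character(0)
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    ei_p <- fe$included[fe$included$participant_id == p$participant_id, ]
    sw_p <- fs$included[fs$included$participant_id == p$participant_id, ]
    ap_p <- if (!is.null(app_tee_days)) {
      app_tee_days[app_tee_days$participant_id == p$participant_id, ]
    } else NULL
    if (nrow(ei_p) < 1 || nrow(sw_p) < 1) {
      dropped <- c(dropped, p$participant_id)
      next
    }
    evals[[length(evals) + 1]] <-
      evaluate_participant(ei_p, sw_p, ap_p, p, band)
  }
  evals <- if (length(evals)) dplyr::bind_rows(evals) else tibble::tibble()
  if (nrow(evals) > 0) {
    extra <- participants[, setdiff(names(participants),
                                    setdiff(names(evals), "participant_id")),
                          drop = FALSE]
    evals <- dplyr::left_join(evals, extra, by = "participant_id")
  }
  list(evaluations = evals, dropped = dropped,
       excluded_ei_days = fe$excluded, excluded_swa_days = fs$excluded)
}

#' Bland-Altman agreement analysis
#'
#' Differences `x - y` against pair means `(x + y)/2`, with limits of
#' agreement `mean(diff) +/- k * sd(diff)` (sample SD, `k = 1.96`).
#'
#' @param x,y Paired measurements (>= 3 complete pairs by default).
#' @param ids Optional identifiers for the pairs.
#' @param k Limit multiplier (default 1.96).
#' @param min_pairs Minimum number of complete pairs (default 3; may be
#'   lowered to 2 for didactic hand-sized examples, where the sample SD is
#'   still defined).
#' @return Object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `pairs` (tibble `id, mean, diff, outside`),
#'   `outside_loa_ids`.
#' @export
bland_altman <- function(x, y, ids = seq_along(x), k = 1.96,
                         min_pairs = 3) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; ids <- ids[ok]
  if (length(x) < max(min_pairs, 2) || length(x) != length(y)) {
    abort(sprintf("Need at least %d complete pairs.", max(min_pairs, 2)),
          class = "dietsense_insufficient_data_error")
  }
  d <- x - y
  m <- mean(d); s <- sd(d)
  lo <- m - k * s; hi <- m + k * s
  outside <- d < lo | d > hi
  structure(list(
    mean_diff = m, sd_diff = s, loa_low = lo, loa_high = hi, k = k,
    pairs = tibble::tibble(id = ids, mean = (x + y) / 2, diff = d,
                           outside = outside),
    outside_loa_ids = ids[outside]),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n=%d  mean diff %.1f (SD %.1f)  LoA [%.1f, %.1f]  %d outside\n",
    nrow(x$pairs), x$mean_diff, x$sd_diff, x$loa_low, x$loa_high,
    length(x$outside_loa_ids)))
  invisible(x)
}

#' Spearman correlations between evaluation fields
#'
#' @param data Data frame of per-participant metrics.
#' @param pairs List of 2-element character vectors naming field pairs.
#' @return Tibble `x, y, rho, p` (two-sided, average ranks for ties).
#' @export
correlations <- function(data, pairs) {
  purrr::map_dfr(pairs, function(pr) {
    a <- data[[pr[1]]]; b <- data[[pr[2]]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) {
      abort("Need at least 3 complete pairs.",
            class = "dietsense_insufficient_data_error")
    }
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      abort("Correlation undefined for a constant vector.",
            class = "dietsense_undefined_correlation_error")
    }
    ct <- suppressWarnings(
      cor.test(a[ok], b[ok], method = "spearman", exact = FALSE))
    tibble::tibble(x = pr[1], y = pr[2], rho = unname(ct$estimate),
                   p = ct$p.value)
  })
}

#' Two-group and paired comparisons
#'
#' `group_compare` runs a two-sided Mann-Whitney U test of `values` between
#' the two levels of `group`; `paired_compare` runs the two-sided Wilcoxon
#' signed-rank test and the paired t test on `(a, b)`. Fully tied paired
#' input reports p = 1 by convention.
#'
#' @param values Numeric vector.
#' @param group Two-level grouping vector.
#' @return `group_compare`: list `statistic`, `p`. `paired_compare`: list
#'   `wilcoxon_p`, `t_p`, `mean_diff`, `median_diff`.
#' @export
group_compare <- function(values, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2 || any(table(group) < 2)) {
    abort("Need two groups with at least 2 observations each.",
          class = "dietsense_argument_error")
  }
  ht <- suppressWarnings(wilcox.test(values ~ group, exact = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' @param a,b Paired numeric vectors of equal length.
#' @rdname group_compare
#' @export
paired_compare <- function(a, b) {
  if (length(a) != length(b)) {
    abort("Paired inputs must have equal length.",
          class = "dietsense_argument_error")
  }
  d <- a - b
  if (all(d == 0)) {
    return(list(wilcoxon_p = 1, t_p = 1, mean_diff = 0,
                median_diff = 0))
  }
  w <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
  # a constant non-zero difference is perfect separation: p -> 0
  tt <- tryCatch(t.test(a, b, paired = TRUE),
                 error = function(e) list(p.value = 0))
  list(wilcoxon_p = w$p.value, t_p = tt$p.value, mean_diff = mean(d),
       median_diff = median(d))
}

#' Study-size formula for a paired energy comparison
#'
#' `n = 2 * (2.8 * sd / difference)^2`, rounded up; the number of
#' participants needed per comparison to detect `difference` at alpha .05
#' and 80 % power.
#'
#' @param sd Expected standard deviation of the difference, kJ.
#' @param difference Smallest meaningful difference, kJ.
#' @return Integer number of participants.
#' @export
sample_size <- function(sd, difference) {
  check_positive(sd, "sd")
  check_positive(difference, "difference")
  as.integer(ceiling(2 * (2.8 * sd / difference)^2))
}

#' Compare two dietary assessment methods variable by variable
#'
#' For each shared variable (energy, nutrients, food groups), pairs the two
#' methods by participant and reports the two-sided Wilcoxon signed-rank p
#' and the Spearman correlation.
#'
#' @param a,b Tibbles with `participant_id` plus one numeric column per
#'   variable; rows are matched by `participant_id`.
#' @param variables Variables to compare; default: all shared numeric
#'   columns.
#' @return Tibble `variable, n, wilcoxon_p, rho, rho_p`.
#' @export
method_comparison <- function(a, b, variables = NULL) {
  if (is.null(variables)) {
    variables <- setdiff(intersect(names(a), names(b)), "participant_id")
  }
  missing_vars <- setdiff(variables, intersect(names(a), names(b)))
  if (length(missing_vars) > 0) {
    abort(paste0("Variable(s) absent in one method: ",
                 paste(missing_vars, collapse = ", ")),
          class = "dietsense_pairing_error")
  }
  merged <- dplyr::inner_join(a[, c("participant_id", variables)],
                              b[, c("participant_id", variables)],
                              by = "participant_id",
                              suffix = c("_a", "_b"))
  if (nrow(merged) < 3 || nrow(merged) < nrow(a) || nrow(merged) < nrow(b)) {
    abort("Methods must be paired by participant (>= 3 shared rows).",
          class = "dietsense_pairing_error")
  }
  purrr::map_dfr(variables, function(v) {
    xa <- merged[[paste0(v, "_a")]]; xb <- merged[[paste0(v, "_b")]]
    pc <- paired_compare(xa, xb)
    if (identical(xa, xb)) {
      # identical methods: perfect agreement by convention
      rho <- 1; rho_p <- 0
    } else if (sd(xa) == 0 || sd(xb) == 0) {
      rho <- NA_real_; rho_p <- NA_real_
    } else {
      ct <- suppressWarnings(cor.test(xa, xb, method = "spearman",
                                      exact = FALSE))
      rho <- unname(ct$estimate); rho_p <- ct$p.value
    }
    tibble::tibble(variable = v, n = nrow(merged),
                   wilcoxon_p = pc$wilcoxon_p, rho = unname(rho),
                   rho_p = rho_p)
  })
}

#' Cohort summary in dual presentation
#'
#' Median (IQR) and mean (SD) for the named metrics, matching the common
#' dual presentation of skewed energy data.
#'
#' @param evaluations Per-participant evaluation tibble.
#' @param metrics Column names to summarise.
#' @return Tibble `metric, n, median, iqr, mean, sd`.
#' @export
cohort_summary <- function(evaluations,
                           metrics = c("bmr_kj", "ei_kj", "tee_swa_kj",
                                       "tee_app_kj", "ei_over_bmr",
                                       "tee_over_bmr", "ei_minus_tee",
                                       "ei_over_tee", "teeapp_minus_teeswa",
                                       "teeapp_over_teeswa")) {
  purrr::map_dfr(intersect(metrics, names(evaluations)), function(m) {
    v <- evaluations[[m]]
    v <- v[is.finite(v)]
    tibble::tibble(metric = m, n = length(v), median = median(v),
                   iqr = unname(diff(quantile(v, c(0.25, 0.75)))),
                   mean = mean(v), sd = sd(v))
  })
}
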