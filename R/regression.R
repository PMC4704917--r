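#' Regression of reporting accuracy on participant factors
#'
#' Fits each candidate predictor one at a time in an ordinary
#' least-squares model of the chosen accuracy outcome (`ei_minus_tee`,
#' kJ/day, or `rel_accuracy`, the dimensionless (EI-TEE)/TEE), then builds
#' a forward stepwise model (entry p < `entry_p`, backward removal
#' p > `removal_p`, F tests). Reference TEE is a candidate only for the
#' kJ-scale outcome; for the relative outcome it is excluded because the
#' outcome is already normalised by it.
#'
#' @param data Per-participant tibble holding the outcome and candidate
#'   columns (typically `evaluations` joined with questionnaire scores and
#'   demographics).
#' @param outcome `"ei_minus_tee"` or `"rel_accuracy"`.
#' @param candidates Candidate column names; default: the standard set
#'   (gender, BMI z-score, TEE for the kJ outcome, parental education,
#'   origin, weekend day in record, school, the six indices, figure-rating
#'   discrepancy, and the frequency/attitude dichotomies) intersected with
#'   the available columns.
#' @param entry_p,removal_p Forward-entry and backward-removal thresholds.
#' @return Object of class `accuracy_regression`: `outcome`, `n`,
#'   `univariable` (tibble `term, coefficient, estimate, conf_low,
#'   conf_high, p, term_p`), `selected` (character), `model` (the final
#'   `lm`), `model_coefficients` (tibble for the stepwise model).
#' @export
accuracy_regression <- function(data,
                                outcome = c("ei_minus_tee", "rel_accuracy"),
                                candidates = NULL,
                                entry_p = 0.05, removal_p = 0.10) {
  outcome <- match.arg(outcome)
  if (is.null(candidates)) {
    candidates <- default_candidates(outcome)
  } else if (outcome == "rel_accuracy") {
    candidates <- setdiff(candidates, "tee_swa_kj")
  }
  candidates <- intersect(candidates, names(data))
  if (length(candidates) == 0) {
    abort("No candidate predictors found in `data`.",
          class = "dietsense_argument_error")
  }
  dat <- data[, c(outcome, candidates)]
  dat <- dat[complete.cases(dat), ]
  if (nrow(dat) < 10) {
    abort("Need at least 10 complete observations.",
          class = "dietsense_insufficient_data_error")
  }
  dat <- droplevels(dat)
  # single-level factors / constant columns cannot enter any model
  usable <- candidates[vapply(candidates, function(cn) {
    v <- dat[[cn]]
    length(unique(v)) > 1
  }, logical(1))]
  if (length(usable) == 0) {
    abort("All candidate predictors are constant.",
          class = "dietsense_argument_error")
  }
  # exactly collinear candidates make the design unidentifiable; name them
  check_rank(lm(stats::reformulate(usable, outcome), data = dat))

  uni <- purrr::map_dfr(usable, function(cn) {
    fit <- lm(stats::reformulate(cn, outcome), data = dat)
    check_rank(fit)
    coefs <- coef_table(fit)
    coefs <- coefs[coefs$coefficient != "(Intercept)", ]
    a <- anova(fit)
    coefs$term <- cn
    coefs$term_p <- a$`Pr(>F)`[1]
    coefs[, c("term", "coefficient", "estimate", "conf_low", "conf_high",
              "p", "term_p")]
  })

  selected <- stepwise_select(dat, outcome, usable, entry_p, removal_p)
  model <- lm(if (length(selected) == 0) {
    stats::reformulate("1", outcome)
  } else {
    stats::reformulate(selected, outcome)
  }, data = dat)
  structure(list(outcome = outcome, n = nrow(dat), univariable = uni,
                 selected = selected, model = model,
                 model_coefficients = coef_table(model)),
            class = "accuracy_regression")
}

default_candidates <- function(outcome) {
  base <- c("gender", "bmi_zscore", "tee_swa_kj", "parental_education",
            "born_outside", "has_weekend_ei_day", "school",
            "conscientiousness", "fear_of_negative_evaluation",
            "social_desirability", "cognitive_restraint",
            "uncontrolled_eating", "emotional_eating", "frs_discrepancy",
            "breakfast_7", "lunch_5", "eat_important_yes",
            "comprehensible_yes", "manageable_yes", "meaningful_yes")
  if (outcome == "rel_accuracy") setdiff(base, "tee_swa_kj") else base
}

coef_table <- function(fit) {
  sm <- suppressWarnings(summary(fit))$coefficients
  ci <- suppressWarnings(confint(fit))
  tibble::tibble(coefficient = rownames(sm), estimate = unname(sm[, 1]),
                 conf_low = unname(ci[, 1]), conf_high = unname(ci[, 2]),
                 p = unname(sm[, 4]))
}

check_rank <- function(fit) {
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Design is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")),
          class = "dietsense_singularity_error")
  }
  invisible(fit)
}

# forward selection with backward pruning, F tests between nested models
stepwise_select <- function(dat, outcome, candidates, entry_p, removal_p) {
  selected <- character(0)
  repeat {
    changed <- FALSE
    current <- lm(if (length(selected) == 0) {
      stats::reformulate("1", outcome)
    } else stats::reformulate(selected, outcome), data = dat)
    remaining <- setdiff(candidates, selected)
    if (length(remaining) > 0) {
      ps <- vapply(remaining, function(cn) {
        fit <- lm(stats::reformulate(c(selected, cn), outcome), data = dat)
        if (anyNA(coef(fit))) return(NA_real_)
        anova(current, fit)$`Pr(>F)`[2]
      }, numeric(1))
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < entry_p) {
        selected <- c(selected, remaining[which.min(ps)])
        changed <- TRUE
      }
    }
    if (length(selected) > 1) {
      full <- lm(stats::reformulate(selected, outcome), data = dat)
      drop_ps <- vapply(selected, function(cn) {
        reduced <- lm(stats::reformulate(setdiff(selected, cn), outcome),
                      data = dat)
        anova(reduced, full)$`Pr(>F)`[2]
      }, numeric(1))
      if (max(drop_ps) > removal_p) {
        selected <- setdiff(selected, selected[which.max(drop_ps)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  selected
}

#' Assemble the per-participant dataset for the accuracy regression
#'
#' Joins the evaluation metrics with questionnaire scores and derives the
#' standard candidate columns: BMI z-score recomputed from measured weight,
#' height and age, and origin dichotomised to born outside the country
#' (participant and/or parents) versus not.
#'
#' @param evaluations Output of [evaluate_cohort()] (the `evaluations`
#'   tibble), carrying `gender`, `weight_kg`, `height_cm`, `age_years` and
#'   optionally `born_outside_sweden`, `school`, `parental_education`.
#' @param scores Optional [score_questionnaire()] tibble to join by
#'   `participant_id`.
#' @param ref LMS reference for the z-score (see [load_lms_reference()]).
#' @return Tibble ready for [accuracy_regression()].
#' @export
regression_dataset <- function(evaluations, scores = NULL,
                               ref = load_lms_reference()) {
  dat <- evaluations
  dat$bmi_zscore <- bmi_zscore(bmi(dat$weight_kg, dat$height_cm),
                               dat$age_years, dat$gender, ref)
  if ("born_outside_sweden" %in% names(dat)) {
    dat$born_outside <- dat$born_outside_sweden != "none"
  }
  if (!is.null(scores)) {
    dat <- dplyr::left_join(dat, scores, by = "participant_id")
  }
  dat
}

#' @export
print.accuracy_regression <- function(x, ...) {
  cat(sprintf("<accuracy_regression> outcome %s, n=%d\n", x$outcome, x$n))
  cat("stepwise selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else
        "(empty model)", "\n")
  invisible(x)
}

#' Mixed-model check of a stepwise accuracy model
#'
#' Refits the selected fixed effects with a random intercept for school
#' (via `lme4`), the standard guard against dependence of participants
#' within schools. The contract on well-conditioned data is that the fixed
#' effects are essentially unchanged relative to OLS.
#'
#' @param reg An [accuracy_regression()] result.
#' @param data The data used to fit it (must contain `school`).
#' @return Tibble `coefficient, estimate` of the mixed model's fixed
#'   effects.
#' @export
accuracy_regression_mixed <- function(reg, data) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    abort("The mixed-model check needs the 'lme4' package.",
          class = "dietsense_argument_error")
  }
  stopifnot("school" %in% names(data))
  terms <- setdiff(reg$selected, "school")
  rhs <- paste(c(if (length(terms)) terms else "1", "(1 | school)"),
               collapse = " + ")
  fml <- stats::as.formula(paste(reg$outcome, "~", rhs))
  fit <- lme4::lmer(fml, data = data)
  fe <- lme4::fixef(fit)
  tibble::tibble(coefficient = names(fe), estimate = unname(fe))
}
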