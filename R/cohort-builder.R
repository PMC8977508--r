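# Arm harmonization. Staggered cluster enrollment gives the two arms
# unequal case-accrual windows; restricting to cases diagnosed within the
# shortest observed follow-up (the uniform follow-up time) makes the arms
# comparable, and the monthly cost curve after first hospitalization fixes
# the window over which costs are collected.

#' Uniform follow-up time across verified cases
#'
#' The shortest follow-up (in days) among the participants owning the
#' supplied cases; used as the uniform accrual window of the harmonized
#' cohort. With `basis = "survival"` follow-up is the participant's own
#' `end_of_followup - enrollment_date` (death- or censor-truncated). With
#' `basis = "accrual"` it is the distance from enrollment to the
#' administrative censoring date, so the minimum reflects enrollment
#' staggering rather than early deaths — the quantity the equal-accrual
#' construction is meant to equalize, and the basis the pipeline uses.
#'
#' @param cases Case tibble (verified treated cases).
#' @param participants Validated participant roster.
#' @param basis `"survival"` or `"accrual"`.
#' @param censor_date Administrative censoring date for `basis = "accrual"`;
#'   defaults to the latest `end_of_followup` in the roster.
#' @return Integer days.
#' @export
uniform_followup <- function(cases, participants,
                             basis = c("survival", "accrual"),
                             censor_date = NULL) {
  basis <- match.arg(basis)
  chk(nrow(cases) > 0, "uniform_followup: empty case set")
  p <- participants[participants$participant_id %in% cases$participant_id, ]
  if (basis == "survival") {
    min(followup_days(p))
  } else {
    censor_date <- censor_date %||% max(participants$end_of_followup)
    min(as.integer(as.Date(censor_date) - p$enrollment_date))
  }
}

#' Restrict cases to those diagnosed within a uniform follow-up time
#'
#' Partitions cases by whether `diagnosis_date - enrollment_date <=
#' uniform_days` (boundary included, i.e. diagnosis exactly at the cutoff
#' qualifies). Conservation holds by construction: included and excluded
#' cases partition the input.
#'
#' @param cases Case tibble.
#' @param participants Validated participant roster covering every case.
#' @param uniform_days Positive integer cutoff, typically from
#'   [uniform_followup()].
#' @return A `perfect_cohort` list with `uniform_followup_days`,
#'   `included`, and `excluded` case tibbles (each carrying
#'   `days_to_diagnosis`).
#' @export
build_perfect_cohort <- function(cases, participants, uniform_days) {
  chk(uniform_days > 0, "build_perfect_cohort: uniform_days must be positive")
  j <- dplyr::left_join(
    cases, participants[, c("participant_id", "enrollment_date")],
    by = "participant_id")
  chk(!anyNA(j$enrollment_date),
      "build_perfect_cohort: case(s) without a matching participant: %s",
      paste(utils::head(j$participant_id[is.na(j$enrollment_date)], 5),
            collapse = ", "))
  j$days_to_diagnosis <- as.integer(j$diagnosis_date - j$enrollment_date)
  inside <- j$days_to_diagnosis <= uniform_days
  structure(list(
    uniform_followup_days = as.integer(uniform_days),
    included = j[inside, , drop = FALSE],
    excluded = j[!inside, , drop = FALSE]
  ), class = "perfect_cohort")
}

#' Locate each case's first treatment hospitalization
#'
#' The start of treatment is the earliest hospitalization at a secondary or
#' tertiary facility whose discharge diagnosis code carries an upper G.I.
#' prefix. Ties on admission date are broken by earlier discharge date, then
#' by record order. Cases with no qualifying episode are flagged untreated
#' and dropped from cost analysis with a warning.
#'
#' @param cases Case tibble.
#' @param episodes Validated episode tibble.
#' @param code_prefixes Qualifying diagnosis-code prefixes.
#' @return Tibble with one row per treated case: `participant_id`,
#'   `first_episode_id`, `first_admission`.
#' @export
first_treatment_episode <- function(cases, episodes,
                                    code_prefixes = upper_gi_code_prefixes()) {
  qual <- episodes$facility_tier %in% c("secondary", "tertiary") &
    vapply(as.character(episodes$discharge_diagnosis_code),
           function(cd) any(startsWith(cd, code_prefixes)), logical(1),
           USE.NAMES = FALSE)
  e <- episodes[qual & episodes$participant_id %in% cases$participant_id, ]
  e$.ord <- seq_len(nrow(e))
  first <- e %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::arrange(.data$admission_date, .data$discharge_date, .data$.ord,
                   .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::select(participant_id = "participant_id",
                  first_episode_id = "episode_id",
                  first_admission = "admission_date")
  untreated <- setdiff(cases$participant_id, first$participant_id)
  if (length(untreated) > 0) {
    warn(sprintf(
      "first_treatment_episode: %d case(s) with no qualifying secondary/tertiary episode dropped as untreated: %s",
      length(untreated), paste(utils::head(untreated, 5), collapse = ", ")))
  }
  first
}

month_bin <- function(admission, first_admission) {
  1L + as.integer(admission - first_admission) %/% 30L
}

# Per-episode costs restricted to the observation window, in base-year USD.
# Shared by the per-case cost summary, the monthly curve, and the
# accumulated-cost curves so their conservation identities hold exactly.
episode_window_costs <- function(cases, episodes, first_tx, params,
                                 window_months = Inf) {
  e <- dplyr::inner_join(episodes, first_tx, by = "participant_id")
  e <- e[e$admission_date >= e$first_admission, , drop = FALSE]
  e$month <- month_bin(e$admission_date, e$first_admission)
  if (is.finite(window_months)) {
    e <- e[e$month <= window_months, , drop = FALSE]
  }
  yr <- as.integer(format(e$admission_date, "%Y"))
  los <- as.numeric(e$discharge_date - e$admission_date)
  e$ols_days <- los
  e$hosp_usd <- adjust_and_convert(e$total_expense, yr, params)
  e$oop_usd <- adjust_and_convert(e$out_of_pocket_expense, yr, params)
  e$time_usd <- adjust_and_convert(time_cost(los, params), yr, params)
  e
}

#' Monthly average treatment cost since first hospitalization
#'
#' Bins each episode's cost (hospitalization plus time cost, base-year USD)
#' into fixed 30-day months from the case's first treatment admission, and
#' divides each month's total by the number of patients still under
#' observation (alive and uncensored at the bin start). Months with a zero
#' denominator report an average of 0.
#'
#' @param cohort A `perfect_cohort`.
#' @param participants Validated participant roster.
#' @param episodes Validated episode tibble.
#' @param first_tx Output of [first_treatment_episode()].
#' @param params An [economic_params()].
#' @param max_months Number of months to tabulate; defaults to the last
#'   month containing any cost (at least 12).
#' @return Tibble with `month`, `total_cost_in_month`,
#'   `n_under_observation`, `average_cost`.
#' @export
monthly_cost_curve <- function(cohort, participants, episodes, first_tx,
                               params, max_months = NULL) {
  ft <- first_tx[first_tx$participant_id %in%
                   cohort$included$participant_id, , drop = FALSE]
  e <- episode_window_costs(cohort$included, episodes, ft, params)
  e$cost <- e$hosp_usd + e$time_usd
  if (is.null(max_months)) {
    max_months <- max(12L, if (nrow(e) > 0) max(e$month) else 0L)
  }
  totals <- e %>%
    dplyr::group_by(month = .data$month) %>%
    dplyr::summarise(total_cost_in_month = sum(.data$cost), .groups = "drop")

  fu <- dplyr::inner_join(
    ft, participants[, c("participant_id", "end_of_followup")],
    by = "participant_id")
  months <- seq_len(max_months)
  n_obs <- vapply(months, function(m) {
    sum(fu$end_of_followup >= fu$first_admission + 30 * (m - 1))
  }, integer(1))

  curve <- tibble::tibble(month = months, n_under_observation = n_obs) %>%
    dplyr::left_join(totals, by = "month") %>%
    dplyr::mutate(
      total_cost_in_month = dplyr::coalesce(.data$total_cost_in_month, 0),
      average_cost = ifelse(.data$n_under_observation > 0,
                            .data$total_cost_in_month /
                              .data$n_under_observation, 0)
    ) %>%
    dplyr::select("month", "total_cost_in_month", "n_under_observation",
                  "average_cost")
  curve
}

#' Choose the standard observation window from the monthly cost curve
#'
#' Returns the smallest month `m` such that every later month's average cost
#' falls below `epsilon_fraction` times the month-1 average — the point at
#' which the L-shaped cost flow has effectively extinguished. When no such
#' month exists the full curve length is returned with a warning. The
#' pipeline default overrides the automatic choice with a fixed 12-month
#' window.
#'
#' @param curve Output of [monthly_cost_curve()].
#' @param epsilon_fraction Extinction threshold as a fraction of the month-1
#'   average.
#' @return Integer number of months.
#' @export
select_window <- function(curve, epsilon_fraction = 0.05) {
  chk(nrow(curve) > 0, "select_window: empty curve")
  chk(any(curve$average_cost > 0), "select_window: all-zero cost curve")
  threshold <- epsilon_fraction * curve$average_cost[1]
  m <- nrow(curve)
  below_after <- vapply(seq_len(m), function(i) {
    i == m || all(curve$average_cost[(i + 1):m] < threshold)
  }, logical(1))
  if (curve$average_cost[m] >= threshold) {
    warn("select_window: curve never falls below threshold; returning full length")
    return(m)
  }
  which(below_after)[1]
}

#' Compare included and excluded cases for selection bias
#'
#' For each covariate, categorical variables are compared by Pearson's
#' chi-squared test (uncorrected; Fisher's exact test when any expected
#' count is below 5) and continuous variables by the Wilcoxon rank-sum
#' test, both two-sided. Covariates with a single observed level are
#' skipped with a note.
#'
#' @param cohort A `perfect_cohort`.
#' @param participants Validated participant roster.
#' @return Tibble with `covariate`, `test`, `p_value`, `note`.
#' @export
selection_bias_table <- function(cohort, participants) {
  chk(nrow(cohort$included) > 0 && nrow(cohort$excluded) > 0,
      "selection_bias_table: both partitions must be non-empty")
  covars <- function(cs) {
    dplyr::left_join(cs, participants[, c("participant_id",
                                          "age_at_enrollment", "gender",
                                          "education", "occupation")],
                     by = "participant_id")
  }
  inc <- covars(cohort$included)
  exc <- covars(cohort$excluded)
  group <- c(rep("included", nrow(inc)), rep("excluded", nrow(exc)))
  specs <- list(
    age_at_enrollment = "continuous", detection_mode = "categorical",
    gender = "categorical", education = "categorical",
    occupation = "categorical", site = "categorical"
  )
  rows <- purrr::imap(specs, function(kind, v) {
    x <- c(inc[[v]], exc[[v]])
    two_group_test(x, group, kind, v)
  })
  dplyr::bind_rows(rows)
}

two_group_test <- function(x, group, kind, name) {
  keep <- !is.na(x)
  x <- x[keep]; group <- group[keep]
  if (kind == "continuous") {
    if (length(unique(x)) < 2) {
      return(tibble::tibble(covariate = name, test = "rank-sum",
                            p_value = NA_real_, note = "single level, skipped"))
    }
    p <- stats::wilcox.test(x ~ factor(group), exact = FALSE)$p.value
    return(tibble::tibble(covariate = name, test = "rank-sum", p_value = p,
                          note = NA_character_))
  }
  tab <- table(factor(group), x)
  if (ncol(tab) < 2) {
    return(tibble::tibble(covariate = name, test = "chi-squared",
                          p_value = NA_real_, note = "single level, skipped"))
  }
  categorical_test(tab, name)
}

# chi-squared without continuity correction; Fisher fallback for sparse
# tables (any expected count < 5), matching common reporting practice.
categorical_test <- function(tab, name) {
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    return(tibble::tibble(covariate = name, test = "fisher-exact",
                          p_value = p, note = "expected count < 5"))
  }
  tibble::tibble(covariate = name, test = "chi-squared",
                 p_value = ct$p.value, note = NA_character_)
}
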