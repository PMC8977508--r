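# Reporting layer: catastrophic-expenditure classification, per-arm
# per-site-group cost summaries with totals and ratios, accumulated-cost
# temporal curves, expense-classification breakdowns, and the two-arm
# comparison statistics.

#' Round half away from zero
#'
#' Reporting convention for percentages: 0.5 rounds up (away from zero),
#' unlike base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Integer percentage as printed in the report tables
#'
#' @param n Numerator count.
#' @param d Denominator count.
#' @return Integer percent, rounded half away from zero.
#' @export
pct <- function(n, d) {
  round_half_up(100 * n / d)
}

#' Classify catastrophic health expenditure
#'
#' Out-of-pocket spending is catastrophic when it strictly exceeds
#' `che_threshold` (40%) of the household's capacity to pay. Capacity is
#' configured in CNY and converted at the PPP rate when `oop` is in USD, so
#' the comparison is always within one currency.
#'
#' @param oop Out-of-pocket cost per case (vectorized).
#' @param params An [economic_params()].
#' @param currency Currency of `oop`: `"usd"` (default) or `"cny"`.
#' @return Logical vector.
#' @export
is_catastrophic <- function(oop, params, currency = c("usd", "cny")) {
  currency <- match.arg(currency)
  chk(all(oop >= 0), "is_catastrophic: negative out-of-pocket cost")
  capacity <- if (currency == "usd") {
    params$capacity_to_pay / params$ppp_rate
  } else {
    params$capacity_to_pay
  }
  oop > params$che_threshold * capacity
}

#' Mean with quartiles for a skewed cost distribution
#'
#' Costs are summarized as mean (lower quartile, upper quartile), the
#' dispersion-aware form used for skewed claims data. Quartiles use the
#' linear-interpolation convention (`stats::quantile` type 7 by default).
#'
#' @param costs Non-empty numeric vector.
#' @param quantile_type `stats::quantile` algorithm type.
#' @return One-row tibble: `n`, `mean`, `lower_quartile`, `upper_quartile`.
#' @export
summarize_costs <- function(costs, quantile_type = 7) {
  chk(length(costs) >= 1, "summarize_costs: empty cost vector")
  q <- stats::quantile(costs, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  tibble::tibble(n = length(costs), mean = mean(costs),
                 lower_quartile = q[1], upper_quartile = q[2])
}

#' Site group of a cancer site
#'
#' Esophageal cancer and cardial plus non-cardial gastric cancer are the two
#' headline strata; the rare duodenal site reports under `"other"`.
#'
#' @param site Character vector of sites.
#' @return Character vector of site groups.
#' @export
site_group <- function(site) {
  dplyr::case_match(site,
    "esophageal" ~ "esophageal",
    c("cardial", "non_cardial_gastric") ~ "cardial_and_non_cardial_gastric",
    .default = "other")
}

#' Per-arm, per-site-group cost report
#'
#' The per-stratum analog of the headline cost table: mean-with-quartiles
#' summaries of time, hospitalization, treatment, and out-of-pocket cost per
#' case; catastrophic-expenditure counts and fractions; and the stratum's
#' total treatment cost (the exact sum of its cases' treatment costs).
#'
#' @param cases Case tibble carrying an `arm` column.
#' @param costs Output of [case_costs()].
#' @param params An [economic_params()].
#' @return Tibble with one row per (arm, site_group).
#' @export
arm_report <- function(cases, costs, params) {
  j <- dplyr::inner_join(cases, costs, by = "participant_id")
  j$site_group <- site_group(j$site)
  j %>%
    dplyr::group_by(.data$arm, .data$site_group) %>%
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(
        c("time_cost_usd", "hospitalization_cost_usd", "treatment_cost_usd",
          "out_of_pocket_usd"),
        list(mean = mean,
             q1 = ~stats::quantile(.x, 0.25, type = 7, names = FALSE),
             q3 = ~stats::quantile(.x, 0.75, type = 7, names = FALSE))),
      che_count = sum(is_catastrophic(.data$out_of_pocket_usd, params)),
      total_treatment_cost = sum(.data$treatment_cost_usd),
      .groups = "drop") %>%
    dplyr::mutate(che_fraction = .data$che_count / .data$n)
}

#' Screening-to-control total-cost ratio per site group
#'
#' Divides the screening arm's total treatment cost by the control arm's,
#' per site group, reported to two decimals with totals carried at full
#' precision. A zero control total yields an `NA` ratio with a note.
#'
#' @param reports Tibble with columns `arm`, `site_group`,
#'   `total_treatment_cost` (e.g. from [arm_report()]).
#' @return Tibble with `site_group`, `screening_total`, `control_total`,
#'   `ratio`, `note`.
#' @export
arm_totals_and_ratio <- function(reports) {
  wide <- reports %>%
    dplyr::select("arm", "site_group", "total_treatment_cost") %>%
    tidyr::pivot_wider(names_from = "arm",
                       values_from = "total_treatment_cost")
  chk(all(c("screening", "control") %in% names(wide)),
      "arm_totals_and_ratio: both arms must be present")
  wide %>%
    dplyr::transmute(
      site_group = .data$site_group,
      screening_total = .data$screening,
      control_total = .data$control,
      ratio = ifelse(.data$control > 0,
                     round_half_up(.data$screening / .data$control, 2),
                     NA_real_),
      note = ifelse(.data$control > 0, NA_character_,
                    "control total is zero; ratio undefined"))
}

#' Accumulated treatment-cost curves by arm and site group
#'
#' Cumulative sums over months 1..`window_months` of each stratum's total
#' treatment cost (hospitalization plus time cost, base-year USD) in fixed
#' 30-day bins since first treatment admission. The final point of each
#' curve equals the stratum's total in-window treatment cost exactly.
#'
#' @param cases Case tibble carrying an `arm` column.
#' @param episodes Validated episode tibble.
#' @param first_tx Output of [first_treatment_episode()].
#' @param params An [economic_params()].
#' @param window_months Observation window length.
#' @return Tibble with `arm`, `site_group`, `month`, `cost_in_month`,
#'   `accumulated_cost`.
#' @export
accumulated_cost_curves <- function(cases, episodes, first_tx, params,
                                    window_months = 12) {
  e <- episode_window_costs(cases, episodes, first_tx, params, window_months)
  e <- dplyr::inner_join(e, cases[, c("participant_id", "arm", "site")],
                         by = "participant_id")
  e$site_group <- site_group(e$site)
  e %>%
    dplyr::group_by(.data$arm, .data$site_group, .data$month) %>%
    dplyr::summarise(cost_in_month = sum(.data$hosp_usd + .data$time_usd),
                     .groups = "drop") %>%
    tidyr::complete(.data$arm, .data$site_group,
                    month = seq_len(window_months),
                    fill = list(cost_in_month = 0)) %>%
    dplyr::arrange(.data$arm, .data$site_group, .data$month) %>%
    dplyr::group_by(.data$arm, .data$site_group) %>%
    dplyr::mutate(accumulated_cost = cumsum(.data$cost_in_month)) %>%
    dplyr::ungroup()
}

#' Mean in-window cost per case by expense classification and arm
#'
#' Distributes each arm's hospitalization spending across the nine expense
#' classifications: for every classification, the sum of adjusted in-window
#' line-item costs in the arm divided by the number of cases in the arm.
#' Summing the per-classification means recovers the arm's mean
#' hospitalization cost per case. Items with an unknown classification are
#' bucketed as `"other"` with a warning.
#'
#' @param cases Case tibble carrying an `arm` column.
#' @param episodes Validated episode tibble.
#' @param line_items Validated line-item tibble.
#' @param first_tx Output of [first_treatment_episode()].
#' @param params An [economic_params()].
#' @param window_months Observation window length.
#' @return Tibble with `arm`, `classification`, `total_cost_usd`,
#'   `mean_cost_per_case_usd`.
#' @export
classification_breakdown <- function(cases, episodes, line_items, first_tx,
                                     params, window_months = 12) {
  ft <- first_tx[first_tx$participant_id %in% cases$participant_id, ,
                 drop = FALSE]
  e <- dplyr::inner_join(episodes, ft, by = "participant_id")
  e <- e[e$admission_date >= e$first_admission &
           month_bin(e$admission_date, e$first_admission) <= window_months, ]
  li <- dplyr::inner_join(
    line_items,
    e[, c("episode_id", "participant_id")], by = "episode_id")
  unknown <- is.na(li$classification) |
    !(li$classification %in% ncms_classifications())
  if (any(unknown)) {
    warn(sprintf("classification_breakdown: %d line item(s) with unknown classification bucketed as 'other'",
                 sum(unknown)))
    li$classification[unknown] <- "other"
  }
  yr <- as.integer(format(li$service_date, "%Y"))
  li$cost_usd <- adjust_and_convert(li$quantity * li$unit_cost, yr, params)
  n_by_arm <- cases %>% dplyr::count(.data$arm, name = "n_cases")
  li %>%
    dplyr::inner_join(cases[, c("participant_id", "arm")],
                      by = "participant_id") %>%
    dplyr::group_by(.data$arm, .data$classification) %>%
    dplyr::summarise(total_cost_usd = sum(.data$cost_usd), .groups = "drop") %>%
    dplyr::inner_join(n_by_arm, by = "arm") %>%
    dplyr::mutate(mean_cost_per_case_usd = .data$total_cost_usd /
                    .data$n_cases) %>%
    dplyr::select("arm", "classification", "total_cost_usd",
                  "mean_cost_per_case_usd")
}

fmt_count_pct <- function(n, d) {
  sprintf("%d (%d%%)", n, pct(n, d))
}

fmt_median_q <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  sprintf("%s (%s; %s)", format(round_half_up(q[2])),
          format(round_half_up(q[1])), format(round_half_up(q[3])))
}

#' Two-arm comparison of cohort characteristics
#'
#' The baseline-characteristics analog: per-arm counts with integer
#' percentages (computed within non-missing values) for categorical
#' covariates and median (Q1; Q3) for continuous ones, with two-sided
#' p-values from Pearson's chi-squared test (uncorrected; Fisher's exact
#' test for sparse tables) or the Wilcoxon rank-sum test. Covariates that
#' are entirely missing or single-level are skipped with a note.
#'
#' @param cases Included-case tibble carrying `arm`, `site`, `stage`,
#'   `therapy`, `detection_mode`, and `days_to_diagnosis`.
#' @param participants Validated participant roster.
#' @param costs Optional [case_costs()] output contributing
#'   episode-frequency and length-of-stay rows.
#' @return Tibble with `variable`, `level`, `control`, `screening`, `test`,
#'   `p_value`, `note` (p reported on each variable's first row).
#' @export
compare_arms_table1 <- function(cases, participants, costs = NULL) {
  chk(all(c("screening", "control") %in% cases$arm),
      "compare_arms_table1: both arms must be non-empty")
  df <- dplyr::left_join(
    cases,
    participants[, c("participant_id", "age_at_enrollment", "gender",
                     "education", "occupation",
                     "household_income_per_capita")],
    by = "participant_id")
  df$age_at_diagnosis <- floor(df$age_at_enrollment +
                                 df$days_to_diagnosis / 365.25)
  if (!is.null(costs)) {
    df <- dplyr::left_join(df, costs, by = "participant_id")
  }
  specs <- list(
    age_at_diagnosis = "continuous",
    gender = "categorical",
    education = "categorical",
    occupation = "categorical",
    household_income_per_capita = "continuous",
    site = "categorical",
    stage = "categorical",
    therapy = "categorical"
  )
  if (!is.null(costs)) {
    specs$n_episodes <- "continuous"
    specs$ols_days <- "continuous"
  }
  rows <- purrr::imap(specs, function(kind, v) {
    table1_row(df, v, kind)
  })
  dplyr::bind_rows(rows)
}

table1_row <- function(df, v, kind) {
  x <- df[[v]]
  keep <- !is.na(x)
  if (!any(keep)) {
    return(tibble::tibble(variable = v, level = NA_character_,
                          control = NA_character_, screening = NA_character_,
                          test = NA_character_, p_value = NA_real_,
                          note = "all missing, skipped"))
  }
  x <- x[keep]
  arm <- df$arm[keep]
  if (kind == "continuous") {
    p <- if (length(unique(x)) < 2) NA_real_ else
      stats::wilcox.test(x ~ factor(arm), exact = FALSE)$p.value
    return(tibble::tibble(
      variable = v, level = NA_character_,
      control = fmt_median_q(x[arm == "control"]),
      screening = fmt_median_q(x[arm == "screening"]),
      test = "rank-sum", p_value = p, note = NA_character_))
  }
  tab <- table(factor(arm, levels = c("control", "screening")), x)
  if (ncol(tab) < 2) {
    tst <- tibble::tibble(test = NA_character_, p_value = NA_real_,
                          note = "single level, skipped")
  } else {
    tst <- categorical_test(tab, v)[, c("test", "p_value", "note")]
  }
  lv <- colnames(tab)
  tibble::tibble(
    variable = v, level = lv,
    control = fmt_count_pct(as.integer(tab["control", lv]),
                            sum(tab["control", ])),
    screening = fmt_count_pct(as.integer(tab["screening", lv]),
                              sum(tab["screening", ])),
    test = c(tst$test, rep(NA_character_, length(lv) - 1)),
    p_value = c(tst$p_value, rep(NA_real_, length(lv) - 1)),
    note = c(tst$note, rep(NA_character_, length(lv) - 1)))
}

#' Univariate logistic regression on cost impact factors
#'
#' Fits one maximum-likelihood logistic regression per covariate against a
#' binary outcome (by default catastrophic-expenditure status) and reports
#' odds ratios with Wald 95% confidence intervals and p-values. Fits
#' showing perfect separation are flagged and their estimates suppressed.
#'
#' @param data Data frame containing `outcome` and the covariates.
#' @param outcome Name of the logical/binary outcome column.
#' @param covariates Character vector of covariate column names.
#' @return Tibble with `covariate`, `term`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `note`.
#' @export
cost_factor_regression <- function(data, outcome = "che",
                                   covariates = NULL) {
  y <- data[[outcome]]
  chk(!is.null(y), "cost_factor_regression: outcome column '%s' not found",
      outcome)
  y <- as.logical(y)
  chk(length(unique(y[!is.na(y)])) == 2,
      "cost_factor_regression: degenerate outcome (constant)")
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c(outcome, "participant_id"))
  }
  rows <- purrr::map(covariates, function(v) {
    d <- data[!is.na(data[[v]]) & !is.na(y), c(outcome, v)]
    names(d) <- c(".y", ".x")
    d$.y <- as.logical(d$.y)
    if (length(unique(d$.x)) < 2 || length(unique(d$.y)) < 2) {
      return(tibble::tibble(covariate = v, term = NA_character_,
                            odds_ratio = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p_value = NA_real_,
                            note = "degenerate covariate or outcome, skipped"))
    }
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(.y ~ .x, data = d, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      })
    cf <- summary(fit)$coefficients
    terms <- setdiff(rownames(cf), "(Intercept)")
    est <- cf[terms, "Estimate"]
    se <- cf[terms, "Std. Error"]
    pv <- cf[terms, "Pr(>|z|)"]
    if (sep || any(abs(est) > 15)) {
      return(tibble::tibble(covariate = v, term = sub("^\\.x", "", terms),
                            odds_ratio = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p_value = NA_real_,
                            note = "perfect separation, estimate suppressed"))
    }
    tibble::tibble(covariate = v, term = sub("^\\.x", "", terms),
                   odds_ratio = exp(est),
                   ci_low = exp(est - stats::qnorm(0.975) * se),
                   ci_high = exp(est + stats::qnorm(0.975) * se),
                   p_value = pv, note = NA_character_)
  })
  dplyr::bind_rows(rows)
}
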