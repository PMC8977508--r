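test_that("catastrophic expenditure uses a strict 40%-of-capacity cutoff", {
  p <- economic_params()
  capacity_usd <- 10906 / 3.55
  expect_false(is_catastrophic(0, p))
  expect_true(is_catastrophic(5972, p))
  # exactly at the threshold is not catastrophic (strict inequality)
  expect_false(is_catastrophic(0.40 * capacity_usd, p))
  expect_true(is_catastrophic(0.40 * capacity_usd + 0.01, p))
  # CNY comparison path
  expect_true(is_catastrophic(5000, p, currency = "cny"))
  expect_false(is_catastrophic(4000, p, currency = "cny"))

  # monotone in the threshold: raising it never adds cases
  oops <- c(0, 500, 1000, 1228, 1229, 3000, 6000)
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(th) {
    sum(is_catastrophic(oops, economic_params(che_threshold = th)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cost summaries report mean with linear-interpolation quartiles", {
  s <- summarize_costs(10)
  expect_equal(unlist(s[, c("mean", "lower_quartile", "upper_quartile")]),
               c(mean = 10, lower_quartile = 10, upper_quartile = 10))
  s <- summarize_costs(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$lower_quartile, 1.75)
  expect_equal(s$upper_quartile, 3.25)
  s <- summarize_costs(rep(7, 5))
  expect_equal(s$mean, s$lower_quartile)
  expect_equal(s$mean, s$upper_quartile)
  expect_error(summarize_costs(numeric(0)), "empty")
})

test_that("arm totals and ratios handle equal and zero totals", {
  rep <- tibble::tibble(
    arm = c("screening", "control", "screening", "control"),
    site_group = c("a", "a", "b", "b"),
    total_treatment_cost = c(500, 500, 100, 0))
  r <- arm_totals_and_ratio(rep)
  expect_equal(r$ratio[r$site_group == "a"], 1.00)
  expect_true(is.na(r$ratio[r$site_group == "b"]))
  expect_match(r$note[r$site_group == "b"], "undefined")
  expect_error(arm_totals_and_ratio(rep[1:2, ][rep$arm[1:2] == "screening", ]),
               "both arms")
})

mk_report_fixture <- function() {
  cases <- tibble::tibble(
    participant_id = c("S1", "S2", "C1", "C2"),
    arm = c("screening", "screening", "control", "control"),
    site = "esophageal",
    detection_mode = c("screen_detected", "screen_detected",
                       "clinically_diagnosed", "clinically_diagnosed"),
    diagnosis_date = as.Date("2018-01-01"),
    stage = c("0-I", "0-I", "III", "IV"),
    therapy = c("endoscopic", "endoscopic", "radio_chemo_only",
                "radio_chemo_only"),
    days_to_diagnosis = 100L)
  episodes <- tibble::tibble(
    episode_id = paste0("E", 1:4),
    participant_id = c("S1", "S2", "C1", "C2"),
    facility_tier = "secondary",
    admission_date = as.Date("2018-02-01"),
    discharge_date = as.Date("2018-02-11"),
    discharge_diagnosis_code = "C15.3",
    total_expense = c(1000, 2000, 3000, 4000),
    reimbursed_expense = c(500, 1000, 1500, 2000),
    out_of_pocket_expense = c(500, 1000, 1500, 2000))
  line_items <- tibble::tibble(
    episode_id = paste0("E", 1:4),
    service_date = as.Date("2018-02-01"),
    classification = c("surgery", "surgery", "radiation", "radiation"),
    quantity = 1,
    unit_cost = c(1000, 2000, 3000, 4000),
    out_of_pocket_portion = c(500, 1000, 1500, 2000))
  first_tx <- tibble::tibble(
    participant_id = c("S1", "S2", "C1", "C2"),
    first_episode_id = paste0("E", 1:4),
    first_admission = as.Date("2018-02-01"))
  list(cases = cases, episodes = episodes, line_items = line_items,
       first_tx = first_tx)
}

test_that("arm report satisfies the cost-table identities", {
  f <- mk_report_fixture()
  p <- flat_params()
  cc <- case_costs(f$cases, f$episodes, f$first_tx, p)
  rep <- arm_report(f$cases, cc, p)
  expect_equal(rep$treatment_cost_usd_mean,
               rep$time_cost_usd_mean + rep$hospitalization_cost_usd_mean)
  expect_equal(rep$total_treatment_cost, rep$n * rep$treatment_cost_usd_mean)
  expect_true(all(rep$che_count <= rep$n))
  ratios <- arm_totals_and_ratio(rep)
  sc <- sum(cc$treatment_cost_usd[f$cases$arm == "screening"])
  co <- sum(cc$treatment_cost_usd[f$cases$arm == "control"])
  expect_equal(ratios$ratio, round(sc / co, 2))
})

test_that("accumulated curves are flat after a single month-1 cost and end at the stratum total", {
  f <- mk_report_fixture()
  p <- flat_params(ani = 0)
  ac <- accumulated_cost_curves(f$cases, f$episodes, f$first_tx, p, 12)
  one <- ac[ac$arm == "screening", ]
  expect_equal(nrow(one), 12)
  expect_true(all(one$accumulated_cost == one$accumulated_cost[1]))
  cc <- case_costs(f$cases, f$episodes, f$first_tx, p, 12)
  for (a in c("screening", "control")) {
    expect_equal(max(ac$accumulated_cost[ac$arm == a]),
                 sum(cc$treatment_cost_usd[f$cases$arm == a]))
  }
})

test_that("classification breakdown localizes radiation fees and partitions costs", {
  f <- mk_report_fixture()
  p <- flat_params(ani = 0)
  bd <- classification_breakdown(f$cases, f$episodes, f$line_items,
                                 f$first_tx, p, 12)
  rad_ctrl <- bd$mean_cost_per_case_usd[bd$arm == "control" &
                                          bd$classification == "radiation"]
  rad_scr <- bd$mean_cost_per_case_usd[bd$arm == "screening" &
                                         bd$classification == "radiation"]
  expect_equal(rad_ctrl, 3500)  # (3000 + 4000) / 2 cases
  expect_equal(length(rad_scr), 0)  # no radiation items in screening arm

  # partition identity: per-class means sum to mean hospitalization cost
  cc <- case_costs(f$cases, f$episodes, f$first_tx, p, 12)
  for (a in c("screening", "control")) {
    expect_equal(sum(bd$mean_cost_per_case_usd[bd$arm == a]),
                 mean(cc$hospitalization_cost_usd[f$cases$arm == a]),
                 tolerance = 1e-9)
  }

  # unknown classifications are bucketed with a warning
  li <- f$line_items
  li$classification[1] <- NA
  expect_warning(
    bd2 <- classification_breakdown(f$cases, f$episodes, li, f$first_tx,
                                    p, 12),
    "unknown classification")
  expect_true("other" %in% bd2$classification)
})

test_that("two-arm comparison table formats counts and picks the right test", {
  # site distribution (24, 9, 8) vs (82, 7, 17): sparse cells trigger the
  # exact test, whose p matches the reported 0.023
  n_ctrl <- c(esophageal = 24, cardial = 9, non_cardial_gastric = 8)
  n_scr <- c(esophageal = 82, cardial = 7, non_cardial_gastric = 17)
  cases <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:147),
    arm = rep(c("control", "screening"), c(41, 106)),
    site = c(rep(names(n_ctrl), n_ctrl), rep(names(n_scr), n_scr)),
    detection_mode = "clinically_diagnosed",
    diagnosis_date = as.Date("2015-01-01"),
    stage = rep(c("II", "III"), length.out = 147),
    therapy = "single_radical_resection",
    days_to_diagnosis = 300L)
  participants <- tibble::tibble(
    participant_id = cases$participant_id,
    arm = cases$arm,
    enrollment_date = as.Date("2014-01-01"),
    end_of_followup = as.Date("2018-12-31"),
    age_at_enrollment = rep(c(55, 60, 65), length.out = 147),
    gender = rep(c("male", "female"), length.out = 147),
    education = "primary-or-below",
    occupation = "manual_worker",
    household_income_per_capita = rep(c(1000, 3000, 9000),
                                      length.out = 147))
  t1 <- compare_arms_table1(cases, participants)
  site <- t1[t1$variable == "site", ]
  expect_equal(site$test[1], "fisher-exact")
  expect_equal(site$p_value[1], 0.023, tolerance = 0.02)
  # formatted percentage for esophageal cancer in the screening arm: 82/106
  expect_match(site$screening[site$level == "esophageal"], "82 \\(77%\\)")
  expect_match(site$control[site$level == "esophageal"], "24 \\(59%\\)")

  # identical arms give p = 1 on a dense categorical row
  cases2 <- cases
  cases2$site <- rep(rep(c("esophageal", "cardial"), each = 20),
                     length.out = 147)
  t2 <- compare_arms_table1(cases2, participants)
  expect_equal(t2$test[t2$variable == "gender"][1], "chi-squared")
  expect_gt(t2$p_value[t2$variable == "gender"][1], 0.5)

  # single-level covariate is skipped with a note
  expect_match(t1$note[t1$variable == "education"][1], "skipped")
})

test_that("percentage formatter rounds half away from zero", {
  expect_equal(pct(58, 86), 67)
  expect_equal(pct(82, 106), 77)
  expect_equal(pct(240, 255), 94)
  expect_equal(pct(1, 8), 13)   # 12.5 rounds up, not to even
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(3071.83), 3072)
})

test_that("univariate logistic regression covers the null and flags separation", {
  set.seed(99)
  # null coverage: covariate independent of outcome; 95% Wald CI should
  # cover OR = 1 in at least 90 of 100 replicates at n = 500
  covered <- 0L
  for (r in 1:100) {
    d <- data.frame(che = stats::runif(500) < 0.4,
                    x = stats::rnorm(500))
    fit <- cost_factor_regression(d, covariates = "x")
    covered <- covered + as.integer(fit$ci_low <= 1 && fit$ci_high >= 1)
  }
  expect_gte(covered, 90)

  # constant outcome is degenerate
  expect_error(
    cost_factor_regression(data.frame(che = rep(TRUE, 10), x = 1:10)),
    "degenerate outcome")

  # perfect separation is flagged and the estimate suppressed
  d <- data.frame(che = rep(c(FALSE, TRUE), each = 25),
                  x = rep(c(0, 1), each = 25))
  fit <- cost_factor_regression(d, covariates = "x")
  expect_match(fit$note, "separation")
  expect_true(is.na(fit$odds_ratio))
})
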