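mk_participants <- function(ids, enroll, end, arm = "screening") {
  tibble::tibble(
    participant_id = ids, arm = arm,
    enrollment_date = as.Date(enroll), end_of_followup = as.Date(end),
    age_at_enrollment = 60, gender = "male",
    education = "primary-or-below", occupation = "manual_worker",
    household_income_per_capita = 3000)
}

mk_cases <- function(ids, diagnosis, site = "esophageal") {
  tibble::tibble(
    participant_id = ids, site = site,
    detection_mode = "clinically_diagnosed",
    diagnosis_date = as.Date(diagnosis), stage = "II",
    therapy = "single_radical_resection")
}

mk_episode <- function(id, pid, adm, dis = NULL, tier = "secondary",
                       code = "C15.3", total = 1000, reimb = 500) {
  tibble::tibble(
    episode_id = id, participant_id = pid, facility_tier = tier,
    admission_date = as.Date(adm),
    discharge_date = as.Date(dis %||% adm) ,
    discharge_diagnosis_code = code, total_expense = total,
    reimbursed_expense = reimb, out_of_pocket_expense = total - reimb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("uniform_followup takes the minimum over case participants", {
  p <- mk_participants(c("A", "B", "C"), "2012-01-01",
                       as.Date("2012-01-01") + c(900, 857, 1200))
  cs <- mk_cases(c("A", "B", "C"), "2012-06-01")
  expect_identical(uniform_followup(cs, p), 857L)
  expect_identical(uniform_followup(cs[2, ], p), 857L)
  # singleton and ties are benign
  p1 <- mk_participants("A", "2012-01-01", as.Date("2012-01-01") + 400)
  expect_identical(uniform_followup(mk_cases("A", "2012-02-01"), p1), 400L)
  pt <- mk_participants(c("A", "B"), "2012-01-01",
                        as.Date("2012-01-01") + c(857, 857))
  expect_identical(uniform_followup(mk_cases(c("A", "B"), "2012-03-01"), pt),
                   857L)
  expect_error(uniform_followup(cs[0, ], p), "empty case set")
})

test_that("accrual basis measures enrollment-to-censor distance, ignoring deaths", {
  p <- mk_participants(c("A", "B"), c("2012-01-01", "2014-01-01"),
                       c("2013-01-01", "2018-12-31"))  # A died early
  cs <- mk_cases(c("A", "B"), c("2012-06-01", "2014-06-01"))
  expect_identical(uniform_followup(cs, p, basis = "survival"), 366L)
  # censor inferred as the roster's latest end of follow-up (2018-12-31);
  # the minimum is then driven by B's later enrollment
  expect_identical(
    uniform_followup(cs, p, basis = "accrual"),
    as.integer(as.Date("2018-12-31") - as.Date("2014-01-01")))
})

test_that("perfect cohort includes the boundary and conserves cases", {
  p <- mk_participants(c("A", "B", "C"), "2012-01-01", "2018-12-31")
  cs <- mk_cases(c("A", "B", "C"),
                 as.Date("2012-01-01") + c(857, 858, 100))
  pc <- build_perfect_cohort(cs, p, 857)
  expect_setequal(pc$included$participant_id, c("A", "C"))
  expect_setequal(pc$excluded$participant_id, "B")
  expect_equal(nrow(pc$included) + nrow(pc$excluded), nrow(cs))
  expect_error(build_perfect_cohort(mk_cases("Z", "2012-06-01"), p, 857),
               "without a matching participant")
})

test_that("shrinking the cutoff never adds cases to the cohort", {
  set.seed(41)
  p <- mk_participants(sprintf("P%02d", 1:40), "2012-01-01", "2018-12-31")
  cs <- mk_cases(p$participant_id,
                 as.Date("2012-01-01") + sample(1:2000, 40))
  sizes <- vapply(c(2000, 1500, 857, 400, 100, 1),
                  function(u) nrow(build_perfect_cohort(cs, p, u)$included),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[1], 40)
})

test_that("first treatment episode honors tier, code, and tie-breaks", {
  cs <- mk_cases("A", "2012-02-01")
  eps <- dplyr::bind_rows(
    mk_episode("E1", "A", "2012-02-10", "2012-02-20", tier = "secondary"),
    mk_episode("E2", "A", "2012-03-10", "2012-03-20", tier = "tertiary"))
  ft <- first_treatment_episode(cs, eps)
  expect_equal(ft$first_episode_id, "E1")

  # primary-tier only: flagged untreated with a warning, dropped
  eps_p <- mk_episode("E1", "A", "2012-02-10", tier = "primary")
  expect_warning(ft <- first_treatment_episode(cs, eps_p), "untreated")
  expect_equal(nrow(ft), 0)

  # non-qualifying code at the right tier is also not a treatment start
  eps_j <- mk_episode("E1", "A", "2012-02-10", code = "J18.9")
  expect_warning(first_treatment_episode(cs, eps_j), "untreated")

  # same-day admissions: earlier discharge wins
  tie <- dplyr::bind_rows(
    mk_episode("E1", "A", "2012-02-10", "2012-02-25", tier = "secondary"),
    mk_episode("E2", "A", "2012-02-10", "2012-02-15", tier = "tertiary"))
  ft <- first_treatment_episode(cs, tie)
  expect_equal(ft$first_episode_id, "E2")
})

test_that("monthly cost curve reproduces hand-traced averages and denominators", {
  params <- flat_params(ani = 0)
  p <- mk_participants(c("A", "B"), "2012-01-01", "2018-12-31")
  cs <- mk_cases(c("A", "B"), "2012-02-01")
  eps <- dplyr::bind_rows(
    mk_episode("E1", "A", "2012-02-05", total = 100, reimb = 50),
    mk_episode("E2", "B", "2012-02-05", total = 300, reimb = 150))
  pc <- build_perfect_cohort(cs, p, 857)
  ft <- first_treatment_episode(cs, eps)
  curve <- monthly_cost_curve(pc, p, eps, ft, params)
  expect_equal(curve$average_cost[1], 200)
  expect_equal(curve$average_cost[2], 0)
  expect_equal(curve$n_under_observation[1:2], c(2L, 2L))

  # death in month 2 removes the patient from later denominators
  p2 <- p
  p2$end_of_followup[1] <- as.Date("2012-02-05") + 40
  curve2 <- monthly_cost_curve(pc, p2, eps, ft, params)
  expect_equal(curve2$n_under_observation[1:3], c(2L, 2L, 1L))
  # costs already booked in month 1 are unaffected
  expect_equal(curve2$total_cost_in_month[1], 400)
})

test_that("curve conserves total window-assigned cost on synthetic data", {
  params <- flat_params(ani = 0)
  d <- generate_claims(small_config(seed = 6, n_per_arm = 600))
  treated <- verify_cases(d)
  treated <- treated[treated$verified, ]
  u <- uniform_followup(treated, d$participants, basis = "accrual")
  pc <- build_perfect_cohort(treated, d$participants, u)
  ft <- first_treatment_episode(pc$included, d$episodes)
  curve <- monthly_cost_curve(pc, d$participants, d$episodes, ft, params)
  # independent oracle: nominal CNY totals of cohort episodes at or after
  # each case's first treatment admission (flat params make USD == CNY)
  e <- merge(d$episodes, ft, by = "participant_id")
  oracle <- sum(e$total_expense[e$admission_date >= e$first_admission])
  expect_equal(sum(curve$total_cost_in_month), oracle, tolerance = 1e-9)
  # identity between columns: average * denominator == total
  nz <- curve$n_under_observation > 0
  expect_equal(curve$average_cost[nz] * curve$n_under_observation[nz],
               curve$total_cost_in_month[nz], tolerance = 1e-6)
})

test_that("select_window scans for cost extinction", {
  curve <- tibble::tibble(month = 1:5,
                          total_cost_in_month = c(1000, 500, 10, 0, 0),
                          n_under_observation = 1L,
                          average_cost = c(1000, 500, 10, 0, 0))
  expect_equal(select_window(curve, 0.05), 2)
  flat <- curve
  flat$average_cost <- c(1000, 900, 800, 700, 600)
  expect_warning(m <- select_window(flat, 0.05), "never falls below")
  expect_equal(m, 5)
  zero <- curve
  zero$average_cost <- 0
  expect_error(select_window(zero, 0.05), "all-zero")
})

test_that("faster cost decay shortens the selected window", {
  win <- function(hl) {
    run <- suppressWarnings(run_pipeline(
      generator_config = small_config(seed = 19, n_per_arm = 600,
                                      cost_decay_halflife_months = hl),
      window = "auto"))
    run$window_months
  }
  expect_lte(win(1), win(4))
})

test_that("selection bias table runs the right test per covariate", {
  p <- mk_participants(sprintf("P%02d", 1:60), "2012-01-01", "2018-12-31")
  p$gender <- c(rep("male", 10), rep("female", 20),
                rep("male", 20), rep("female", 10))
  cs <- mk_cases(p$participant_id,
                 as.Date("2012-01-01") + c(rep(100, 30), rep(900, 30)))
  pc <- build_perfect_cohort(cs, p, 857)
  tab <- selection_bias_table(pc, p)
  # gender split 10/20 vs 20/10: hand-computed chi-squared = 6.667
  # (uncorrected), p = 0.0098
  g <- tab[tab$covariate == "gender", ]
  expect_equal(g$test, "chi-squared")
  expect_equal(g$p_value, 0.009823, tolerance = 1e-3)
  # constant covariates are skipped with a note
  expect_match(tab$note[tab$covariate == "age_at_enrollment"], "skipped")
  expect_match(tab$note[tab$covariate == "site"], "skipped")
})
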