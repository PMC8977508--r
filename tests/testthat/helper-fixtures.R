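# Small in-code fixtures shared across test files.

fix_participants <- function() {
  tibble::tibble(
    participant_id = c("P1", "P2", "P3"),
    arm = c("screening", "control", "control"),
    enrollment_date = as.Date(c("2012-01-01", "2012-03-01", "2013-01-01")),
    end_of_followup = as.Date(c("2014-05-07", "2013-03-01", "2018-12-31")),
    age_at_enrollment = c(60, 55, 48),
    gender = c("male", "female", "male"),
    education = c("primary-or-below", "middle-or-above", "primary-or-below"),
    occupation = c("manual_worker", "manual_worker", "technical_staff"),
    household_income_per_capita = c(3000, 5000, 2000)
  )
}

fix_cases <- function() {
  tibble::tibble(
    participant_id = c("P1", "P2"),
    site = c("esophageal", "non_cardial_gastric"),
    detection_mode = c("screen_detected", "clinically_diagnosed"),
    diagnosis_date = as.Date(c("2012-06-01", "2012-09-01")),
    stage = c("0-I", "III"),
    therapy = c("single_radical_resection", "radio_chemo_only")
  )
}

fix_episodes <- function() {
  tibble::tibble(
    episode_id = c("E1", "E2", "E3", "E4"),
    participant_id = c("P1", "P1", "P2", "P3"),
    facility_tier = c("secondary", "tertiary", "tertiary", "primary"),
    admission_date = as.Date(c("2012-06-10", "2012-08-15", "2012-09-05",
                               "2014-02-01")),
    discharge_date = as.Date(c("2012-06-30", "2012-08-25", "2012-10-05",
                               "2014-02-05")),
    discharge_diagnosis_code = c("C15.3", "C15.3", "C16.2", "J18.9"),
    total_expense = c(10000, 4000, 20000, 1500),
    reimbursed_expense = c(6000, 2400, 11000, 900),
    out_of_pocket_expense = c(4000, 1600, 9000, 600)
  )
}

fix_line_items <- function() {
  tibble::tibble(
    episode_id = c("E1", "E1", "E2", "E3", "E3", "E4"),
    service_date = as.Date(c("2012-06-10", "2012-06-12", "2012-08-15",
                             "2012-09-05", "2012-09-06", "2014-02-01")),
    classification = c("surgery", "bed", "medication_other", "radiation",
                       "medication_chemo", "medication_other"),
    quantity = c(1, 20, 1, 1, 1, 1),
    unit_cost = c(7000, 150, 4000, 12000, 8000, 1500),
    out_of_pocket_portion = c(2800, 1200, 1600, 5400, 3600, 600)
  )
}

fix_data <- function() {
  validate_claims_data(list(
    participants = fix_participants(), cases = fix_cases(),
    episodes = fix_episodes(), line_items = fix_line_items()
  ))
}

# Degenerate economic parameters: zero discount, flat CPI, PPP 1, so
# adjusted costs equal nominal CNY sums.
flat_params <- function(...) {
  economic_params(discount_rate = 0,
                  cpi_medical = default_cpi_medical(2010:2020,
                                                    annual_inflation = 0),
                  ppp_rate = 1, ...)
}

# Small boosted-incidence generator config so a few hundred cases appear
# quickly in tests.
small_config <- function(seed = 11, n_per_arm = 800,
                         incidence = c(esophageal = 900, cardial = 220,
                                       non_cardial_gastric = 230,
                                       duodenal = 5), ...) {
  claims_generator_config(seed = seed, n_per_arm = n_per_arm,
                          annual_incidence_by_site = incidence, ...)
}
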