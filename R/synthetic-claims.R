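# Synthetic claims generator. Emulates the data-generating features the
# downstream analysis relies on: a two-arm trial with staggered enrollment
# (screening arm enrolled earlier), screening-induced down-staging,
# stage-dependent therapy mix, heavy-tailed (lognormal) hospitalization
# costs itemized into nine expense classifications, an L-shaped monthly cost
# flow decaying geometrically from the first hospitalization, partial
# reimbursement, and death-truncated follow-up with administrative
# censoring. It does not model village-level cluster randomization or
# screening test characteristics.

default_stage_distribution <- function() {
  list(
    # screen-detected disease skews early; clinical presentation skews late
    screen_detected = c("0-I" = 0.78, "II" = 0.17, "III" = 0.03, "IV" = 0.02),
    clinical        = c("0-I" = 0.05, "II" = 0.14, "III" = 0.36, "IV" = 0.45)
  )
}

default_therapy_given_stage <- function() {
  m <- rbind(
    "0-I" = c(endoscopic = 0.20, single_radical_resection = 0.72,
              radical_plus_adjuvant = 0.05, radio_chemo_only = 0.02,
              supportive = 0.01),
    "II"  = c(0.02, 0.48, 0.40, 0.07, 0.03),
    "III" = c(0.00, 0.10, 0.50, 0.25, 0.15),
    "IV"  = c(0.00, 0.02, 0.13, 0.40, 0.45)
  )
  colnames(m) <- therapy_classes()
  m
}

# Per-therapy lognormal location for a first-month episode's total cost
# (CNY, log scale) and the split of that cost across the nine expense
# classifications. Anchored so that an early-stage resection-dominated case
# lands near 45,000 CNY (~13,000 USD at PPP 3.55) while late-stage
# multi-episode adjuvant/radio-chemotherapy care, whose radiation and
# chemotherapy-medication fees dominate, accumulates to 80,000-100,000 CNY
# (~23,000-28,000 USD). The gap is wide enough that per-case costs stay
# lower in the down-staged screening arm even though its earlier service
# years are inflated more by discounting and the medical CPI.
default_cost_model <- function() {
  meanlog <- c(endoscopic = log(15000), single_radical_resection = log(33000),
               radical_plus_adjuvant = log(45000),
               radio_chemo_only = log(36000), supportive = log(12000))
  shares <- rbind(
    endoscopic               = c(0.08, 0.04, 0.10, 0.12, 0.10, 0.40, 0.00, 0.00, 0.16),
    single_radical_resection = c(0.08, 0.05, 0.06, 0.08, 0.08, 0.40, 0.00, 0.00, 0.25),
    radical_plus_adjuvant    = c(0.07, 0.05, 0.05, 0.07, 0.07, 0.25, 0.12, 0.20, 0.12),
    radio_chemo_only         = c(0.08, 0.06, 0.05, 0.08, 0.08, 0.00, 0.25, 0.30, 0.10),
    supportive               = c(0.15, 0.12, 0.08, 0.08, 0.10, 0.00, 0.00, 0.05, 0.42)
  )
  colnames(shares) <- ncms_classifications()
  list(meanlog_by_therapy = meanlog, sdlog = 0.5, class_shares = shares)
}

#' Configuration for the synthetic claims generator
#'
#' Defaults mirror the study conditions of the parent screening trial: two
#' arms of 17,000 participants aged 45-69, screening arm enrolled during
#' 2012-2013 and control arm during 2013-2016, administrative censoring at
#' 2018-12-31, esophageal-cancer incidence 25.58 per 100,000 person-years
#' versus 12.45 for cardial plus non-cardial gastric cancer, and an
#' L-shaped cost flow with a 3-month geometric half-life so monthly average
#' costs are near zero by 12 months.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @param n_per_arm Participants per arm.
#' @param enrollment_window_screening,enrollment_window_control Two ISO
#'   dates each; the screening window must start no later than the control
#'   window (staggered enrollment).
#' @param censor_date Administrative end of follow-up.
#' @param annual_incidence_by_site Clinical incidence per 100,000
#'   person-years, named by site.
#' @param screening_case_multiplier Multiplier on case occurrence in the
#'   screening arm, emulating the prevalence harvest of endoscopic
#'   screening (more cases, found earlier).
#' @param screen_detection_fraction Probability that a screening-arm case is
#'   screen-detected (diagnosed near enrollment, early-stage-heavy) rather
#'   than clinically diagnosed.
#' @param stage_distribution List with probability vectors
#'   `screen_detected` and `clinical` over stages 0-I..IV (each summing to 1
#'   within 1e-9).
#' @param therapy_given_stage Row-stochastic matrix stage x therapy.
#' @param episode_lambda_by_stage Poisson mean of additional hospitalizations
#'   beyond the first, per stage.
#' @param los_median_by_stage Median per-episode length of stay (days).
#' @param los_sdlog Lognormal log-scale spread of length of stay.
#' @param cost_model List with `meanlog_by_therapy`, `sdlog`, and
#'   row-stochastic `class_shares` (therapy x nine classifications).
#' @param cost_decay_halflife_months Half-life (months since first
#'   hospitalization) of the geometric decay applied to episode costs.
#' @param reimbursement_rate Mean reimbursed fraction of each episode's
#'   total expense.
#' @param reimbursement_concentration Beta concentration of the per-episode
#'   reimbursement draw around `reimbursement_rate`.
#' @param death_hazard_by_stage Annual death hazard after diagnosis, per
#'   stage; death truncates follow-up and episode generation.
#' @param background_episode_rate Probability that a cancer-free participant
#'   contributes one unrelated hospitalization (exercises case
#'   verification).
#' @return A validated `claims_generator_config` list.
#' @export
claims_generator_config <- function(
    seed = 1L,
    n_per_arm = 17000L,
    enrollment_window_screening = c("2012-01-01", "2013-12-31"),
    enrollment_window_control = c("2013-06-01", "2016-06-30"),
    censor_date = "2018-12-31",
    annual_incidence_by_site = c(esophageal = 25.58, cardial = 6.0,
                                 non_cardial_gastric = 6.35, duodenal = 0.10),
    screening_case_multiplier = 2.5,
    screen_detection_fraction = 0.8,
    stage_distribution = default_stage_distribution(),
    therapy_given_stage = default_therapy_given_stage(),
    episode_lambda_by_stage = c("0-I" = 0.3, "II" = 1.0, "III" = 2.0,
                                "IV" = 2.5),
    los_median_by_stage = c("0-I" = 16, "II" = 15, "III" = 13, "IV" = 12),
    los_sdlog = 0.45,
    cost_model = default_cost_model(),
    cost_decay_halflife_months = 3,
    reimbursement_rate = 0.5,
    reimbursement_concentration = 50,
    death_hazard_by_stage = c("0-I" = 0.03, "II" = 0.15, "III" = 0.45,
                              "IV" = 0.80),
    background_episode_rate = 0.01) {
  cfg <- list(
    seed = as.integer(seed), n_per_arm = as.integer(n_per_arm),
    enrollment_window_screening = as.Date(enrollment_window_screening),
    enrollment_window_control = as.Date(enrollment_window_control),
    censor_date = as.Date(censor_date),
    annual_incidence_by_site = annual_incidence_by_site,
    screening_case_multiplier = screening_case_multiplier,
    screen_detection_fraction = screen_detection_fraction,
    stage_distribution = stage_distribution,
    therapy_given_stage = therapy_given_stage,
    episode_lambda_by_stage = episode_lambda_by_stage,
    los_median_by_stage = los_median_by_stage,
    los_sdlog = los_sdlog,
    cost_model = cost_model,
    cost_decay_halflife_months = cost_decay_halflife_months,
    reimbursement_rate = reimbursement_rate,
    reimbursement_concentration = reimbursement_concentration,
    death_hazard_by_stage = death_hazard_by_stage,
    background_episode_rate = background_episode_rate
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  tolsum1 <- function(p, what) {
    chk(abs(sum(p) - 1) <= 1e-9, "generator config: %s must sum to 1", what)
    chk(all(p >= 0), "generator config: %s has negative entries", what)
  }
  chk(cfg$n_per_arm > 0, "generator config: n_per_arm must be positive")
  chk(cfg$enrollment_window_screening[1] <= cfg$enrollment_window_control[1],
      "generator config: screening enrollment must start first")
  chk(all(diff(cfg$enrollment_window_screening) >= 0) &&
        all(diff(cfg$enrollment_window_control) >= 0),
      "generator config: enrollment windows must be ordered date pairs")
  chk(all(cfg$annual_incidence_by_site >= 0) &&
        setequal(names(cfg$annual_incidence_by_site), cancer_sites()),
      "generator config: annual_incidence_by_site must cover all sites")
  chk(cfg$screen_detection_fraction >= 0 && cfg$screen_detection_fraction <= 1,
      "generator config: screen_detection_fraction must be in [0,1]")
  tolsum1(cfg$stage_distribution$screen_detected,
          "stage_distribution$screen_detected")
  tolsum1(cfg$stage_distribution$clinical, "stage_distribution$clinical")
  for (s in rownames(cfg$therapy_given_stage)) {
    tolsum1(cfg$therapy_given_stage[s, ],
            sprintf("therapy_given_stage['%s',]", s))
  }
  for (t in rownames(cfg$cost_model$class_shares)) {
    tolsum1(cfg$cost_model$class_shares[t, ],
            sprintf("cost_model$class_shares['%s',]", t))
  }
  chk(cfg$cost_decay_halflife_months > 0,
      "generator config: cost_decay_halflife_months must be positive")
  chk(cfg$reimbursement_rate > 0 && cfg$reimbursement_rate < 1,
      "generator config: reimbursement_rate must be in (0,1)")
  chk(all(cfg$death_hazard_by_stage >= 0),
      "generator config: death hazards must be non-negative")
  structure(cfg, class = "claims_generator_config")
}

runif_dates <- function(n, from, to) {
  from + floor(stats::runif(n) * (as.numeric(to - from) + 1))
}

sample_levels <- function(n, prob) {
  names(prob)[sample.int(length(prob), n, replace = TRUE, prob = prob)]
}

site_code <- function(site, stage) {
  pool <- switch(site,
    esophageal = c("C15.3", "C15.4", "C15.5", "C15.9"),
    cardial = "C16.0",
    non_cardial_gastric = c("C16.1", "C16.2", "C16.9"),
    duodenal = "D00.2"
  )
  # a share of earliest-stage disease enters claims as an in-situ or
  # precancerous-lesion code rather than an invasive-cancer code
  if (stage == "0-I" && stats::runif(1) < 0.2) {
    sample(c("D00.1", "K22.7"), 1)
  } else {
    sample(pool, 1)
  }
}

#' Generate a synthetic claims dataset
#'
#' Draws participants, cancer cases, hospitalization episodes and itemized
#' line items under `config`, validates every claims-model invariant, and
#' returns a `claims_data` list. Output is byte-identical for a fixed seed.
#' If the configured incidence yields zero cases at the requested sample
#' size a warning is emitted (not an error).
#'
#' @param config A [claims_generator_config()].
#' @return A validated `claims_data` list.
#' @export
generate_claims <- function(config) {
  stopifnot(inherits(config, "claims_generator_config"))
  cfg <- config
  set.seed(cfg$seed)

  n <- cfg$n_per_arm
  participants <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(2L * n)),
    arm = rep(c("screening", "control"), each = n),
    enrollment_date = c(
      runif_dates(n, cfg$enrollment_window_screening[1],
                  cfg$enrollment_window_screening[2]),
      runif_dates(n, cfg$enrollment_window_control[1],
                  cfg$enrollment_window_control[2])
    ),
    age_at_enrollment = sample(45:69, 2L * n, replace = TRUE),
    gender = sample(c("male", "female"), 2L * n, replace = TRUE,
                    prob = c(0.55, 0.45)),
    education = sample(c("primary-or-below", "middle-or-above"), 2L * n,
                       replace = TRUE, prob = c(0.7, 0.3)),
    occupation = sample(c("manual_worker", "technical_staff"), 2L * n,
                        replace = TRUE, prob = c(0.98, 0.02)),
    household_income_per_capita = round(
      ifelse(stats::runif(2L * n) < 0.1, 0,
             stats::rlnorm(2L * n, log(3000), 1.1)), 2)
  )
  participants$end_of_followup <- cfg$censor_date

  # -- which participants become cancer cases ------------------------------
  py <- as.numeric(cfg$censor_date - participants$enrollment_date) / 365.25
  mult <- ifelse(participants$arm == "screening",
                 cfg$screening_case_multiplier, 1)
  sites <- cancer_sites()
  p_site <- vapply(sites, function(s) {
    1 - exp(-cfg$annual_incidence_by_site[[s]] / 1e5 * py * mult)
  }, numeric(length(py)))
  u <- matrix(stats::runif(length(py) * length(sites)), ncol = length(sites))
  hit <- u < p_site
  first_site <- apply(hit, 1, function(r) if (any(r)) sites[which(r)[1]] else NA_character_)
  case_idx <- which(!is.na(first_site))

  if (length(case_idx) == 0) {
    warn("generate_claims: configured incidence produced zero cases")
    empty <- validate_claims_data(list(
      participants = participants,
      cases = tibble::tibble(participant_id = character(), site = character(),
                             detection_mode = character(),
                             diagnosis_date = as.Date(character()),
                             stage = character(), therapy = character()),
      episodes = empty_episodes(), line_items = empty_line_items()
    ))
    return(empty)
  }

  cases <- tibble::tibble(
    participant_id = participants$participant_id[case_idx],
    arm = participants$arm[case_idx],
    enrollment_date = participants$enrollment_date[case_idx],
    site = first_site[case_idx]
  )
  cases$detection_mode <- ifelse(
    cases$arm == "screening" &
      stats::runif(nrow(cases)) < cfg$screen_detection_fraction,
    "screen_detected", "clinically_diagnosed")
  sd_ix <- cases$detection_mode == "screen_detected"
  span <- pmax(as.numeric(cfg$censor_date - cases$enrollment_date) - 30, 31)
  diag_offset <- ifelse(sd_ix, 7 + floor(stats::runif(nrow(cases)) * 114),
                        30 + floor(stats::runif(nrow(cases)) * (span - 30)))
  cases$diagnosis_date <- cases$enrollment_date + diag_offset
  cases$stage <- NA_character_
  cases$stage[sd_ix] <- sample_levels(sum(sd_ix),
                                      cfg$stage_distribution$screen_detected)
  cases$stage[!sd_ix] <- sample_levels(sum(!sd_ix),
                                       cfg$stage_distribution$clinical)
  cases$therapy <- vapply(cases$stage, function(s) {
    sample_levels(1, cfg$therapy_given_stage[s, ])
  }, character(1), USE.NAMES = FALSE)

  # death truncates follow-up; everyone else is censored administratively
  hz <- pmax(cfg$death_hazard_by_stage[cases$stage], 1e-12)
  death_days <- pmin(stats::rexp(nrow(cases), rate = hz / 365.25), 5e5)
  end_fu <- pmin(cases$diagnosis_date + ceiling(death_days), cfg$censor_date)
  participants$end_of_followup[case_idx] <- end_fu
  cases$end_of_followup <- end_fu

  eps <- purrr::map(seq_len(nrow(cases)), function(i) {
    case_episodes(cases[i, ], cfg, i)
  })
  episodes <- dplyr::bind_rows(purrr::map(eps, "episodes"))
  line_items <- dplyr::bind_rows(purrr::map(eps, "line_items"))

  # unrelated hospitalizations among cancer-free participants
  free_ix <- setdiff(seq_len(2L * n), case_idx)
  bg_ix <- free_ix[stats::runif(length(free_ix)) < cfg$background_episode_rate]
  if (length(bg_ix) > 0) {
    bg <- background_episodes(participants[bg_ix, ], cfg)
    episodes <- dplyr::bind_rows(episodes, bg$episodes)
    line_items <- dplyr::bind_rows(line_items, bg$line_items)
  }

  cases$arm <- NULL
  cases$enrollment_date <- NULL
  cases$end_of_followup <- NULL
  validate_claims_data(list(participants = participants, cases = cases,
                            episodes = episodes, line_items = line_items))
}

empty_episodes <- function() {
  tibble::tibble(episode_id = character(), participant_id = character(),
                 facility_tier = character(),
                 admission_date = as.Date(character()),
                 discharge_date = as.Date(character()),
                 discharge_diagnosis_code = character(),
                 total_expense = numeric(), reimbursed_expense = numeric(),
                 out_of_pocket_expense = numeric())
}

empty_line_items <- function() {
  tibble::tibble(episode_id = character(),
                 service_date = as.Date(character()),
                 classification = character(), quantity = numeric(),
                 unit_cost = numeric(), out_of_pocket_portion = numeric())
}

# Episodes for one cancer case. The first hospitalization follows diagnosis
# within two weeks at a secondary or tertiary facility; later episodes fall
# in subsequent 30-day months with geometrically decaying costs.
case_episodes <- function(case, cfg, case_no) {
  n_extra <- stats::rpois(1, cfg$episode_lambda_by_stage[[case$stage]])
  months <- c(1, 1 + cumsum(1L + stats::rgeom(n_extra, 0.6)))
  first_adm <- min(case$diagnosis_date + sample(0:14, 1), case$end_of_followup)
  adm <- first_adm + 30 * (months - 1) +
    c(0, sample(0:15, max(n_extra, 1), replace = TRUE)[seq_len(n_extra)])
  keep <- adm <= case$end_of_followup
  keep[1] <- TRUE
  adm <- adm[keep]
  months <- months[keep]
  k <- length(adm)

  los <- pmax(1, round(stats::rlnorm(
    k, log(cfg$los_median_by_stage[[case$stage]]), cfg$los_sdlog)))
  dis <- pmin(adm + los, case$end_of_followup)
  dis <- pmax(dis, adm)

  tier <- c(sample(c("secondary", "tertiary"), 1, prob = c(0.55, 0.45)),
            sample(c("primary", "secondary", "tertiary"), max(k - 1, 0),
                   replace = TRUE, prob = c(0.10, 0.50, 0.40)))
  code <- vapply(seq_len(k), function(j) site_code(case$site, case$stage),
                 character(1))

  shares <- cfg$cost_model$class_shares[case$therapy, ]
  active <- names(shares)[shares > 0]
  decay <- 2^(-(months - 1) / cfg$cost_decay_halflife_months)
  rr <- stats::rbeta(k, cfg$reimbursement_rate * cfg$reimbursement_concentration,
                     (1 - cfg$reimbursement_rate) * cfg$reimbursement_concentration)

  li <- purrr::map(seq_len(k), function(j) {
    cost <- stats::rlnorm(
      length(active),
      meanlog = cfg$cost_model$meanlog_by_therapy[[case$therapy]] +
        log(shares[active]),
      sdlog = cfg$cost_model$sdlog) * decay[j]
    cost <- round(cost, 2)
    tibble::tibble(
      episode_j = j,
      service_date = adm[j],
      classification = active,
      quantity = 1,
      unit_cost = cost,
      out_of_pocket_portion = round((1 - rr[j]) * cost, 2)
    )
  })
  li <- dplyr::bind_rows(li)

  totals <- vapply(split(li$quantity * li$unit_cost, li$episode_j), sum,
                   numeric(1))
  oop <- vapply(split(li$out_of_pocket_portion, li$episode_j), sum,
                numeric(1))
  ids <- sprintf("E%05d-%02d", case_no, seq_len(k))
  episodes <- tibble::tibble(
    episode_id = ids,
    participant_id = case$participant_id,
    facility_tier = tier,
    admission_date = adm,
    discharge_date = dis,
    discharge_diagnosis_code = code,
    total_expense = unname(totals),
    reimbursed_expense = unname(totals - oop),
    out_of_pocket_expense = unname(oop)
  )
  li$episode_id <- ids[li$episode_j]
  li$episode_j <- NULL
  list(episodes = episodes,
       line_items = li[, c("episode_id", "service_date", "classification",
                           "quantity", "unit_cost", "out_of_pocket_portion")])
}

background_episodes <- function(participants, cfg) {
  k <- nrow(participants)
  adm <- participants$enrollment_date + floor(
    stats::runif(k) * pmax(as.numeric(participants$end_of_followup -
                                        participants$enrollment_date), 1))
  los <- pmax(1, round(stats::rlnorm(k, log(6), 0.6)))
  total <- round(stats::rlnorm(k, log(3000), 0.7), 2)
  rr <- stats::rbeta(k, cfg$reimbursement_rate * cfg$reimbursement_concentration,
                     (1 - cfg$reimbursement_rate) * cfg$reimbursement_concentration)
  oop <- round((1 - rr) * total, 2)
  ids <- sprintf("B%05d", seq_len(k))
  episodes <- tibble::tibble(
    episode_id = ids,
    participant_id = participants$participant_id,
    facility_tier = sample(c("primary", "secondary"), k, replace = TRUE,
                           prob = c(0.6, 0.4)),
    admission_date = adm,
    discharge_date = pmin(adm + los, participants$end_of_followup),
    discharge_diagnosis_code = sample(c("J18.9", "I10", "K35.8", "E11.9"),
                                      k, replace = TRUE),
    total_expense = total,
    reimbursed_expense = total - oop,
    out_of_pocket_expense = oop
  )
  line_items <- tibble::tibble(
    episode_id = ids,
    service_date = adm,
    classification = "medication_other",
    quantity = 1,
    unit_cost = total,
    out_of_pocket_portion = oop
  )
  list(episodes = episodes, line_items = line_items)
}

#' Summaries for eyeballing a generated dataset against its anchors
#'
#' Returns empirical stage and site distributions by arm, episode-count and
#' length-of-stay medians by arm, the realized reimbursement fraction, and
#' the nominal monthly cost curve (30-day bins since each case's first
#' hospitalization), for comparison with the generator's calibration
#' anchors.
#'
#' @param data A `claims_data` list.
#' @return A list of tibbles (`stage_by_arm`, `site_by_arm`,
#'   `utilization_by_arm`, `reimbursement_fraction`, `monthly_curve`); all
#'   empty when the dataset has no cases.
#' @export
calibration_report <- function(data) {
  cases <- dplyr::inner_join(
    data$cases, data$participants[, c("participant_id", "arm")],
    by = "participant_id")
  if (nrow(cases) == 0) {
    return(list(stage_by_arm = tibble::tibble(),
                site_by_arm = tibble::tibble(),
                utilization_by_arm = tibble::tibble(),
                reimbursement_fraction = NA_real_,
                monthly_curve = tibble::tibble()))
  }
  stage_by_arm <- cases %>%
    dplyr::count(.data$arm, .data$stage) %>%
    dplyr::group_by(.data$arm) %>%
    dplyr::mutate(prop = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
  site_by_arm <- cases %>%
    dplyr::count(.data$arm, .data$site) %>%
    dplyr::group_by(.data$arm) %>%
    dplyr::mutate(prop = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()

  eps <- dplyr::semi_join(data$episodes,
                          cases[, "participant_id", drop = FALSE],
                          by = "participant_id")
  util <- eps %>%
    dplyr::mutate(los = as.numeric(.data$discharge_date -
                                     .data$admission_date)) %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::summarise(n_episodes = dplyr::n(), total_los = sum(.data$los),
                     .groups = "drop") %>%
    dplyr::inner_join(cases[, c("participant_id", "arm")],
                      by = "participant_id") %>%
    dplyr::group_by(.data$arm) %>%
    dplyr::summarise(median_episodes = stats::median(.data$n_episodes),
                     median_total_los = stats::median(.data$total_los),
                     .groups = "drop")

  monthly <- eps %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::mutate(month = 1 + as.numeric(.data$admission_date -
                                           min(.data$admission_date)) %/% 30) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(.data$month) %>%
    dplyr::summarise(total_cost = sum(.data$total_expense),
                     n_episodes = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(average_cost = .data$total_cost /
                    dplyr::n_distinct(eps$participant_id))

  list(
    stage_by_arm = stage_by_arm,
    site_by_arm = site_by_arm,
    utilization_by_arm = util,
    reimbursement_fraction = sum(eps$reimbursed_expense) /
      sum(eps$total_expense),
    monthly_curve = monthly
  )
}
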