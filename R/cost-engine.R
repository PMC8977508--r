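# Cost valuation. Nominal CNY claims amounts are inflated to the base year
# with annual compound discounting, deflated/reflated by the medical-care
# CPI, and converted to USD at the purchasing-power-parity rate. Time cost
# follows the human-capital approach: each inpatient day is valued at the
# rural annual net income per capita divided by 365, doubled to cover one
# accompanying caregiver.

#' Default medical-care CPI series
#'
#' A stand-in consumer-price-index series for medical goods and services,
#' normalized to base year 2018 = 1 and built from an assumed 4.5% annual
#' medical inflation. The series the original claims were adjusted with is
#' not public; supply your own through [economic_params()] for real
#' analyses.
#'
#' @param years Years to cover.
#' @param base_year Index base year (value 1).
#' @param annual_inflation Assumed annual medical inflation rate.
#' @return Named numeric vector, year -> index.
#' @export
default_cpi_medical <- function(years = 2010:2018, base_year = 2018,
                                annual_inflation = 0.045) {
  idx <- (1 + annual_inflation)^(years - base_year)
  stats::setNames(idx, as.character(years))
}

#' Economic valuation parameters
#'
#' @param discount_rate Annual discount rate used to annualize past costs to
#'   the base year (default 3%).
#' @param base_year Reference year for real costs (2018).
#' @param cpi_medical Named numeric vector mapping service year to a
#'   medical-care CPI index with `cpi_medical[base_year] == 1`.
#' @param ppp_rate Purchasing-power-parity exchange rate, CNY per USD
#'   (2018: 3.55).
#' @param ani Annual net income per capita of rural residents (CNY/year),
#'   the wage proxy of the human-capital time valuation. The default is the
#'   2017 provincial statistic for rural Henan; treat it as user-supplied.
#' @param caregiver_multiplier Person-days valued per inpatient day (2 =
#'   patient plus one caregiver).
#' @param che_threshold Catastrophic-expenditure threshold as a fraction of
#'   capacity to pay (WHO standard 0.40).
#' @param capacity_to_pay Household capacity to pay, CNY (2017 rural
#'   per-capita disposable income of the study county: 10,906 CNY, i.e.
#'   3,072 USD at PPP).
#' @return A validated `economic_params` list.
#' @export
economic_params <- function(discount_rate = 0.03,
                            base_year = 2018L,
                            cpi_medical = default_cpi_medical(),
                            ppp_rate = 3.55,
                            ani = 12719,
                            caregiver_multiplier = 2,
                            che_threshold = 0.40,
                            capacity_to_pay = 10906) {
  chk(discount_rate >= 0, "economic_params: discount_rate must be >= 0")
  chk(ppp_rate > 0, "economic_params: ppp_rate must be positive")
  chk(as.character(base_year) %in% names(cpi_medical) &&
        abs(cpi_medical[[as.character(base_year)]] - 1) < 1e-12,
      "economic_params: cpi_medical must contain base_year with index 1")
  chk(che_threshold > 0 && che_threshold < 1,
      "economic_params: che_threshold must be in (0,1)")
  chk(ani >= 0 && caregiver_multiplier >= 0 && capacity_to_pay >= 0,
      "economic_params: ani, caregiver_multiplier, capacity_to_pay must be non-negative")
  structure(list(discount_rate = discount_rate,
                 base_year = as.integer(base_year),
                 cpi_medical = cpi_medical, ppp_rate = ppp_rate, ani = ani,
                 caregiver_multiplier = caregiver_multiplier,
                 che_threshold = che_threshold,
                 capacity_to_pay = capacity_to_pay),
            class = "economic_params")
}

#' Human-capital time cost of hospitalization
#'
#' `ols_days * (ani / 365) * caregiver_multiplier`, in nominal CNY of the
#' service year: each inpatient day costs the patient's daily income and
#' that of one accompanying caregiver.
#'
#' @param ols_days Overall length of stay in days (vectorized).
#' @param params An [economic_params()].
#' @return Nominal CNY, same length as `ols_days`.
#' @export
time_cost <- function(ols_days, params) {
  chk(all(ols_days >= 0), "time_cost: negative length of stay")
  ols_days * (params$ani / 365) * params$caregiver_multiplier
}

#' Annualize, CPI-adjust, and PPP-convert a nominal CNY amount
#'
#' `amount * (1 + discount_rate)^(base_year - service_year) *
#' cpi[base_year] / cpi[service_year] / ppp_rate`. For base-year amounts
#' this reduces to pure PPP division.
#'
#' @param amount_cny Nominal CNY amounts (vectorized).
#' @param service_year Year of service for each amount (recycled).
#' @param params An [economic_params()].
#' @return Base-year real USD.
#' @export
adjust_and_convert <- function(amount_cny, service_year, params) {
  yr <- as.character(service_year)
  missing <- setdiff(unique(yr), names(params$cpi_medical))
  chk(length(missing) == 0,
      "adjust_and_convert: no CPI index for year(s) %s",
      paste(missing, collapse = ", "))
  cpi <- unname(params$cpi_medical[yr])
  base_cpi <- params$cpi_medical[[as.character(params$base_year)]]
  amount_cny * (1 + params$discount_rate)^(params$base_year -
                                             as.numeric(service_year)) *
    (base_cpi / cpi) / params$ppp_rate
}

#' Per-case costs within the standard observation window
#'
#' For each treated case, sums over episodes admitted within
#' `window_months` fixed 30-day months of the first treatment admission:
#' hospitalization cost (adjusted total expense), out-of-pocket cost
#' (adjusted out-of-pocket expense), and time cost (the human-capital
#' formula on each episode's length of stay, valued in its service year and
#' then adjusted). Treatment cost is hospitalization plus time cost, an
#' exact identity. Cases with no in-window episode get zero costs with a
#' warning.
#'
#' @param cases Case tibble (the harmonized cohort's included cases).
#' @param episodes Validated episode tibble.
#' @param first_tx Output of [first_treatment_episode()].
#' @param params An [economic_params()].
#' @param window_months Observation window length in 30-day months.
#' @return Tibble with one row per case: `participant_id`,
#'   `hospitalization_cost_usd`, `time_cost_usd`, `treatment_cost_usd`,
#'   `out_of_pocket_usd`, `ols_days`, `n_episodes`.
#' @export
case_costs <- function(cases, episodes, first_tx, params,
                       window_months = 12) {
  ft <- first_tx[first_tx$participant_id %in% cases$participant_id, ,
                 drop = FALSE]
  e <- episode_window_costs(cases, episodes, ft, params, window_months)
  per_case <- e %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::summarise(
      hospitalization_cost_usd = sum(.data$hosp_usd),
      time_cost_usd = sum(.data$time_usd),
      out_of_pocket_usd = sum(.data$oop_usd),
      ols_days = sum(.data$ols_days),
      n_episodes = dplyr::n(),
      .groups = "drop")
  out <- tibble::tibble(participant_id = ft$participant_id) %>%
    dplyr::left_join(per_case, by = "participant_id")
  empty <- is.na(out$n_episodes)
  if (any(empty)) {
    warn(sprintf("case_costs: %d case(s) with no in-window episode; zero costs assigned",
                 sum(empty)))
    out[empty, c("hospitalization_cost_usd", "time_cost_usd",
                 "out_of_pocket_usd", "ols_days")] <- 0
    out$n_episodes[empty] <- 0L
  }
  out$treatment_cost_usd <- out$hospitalization_cost_usd + out$time_cost_usd
  out[, c("participant_id", "hospitalization_cost_usd", "time_cost_usd",
          "treatment_cost_usd", "out_of_pocket_usd", "ols_days",
          "n_episodes")]
}
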