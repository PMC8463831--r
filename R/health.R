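# Comparative risk assessment: weekly mMETh dose changes -> relative risks
# (power scaling, capped) -> deaths averted, discounted years of life lost,
# sickness-absence hours, and their monetary value.

#' Health dose-response and valuation parameters
#'
#' @param rr_pa Relative risk of all-cause mortality per `reference_dose`
#'   mMETh/week of cycling or walking (0.9).
#' @param reference_dose Reference weekly dose, mMETh; 8.75 is roughly 150
#'   minutes of moderate activity at 3.5 mMET.
#' @param cap_cycle,cap_walk Floors on the mortality relative risk for
#'   cycling (0.55: at most a 45% decrease) and walking (0.70).
#' @param rr_sick Relative sickness-absence risk per reference dose (0.75: a
#'   0.25 relative reduction).
#' @param cap_sick Floor on the sickness relative risk (0.50).
#' @param vsly Value of a statistical life year, GBP (2010 prices).
#' @param discount_rate Annual discount rate applied to future life years.
#' @return List of class `health_params`.
#' @export
health_params <- function(rr_pa = 0.9, reference_dose = 8.75,
                          cap_cycle = 0.55, cap_walk = 0.70,
                          rr_sick = 0.75, cap_sick = 0.50,
                          vsly = 57965, discount_rate = 0.015) {
  stopifnot(rr_pa > 0, rr_pa < 1, rr_sick > 0, rr_sick < 1,
            reference_dose > 0,
            cap_cycle > 0, cap_cycle < rr_pa,
            cap_walk > 0, cap_walk < 1,
            cap_sick > 0, cap_sick < 1,
            vsly > 0, discount_rate >= 0)
  structure(list(rr_pa = rr_pa, reference_dose = reference_dose,
                 cap_cycle = cap_cycle, cap_walk = cap_walk,
                 rr_sick = rr_sick, cap_sick = cap_sick,
                 vsly = vsly, discount_rate = discount_rate),
            class = "health_params")
}

#' Apply the dose-response power scaling to a weekly dose change
#'
#' `RR = max(cap, base_rr ^ (delta / reference))`: e.g. a gain of 1.2
#' mMETh/week at base 0.9 per 8.75 gives 0.9^(1.2/8.75) = 0.986.
#'
#' @param delta_mmeth Non-negative weekly dose change, mMETh.
#' @param base_rr Base relative risk per reference dose.
#' @param reference Reference dose, mMETh/week.
#' @param cap Floor on the relative risk.
#' @return Relative risk in \[cap, 1\].
#' @export
applied_rr <- function(delta_mmeth, base_rr = 0.9, reference = 8.75,
                       cap = 0.55) {
  if (any(delta_mmeth < 0)) {
    stop("dose change must be non-negative; pass gains and displaced ",
         "walking separately")
  }
  pmax(cap, base_rr^(delta_mmeth / reference))
}

#' Net deaths averted per year for one individual
#'
#' Deaths avoided through the cycling dose gained minus deaths incurred
#' through displaced walking: `m * (1 - RR_cycle(gain)) - m * (1 -
#' RR_walk(walk_lost))`, where `m` is the individual's annual background
#' mortality rate. The walking debit is the protection the displaced walking
#' was providing (symmetric convention); the net value may be negative.
#'
#' @param gain_mmeth Weekly cycling dose gained, mMETh (>= 0).
#' @param walk_lost_mmeth Weekly walking dose displaced, mMETh (>= 0).
#' @param mortality_rate Annual background mortality rate (deaths per
#'   person-year).
#' @param params [health_params()].
#' @return Net deaths averted per year (vectorised).
#' @export
deaths_averted <- function(gain_mmeth, walk_lost_mmeth, mortality_rate,
                           params = health_params()) {
  stopifnot(all(mortality_rate >= 0))
  rr_c <- applied_rr(gain_mmeth, params$rr_pa, params$reference_dose,
                     params$cap_cycle)
  rr_w <- applied_rr(walk_lost_mmeth, params$rr_pa, params$reference_dose,
                     params$cap_walk)
  mortality_rate * (1 - rr_c) - mortality_rate * (1 - rr_w)
}

#' Discounted years of life lost averted
#'
#' Each death averted saves a stream of `yll_per_death` future life years,
#' valued as an annuity discounted at `discount_rate`:
#' `(1 - (1 + r)^-L) / r` (equal to `L` when `r = 0`).
#'
#' @param deaths Deaths averted per year.
#' @param yll_per_death Undiscounted years of life lost per death.
#' @param discount_rate Annual discount rate.
#' @return Discounted YLLs averted per year.
#' @export
ylls_averted <- function(deaths, yll_per_death, discount_rate = 0.015) {
  stopifnot(all(yll_per_death >= 0))
  ann <- if (discount_rate == 0) yll_per_death else
    (1 - (1 + discount_rate)^(-yll_per_death)) / discount_rate
  deaths * ann
}

#' Monetise YLLs at the value of a statistical life year
#'
#' @param ylls Discounted YLLs averted per year.
#' @param params [health_params()].
#' @return GBP per year.
#' @export
monetise_ylls <- function(ylls, params = health_params()) {
  ylls * params$vsly
}

#' Net change in sickness-absence hours and its value
#'
#' The same power-scaled dose-response as for mortality, with base 0.75 per
#' reference dose capped at 0.50: reduction = hours x (1 - RR(gain)) minus
#' the increase from displaced walking, valued at the regional hourly salary.
#'
#' @param gain_mmeth,walk_lost_mmeth Weekly doses, mMETh (>= 0).
#' @param annual_hours Background annual sickness-absence hours.
#' @param hourly_salary Regional hourly salary, GBP.
#' @param params [health_params()].
#' @return Tibble with `hours_reduced` and `value_gbp` per year.
#' @export
sickness_change <- function(gain_mmeth, walk_lost_mmeth, annual_hours,
                            hourly_salary, params = health_params()) {
  stopifnot(all(annual_hours >= 0), all(hourly_salary >= 0))
  rr_c <- applied_rr(gain_mmeth, params$rr_sick, params$reference_dose,
                     params$cap_sick)
  rr_w <- applied_rr(walk_lost_mmeth, params$rr_sick, params$reference_dose,
                     params$cap_sick)
  hours <- annual_hours * (1 - rr_c) - annual_hours * (1 - rr_w)
  tibble::tibble(hours_reduced = hours, value_gbp = hours * hourly_salary)
}

#' Synthetic background rates by age band, sex and region
#'
#' Mortality per 1000 commuters rises steeply with age (0.24 per 1000 at
#' 16-24 to the high twenties at 75+), is higher for men, and varies mildly
#' by region; years of life lost per death decline with age; annual
#' sickness-absence hours span 8.2 (men 16-24, East Midlands) to 69.9 (men
#' 50-64, Wales); hourly salary spans 17.16 (North East) to 24.15 (London).
#' These are synthetic tables constructed to span published anchor ranges,
#' not extracts of any vital-statistics dataset.
#'
#' @return Tibble keyed by `age_band`, `sex`, `region` with
#'   `mortality_per_1000`, `yll_per_death`, `sick_hours`, `hourly_salary`.
#' @export
default_background_rates <- function() {
  grid <- expand.grid(age_band = age_band_levels(),
                      sex = c("male", "female"),
                      region = region_levels(),
                      stringsAsFactors = FALSE)
  mort_age <- c("16-24" = 0.24, "25-34" = 0.51, "35-49" = 1.44,
                "50-64" = 4.68, "65-74" = 10.50, "75+" = 28.00)
  yll_age <- c("16-24" = 43.1, "25-34" = 39.5, "35-49" = 33.2,
               "50-64" = 25.4, "65-74" = 18.5, "75+" = 12.5)
  sick_age <- c("16-24" = 12.0, "25-34" = 20.0, "35-49" = 28.0,
                "50-64" = 45.0, "65-74" = 25.0, "75+" = 15.0)
  mort_region <- setNames(
    c(1.15, 1.10, 1.08, 1.02, 1.05, 0.95, 0.92, 0.90, 0.88, 0.93, 1.12),
    region_levels())
  sick_region <- setNames(
    c(1.30, 1.20, 1.15, 8.2 / 12.0, 1.05, 0.95, 0.90, 0.92, 0.85, 0.98,
      69.9 / 45.0),
    region_levels())
  salary_region <- setNames(
    c(17.16, 18.50, 18.20, 18.00, 18.60, 20.50, 24.15, 22.80, 21.90, 19.40,
      17.80),
    region_levels())
  sexf <- function(x, male, female) ifelse(x == "male", male, female)
  tibble::as_tibble(grid) %>%
    dplyr::mutate(
      mortality_per_1000 = unname(mort_age[age_band] *
        sexf(sex, 1.24, 0.76) * mort_region[region]),
      yll_per_death = unname(yll_age[age_band] + sexf(sex, -0.3, 0.3)),
      sick_hours = unname(sick_age[age_band] * sexf(sex, 1.0, 1.12) *
        sick_region[region]),
      hourly_salary = unname(salary_region[region])
    )
}

#' Per-commuter impact ledger for a scenario
#'
#' For every potential switcher, computes the full-switch weekly dose (via
#' [weekly_dose()], with the individual's own baseline mode as former mode),
#' converts it to annual deaths averted, discounted YLLs, sickness-absence
#' hours and their monetary values, plus CO2 savings for ex-car-drivers, and
#' scales every entry by the switch probability (impacts are expectations
#' over the Bernoulli switch, so the non-linear dose-response is applied to
#' the full-switch dose before weighting). Baseline cyclists and zero-dose
#' individuals contribute exactly zero.
#'
#' @param population A `cyclehia_population`.
#' @param scenario_result A `scenario_result`.
#' @param rates Background rates table ([default_background_rates()]).
#' @param trips Trips-per-week table ([default_trips_per_week()]).
#' @param act [activity_params()].
#' @param hp [health_params()].
#' @param cp [carbon_params()].
#' @param cycle_mode `"bike"`, or `"ebike"` for the E-bikes scenario.
#' @param gradient_override Optional single gradient (percent) used for every
#'   route in the dose computation (e.g. the population mean, to quantify the
#'   effect of modelling hilliness); route distances are unchanged.
#' @return Tibble of class `impact_ledger`, one row per commuter.
#' @export
impact_ledger <- function(population, scenario_result,
                          rates = default_background_rates(),
                          trips = default_trips_per_week(),
                          act = activity_params(),
                          hp = health_params(),
                          cp = carbon_params(),
                          cycle_mode = c("bike", "ebike"),
                          gradient_override = NULL) {
  cycle_mode <- match.arg(cycle_mode)
  cm <- population$commuters
  r <- scenario_result$result
  stopifnot(identical(r$id, cm$id))

  key <- paste(cm$age_band, cm$sex, cm$region)
  rkey <- paste(rates$age_band, rates$sex, rates$region)
  ridx <- match(key, rkey)
  if (anyNA(ridx)) {
    bad <- which(is.na(ridx))[1]
    stop("missing background-rates cell for age_band=", cm$age_band[bad],
         " sex=", cm$sex[bad], " region=", cm$region[bad])
  }
  tkey <- paste(cm$sex, cm$age_band)
  tidx <- match(tkey, paste(trips$sex, trips$age_band))
  if (anyNA(tidx)) {
    bad <- which(is.na(tidx))[1]
    stop("missing trips-per-week cell for sex=", cm$sex[bad],
         " age_band=", cm$age_band[bad])
  }
  tr <- trips$trips_per_week[tidx]

  g <- if (is.null(gradient_override)) cm$gradient_pct else
    rep(gradient_override, nrow(cm))
  dose <- weekly_dose(cm$distance_km, g, tr, cm$mode, act,
                      cycle_mode = cycle_mode)
  gain <- dose$mmeth_gain
  walk_lost <- -dose$mmeth_displaced

  p <- r$p_switch
  m_rate <- rates$mortality_per_1000[ridx] / 1000
  deaths <- p * deaths_averted(gain, walk_lost, m_rate, hp)
  ylls <- p * ylls_averted(deaths_averted(gain, walk_lost, m_rate, hp),
                           rates$yll_per_death[ridx], hp$discount_rate)
  sick <- sickness_change(gain, walk_lost, rates$sick_hours[ridx],
                          rates$hourly_salary[ridx], hp)
  co2 <- p * co2_saved(as.numeric(cm$mode == "car_driver"),
                       cm$distance_km, tr, cp)

  out <- tibble::tibble(
    id = cm$id, od_id = cm$od_id, region = cm$region, sex = cm$sex,
    age_band = cm$age_band, ethnicity = cm$ethnicity, has_car = cm$has_car,
    imd_quintile = cm$imd_quintile, urban_rural = cm$urban_rural,
    gradient_pct = cm$gradient_pct,
    p_switch = p, former_mode = ifelse(r$baseline_cyclist, NA, cm$mode),
    mmeth_gain = p * gain, mmeth_net = p * dose$mmeth_net,
    deaths_averted = deaths,
    ylls_averted = ylls,
    value_mortality_gbp = monetise_ylls(ylls, hp),
    sick_hours_reduced = p * sick$hours_reduced,
    value_sickness_gbp = p * sick$value_gbp,
    co2_kg_saved = co2,
    value_co2_gbp = monetise_carbon(co2, cp)
  )
  class(out) <- c("impact_ledger", class(out))
  out
}

ledger_fields <- function() {
  c("deaths_averted", "ylls_averted", "value_mortality_gbp",
    "sick_hours_reduced", "value_sickness_gbp", "co2_kg_saved",
    "value_co2_gbp")
}
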