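# Mode-shift carbon accounting: only former car drivers generate savings
# (public transport keeps running; car passengers yield health but no carbon
# benefit).

#' Carbon accounting parameters
#'
#' @param emission_kg_km CO2-equivalent emissions per car kilometre (0.182
#'   kg, the 2017 average-car value).
#' @param weeks_per_year Commuting weeks per year (52.2).
#' @param price_per_tonne Carbon price, GBP per tonne CO2e (user-supplied
#'   appraisal value; a config scalar, not an empirical constant).
#' @return List of class `carbon_params`.
#' @export
carbon_params <- function(emission_kg_km = 0.182, weeks_per_year = 52.2,
                          price_per_tonne = 70) {
  if (is.null(price_per_tonne) || is.na(price_per_tonne)) {
    stop("missing carbon price")
  }
  stopifnot(emission_kg_km > 0, weeks_per_year > 0, price_per_tonne > 0)
  structure(list(emission_kg_km = emission_kg_km,
                 weeks_per_year = weeks_per_year,
                 price_per_tonne = price_per_tonne),
            class = "carbon_params")
}

#' Annual CO2-equivalent savings from ex-car-driver switchers
#'
#' `n_ex_drivers x distance_km x trips_per_week x weeks_per_year x
#' emission_kg_km`. The former car distance is taken equal to the new
#' fastest-route cycling distance. Linear in every factor; ex-walkers,
#' ex-passengers and ex-bus users contribute zero (pass `n_ex_drivers = 0`).
#'
#' @param n_ex_drivers (Expected) number of former car drivers switching.
#' @param distance_km One-way route distance, km.
#' @param trips_per_week Cycle-commute trips per week.
#' @param params [carbon_params()].
#' @return kg CO2e per year (vectorised).
#' @export
co2_saved <- function(n_ex_drivers, distance_km, trips_per_week,
                      params = carbon_params()) {
  if (any(n_ex_drivers < 0) || any(distance_km < 0) ||
      any(trips_per_week < 0)) {
    stop("carbon inputs must be non-negative")
  }
  n_ex_drivers * distance_km * trips_per_week * params$weeks_per_year *
    params$emission_kg_km
}

#' Monetise CO2 savings
#'
#' @param kg kg CO2e per year.
#' @param params [carbon_params()].
#' @return GBP per year.
#' @export
monetise_carbon <- function(kg, params = carbon_params()) {
  kg / 1000 * params$price_per_tonne
}
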