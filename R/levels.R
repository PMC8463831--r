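# Closed category sets used throughout the model.

#' Category levels
#'
#' Closed sets of levels for regions (the 10 standard regions of England and
#' Wales with London split into Inner and Outer), age bands, urban/rural
#' classification and main commute modes.
#'
#' @return Character vector of levels.
#' @export
region_levels <- function() {
  c("North East", "North West", "Yorkshire and the Humber",
    "East Midlands", "West Midlands", "East of England",
    "Inner London", "Outer London", "South East", "South West", "Wales")
}

#' @rdname region_levels
#' @export
age_band_levels <- function() {
  c("16-24", "25-34", "35-49", "50-64", "65-74", "75+")
}

#' @rdname region_levels
#' @export
urban_rural_levels <- function() {
  c("Urban major conurbation", "Urban minor conurbation",
    "Urban city and town", "Rural town and fringe",
    "Rural village and dispersed")
}

#' @rdname region_levels
#' @export
mode_levels <- function() {
  c("walk", "cycle", "car_driver", "car_passenger", "bus", "rail", "other")
}

#' @rdname region_levels
#' @export
broad_age_levels <- function() c("16-49", "50+")

#' Collapse age bands to the two stratification bands
#'
#' @param age_band Age band values from [age_band_levels()].
#' @return `"16-49"` or `"50+"`.
#' @export
broad_age <- function(age_band) {
  ifelse(age_band %in% c("16-24", "25-34", "35-49"), "16-49", "50+")
}

is_rural <- function(urban_rural) {
  urban_rural %in% c("Rural town and fringe", "Rural village and dispersed")
}
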