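# Small hand-built populations for deterministic scenario arithmetic, and a
# shared medium synthetic population for statistical checks.

# Build a cyclehia_population from explicit OD pairs and commuters, filling
# unspecified commuter attributes with fixed defaults.
manual_population <- function(od, commuters) {
  defaults <- list(sex = "male", age_band = "25-34", ethnicity = "white",
                   has_car = TRUE, imd_quintile = 3L,
                   urban_rural = "Urban city and town", sparse = FALSE,
                   region = "North West", mode = "car_driver")
  for (nm in names(defaults)) {
    if (!nm %in% names(commuters)) commuters[[nm]] <- defaults[[nm]]
  }
  if (!"dest_type" %in% names(od)) od$dest_type <- "fixed"
  if (!"far" %in% names(od)) od$far <- od$distance_km >= 30
  if (!"origin" %in% names(od)) od$origin <- "Z001"
  if (!"destination" %in% names(od)) od$destination <- "Z002"
  if (!"id" %in% names(commuters)) {
    commuters$id <- sprintf("C%04d", seq_len(nrow(commuters)))
  }
  if (!"zone_id" %in% names(commuters)) commuters$zone_id <- "Z001"
  j <- match(commuters$od_id, od$od_id)
  commuters$dest_type <- od$dest_type[j]
  commuters$distance_km <- od$distance_km[j]
  commuters$gradient_pct <- od$gradient_pct[j]
  commuters$far <- od$far[j]
  zones <- tibble::tibble(
    zone_id = unique(c(od$origin, commuters$zone_id)),
    region = "North West", imd_quintile = 3L,
    urban_rural = "Urban city and town", sparse = FALSE,
    mortality_table_key = "North West")
  structure(list(zones = zones, od_pairs = tibble::as_tibble(od),
                 commuters = tibble::as_tibble(commuters), config = NULL),
            class = "cyclehia_population")
}

# A distance-only logit model object with chosen coefficients (all basis
# terms default to zero).
stub_baseline_model <- function(intercept = 0, d = 0, sqrt_d = 0, d2 = 0,
                                grad = 0, d_grad = 0, sqrt_d_grad = 0) {
  cf <- c(`(Intercept)` = intercept, d = d, sqrt_d = sqrt_d, d2 = d2,
          grad = grad, d_grad = d_grad, sqrt_d_grad = sqrt_d_grad)
  structure(list(coefficients = cf, se = cf * NA, converged = TRUE,
                 dropped = character(0), design = "distance"),
            class = c("baseline_model", "cyclehia_model"))
}

# Distance value at which a stub model with coefficients (0, -1, 0, ...)
# predicts probability p: plogis(-d) = p  =>  d = -qlogis(p).
dist_for_prob <- function(p) -stats::qlogis(p)

shared_pop <- NULL
get_shared_pop <- function() {
  if (is.null(shared_pop)) {
    shared_pop <<- generate_population(
      population_config(n_commuters = 6000, seed = 101))
  }
  shared_pop
}
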