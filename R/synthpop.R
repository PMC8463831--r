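# Seeded synthetic commuter population: zones, OD pairs and individuals,
# emulating a census-based commuting population. Distances come from
# log-normal distributions differing by urban/rural class, gradients from a
# truncated normal; demographics follow configurable marginals; car ownership
# and ethnicity are imputed sequentially within OD-pair x mode cells so that
# per-cell marginal counts are exactly preserved.

#' Synthetic population configuration
#'
#' Defaults emulate the commuting population of England and Wales: mean route
#' distance about 8.3 km (urban) and 11.6 km (rural) among sub-30 km trips,
#' mean gradient about 1.9%, a 3% cycling mode share skewed male, 8.75% of
#' commuters with no fixed workplace and about 12% commuting 30 km or more or
#' overseas (who are excluded from scenario uptake).
#'
#' @param n_zones Number of home zones.
#' @param n_commuters Number of individuals.
#' @param seed Integer seed; the generator consumes one RNG stream in a fixed
#'   order (zones, OD pairs, individuals, car ownership, ethnicity).
#' @param dests_per_zone Fixed-workplace destination zones sampled per origin.
#' @param p_urban_zone Probability vector over [urban_rural_levels()] for
#'   zone classes.
#' @param distance Log-normal `meanlog`/`sdlog` per urban/rural origin class.
#' @param gradient Truncated-normal mean/sd per class, truncation bounds.
#' @param p_female,p_age,p_nonwhite_by_mode,p_car_by_mode Demographic
#'   marginals. `p_age` is over [age_band_levels()]; the car-ownership and
#'   ethnicity probabilities vary by commute mode (these drive the per-cell
#'   imputation counts).
#' @param p_no_fixed,p_far_overseas Shares of commuters with no fixed
#'   workplace and working 30 km+ away or overseas.
#' @param mode_shares_noncycle Mode split among non-cyclists.
#' @param cycle_coef Coefficients of the data-generating cycling logit (see
#'   [cycle_logit()]).
#' @param p_sparse Probability a rural zone is flagged sparse.
#' @param far_cycle_prob Baseline cycling probability for 30 km+/overseas
#'   commuters.
#' @return A list of class `population_config`.
#' @export
population_config <- function(
    n_zones = 60,
    n_commuters = 10000,
    seed = 1L,
    dests_per_zone = 5,
    p_urban_zone = c(0.30, 0.10, 0.40, 0.12, 0.08),
    distance = list(urban = c(meanlog = 1.90, sdlog = 0.65),
                    rural = c(meanlog = 2.25, sdlog = 0.65)),
    gradient = list(urban = c(mean = 1.8, sd = 1.0),
                    rural = c(mean = 2.1, sd = 1.0),
                    lo = 0, hi = 5),
    p_female = 0.478,
    p_age = c(0.135, 0.232, 0.362, 0.243, 0.022, 0.006),
    p_nonwhite_by_mode = c(walk = 0.12, cycle = 0.07, car_driver = 0.11,
                           car_passenger = 0.13, bus = 0.18, rail = 0.15,
                           other = 0.12),
    p_car_by_mode = c(walk = 0.55, cycle = 0.55, car_driver = 0.98,
                      car_passenger = 0.90, bus = 0.55, rail = 0.75,
                      other = 0.80),
    p_no_fixed = 0.0875,
    p_far_overseas = 0.10,
    mode_shares_noncycle = c(walk = 0.112, car_driver = 0.627,
                             car_passenger = 0.052, bus = 0.075,
                             rail = 0.083, other = 0.051),
    cycle_coef = default_cycle_coef(),
    p_sparse = 0.25,
    far_cycle_prob = 0.002) {
  cfg <- list(
    n_zones = n_zones, n_commuters = n_commuters, seed = as.integer(seed),
    dests_per_zone = dests_per_zone, p_urban_zone = p_urban_zone,
    distance = distance, gradient = gradient,
    p_female = p_female, p_age = p_age,
    p_nonwhite_by_mode = p_nonwhite_by_mode, p_car_by_mode = p_car_by_mode,
    p_no_fixed = p_no_fixed, p_far_overseas = p_far_overseas,
    mode_shares_noncycle = mode_shares_noncycle,
    cycle_coef = cycle_coef, p_sparse = p_sparse,
    far_cycle_prob = far_cycle_prob
  )
  validate_population_config(cfg)
  structure(cfg, class = "population_config")
}

validate_population_config <- function(cfg) {
  stopifnot(cfg$n_commuters >= 1, cfg$n_zones >= 2)
  check_sum1 <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("marginal probabilities for ", what,
           " must be non-negative and sum to 1 (got sum = ", sum(p), ")")
    }
  }
  check_sum1(cfg$p_urban_zone, "urban/rural zone classes")
  check_sum1(cfg$p_age, "age bands")
  check_sum1(cfg$mode_shares_noncycle, "non-cycling modes")
  check_sum1(c(cfg$p_female, 1 - cfg$p_female), "sex")
  stopifnot(all(cfg$p_nonwhite_by_mode >= 0 & cfg$p_nonwhite_by_mode <= 1),
            all(cfg$p_car_by_mode >= 0 & cfg$p_car_by_mode <= 1),
            cfg$p_no_fixed >= 0, cfg$p_far_overseas >= 0,
            cfg$p_no_fixed + cfg$p_far_overseas < 1)
  invisible(cfg)
}

#' Data-generating coefficients for the cycling logit
#'
#' Distance/hilliness terms follow the published national commuter-cycling
#' logit family (distance in km, gradient in percent); demographic offsets
#' produce the observed skews (male, younger commuters cycle more; sparse
#' rural areas less). Car ownership and ethnicity are not part of the
#' generating logit (they are imputed afterwards from mode-conditional
#' marginals, which is what induces their association with cycling); a fully
#' individual-level simulation can add `has_car_direct`, `nonwhite_direct`
#' and `car_london` (a London offset weakening the car effect) terms, which
#' [cycle_logit()] applies when the corresponding columns exist.
#'
#' @return Named list of coefficients.
#' @export
default_cycle_coef <- function() {
  list(
    intercept = -3.36,
    d = -0.5963, sqrt_d = 1.866, d2 = 0.008050,
    grad = -0.2710, d_grad = 0.009394, sqrt_d_grad = -0.05135,
    female = -0.90,
    age = c("16-24" = 0, "25-34" = 0.10, "35-49" = 0.05, "50-64" = -0.25,
            "65-74" = -0.60, "75+" = -1.00),
    imd = -0.05,
    urban_rural = c("Urban major conurbation" = 0.20,
                    "Urban minor conurbation" = 0,
                    "Urban city and town" = 0,
                    "Rural town and fringe" = -0.20,
                    "Rural village and dispersed" = -0.30),
    sparse = -0.30
  )
}

#' Linear predictor of the data-generating cycling logit
#'
#' Evaluates the logit of the cycling probability for each row of a commuter
#' table with columns `distance_km`, `gradient_pct`, `sex`, `age_band`,
#' `region`, `imd_quintile`, `urban_rural`, `sparse` and (optionally, if the
#' corresponding coefficients are non-zero and the columns exist)
#' `ethnicity`, `has_car`.
#'
#' @param df Commuter table.
#' @param coef Coefficient list as in [default_cycle_coef()].
#' @return Numeric vector of logits.
#' @export
cycle_logit <- function(df, coef = default_cycle_coef()) {
  d <- df$distance_km
  g <- df$gradient_pct
  eta <- coef$intercept + coef$d * d + coef$sqrt_d * sqrt(d) + coef$d2 * d^2 +
    coef$grad * g + coef$d_grad * d * g + coef$sqrt_d_grad * sqrt(d) * g +
    coef$female * (df$sex == "female") +
    coef$age[df$age_band] +
    coef$imd * (df$imd_quintile - 3) +
    coef$urban_rural[df$urban_rural] +
    coef$sparse * df$sparse
  if ("ethnicity" %in% names(df) && !is.null(coef$nonwhite_direct)) {
    eta <- eta + coef$nonwhite_direct * (df$ethnicity == "non-white")
  }
  if ("has_car" %in% names(df) && !is.null(coef$has_car_direct)) {
    car_eff <- coef$has_car_direct +
      ifelse(df$region %in% c("Inner London", "Outer London"),
             coef$car_london %||% 0, 0)
    eta <- eta + car_eff * df$has_car
  }
  unname(eta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' @importFrom stats pnorm
generate_zones <- function(cfg) {
  regions <- sample(region_levels(), cfg$n_zones, replace = TRUE)
  ur <- sample(urban_rural_levels(), cfg$n_zones, replace = TRUE,
               prob = cfg$p_urban_zone)
  # London zones are urban by definition
  ur[regions %in% c("Inner London", "Outer London")] <-
    "Urban major conurbation"
  tibble::tibble(
    zone_id = sprintf("Z%03d", seq_len(cfg$n_zones)),
    region = regions,
    imd_quintile = sample(1:5, cfg$n_zones, replace = TRUE),
    urban_rural = ur,
    sparse = is_rural(ur) & runif(cfg$n_zones) < cfg$p_sparse,
    mortality_table_key = regions
  )
}

generate_od_pairs <- function(cfg, zones) {
  rural <- is_rural(zones$urban_rural)
  origin <- rep(zones$zone_id, each = cfg$dests_per_zone)
  dest <- unlist(lapply(seq_len(nrow(zones)), function(i) {
    sample(zones$zone_id[-i], cfg$dests_per_zone)
  }))
  cls <- rep(ifelse(rural, "rural", "urban"), each = cfg$dests_per_zone)
  dpar <- cfg$distance
  gpar <- cfg$gradient
  n <- length(origin)
  dist <- rlnorm(n,
                 ifelse(cls == "rural", dpar$rural["meanlog"], dpar$urban["meanlog"]),
                 ifelse(cls == "rural", dpar$rural["sdlog"], dpar$urban["sdlog"]))
  grad <- rtruncnorm1(n,
                      ifelse(cls == "rural", gpar$rural["mean"], gpar$urban["mean"]),
                      ifelse(cls == "rural", gpar$rural["sd"], gpar$urban["sd"]),
                      gpar$lo, gpar$hi)
  fixed <- tibble::tibble(
    od_id = sprintf("OD%05d", seq_len(n)),
    origin = origin, destination = dest, dest_type = "fixed",
    distance_km = dist, gradient_pct = grad,
    far = dist >= 30
  )
  # One pseudo-pair per zone for no-fixed-workplace commuters, carrying the
  # zone's mean sub-30 km route attributes, and one for 30 km+/overseas.
  zone_mean <- fixed %>%
    dplyr::filter(!far) %>%
    dplyr::group_by(origin) %>%
    dplyr::summarise(d = mean(distance_km), g = mean(gradient_pct),
                     .groups = "drop")
  zm_d <- setNames(zone_mean$d, zone_mean$origin)
  zm_g <- setNames(zone_mean$g, zone_mean$origin)
  fallback_d <- mean(fixed$distance_km[!fixed$far])
  fallback_g <- mean(fixed$gradient_pct[!fixed$far])
  nf <- tibble::tibble(
    od_id = paste0("NF_", zones$zone_id),
    origin = zones$zone_id, destination = NA_character_,
    dest_type = "no_fixed",
    distance_km = unname(ifelse(is.na(zm_d[zones$zone_id]), fallback_d,
                                zm_d[zones$zone_id])),
    gradient_pct = unname(ifelse(is.na(zm_g[zones$zone_id]), fallback_g,
                                 zm_g[zones$zone_id])),
    far = FALSE
  )
  fo <- tibble::tibble(
    od_id = paste0("FAR_", zones$zone_id),
    origin = zones$zone_id, destination = NA_character_,
    dest_type = "far_overseas",
    distance_km = 45,
    gradient_pct = unname(ifelse(is.na(zm_g[zones$zone_id]), fallback_g,
                                 zm_g[zones$zone_id])),
    far = TRUE
  )
  dplyr::bind_rows(fixed, nf, fo)
}

#' Generate a synthetic commuter population
#'
#' Draws zones, OD pairs and individual commuters under `config`, assigns
#' sex, age and main commute mode, then imputes car ownership and ethnicity
#' sequentially within OD-pair x mode cells (see
#' [impute_car_then_ethnicity()]). Bit-reproducible for a fixed seed.
#'
#' @param config A [population_config()].
#' @return A list of class `cyclehia_population` with tibbles `zones`,
#'   `od_pairs`, `commuters` and the `config`.
#' @export
generate_population <- function(config = population_config()) {
  validate_population_config(config)
  set.seed(config$seed)
  zones <- generate_zones(config)
  od <- generate_od_pairs(config, zones)

  n <- config$n_commuters
  zone_w <- rgamma(nrow(zones), shape = 2)
  home <- sample(zones$zone_id, n, replace = TRUE, prob = zone_w)

  # destination category, then a fixed OD pair within the home zone with
  # short-distance-favouring weights
  u <- runif(n)
  cat_nf <- u < config$p_no_fixed
  cat_far <- !cat_nf & u < config$p_no_fixed + config$p_far_overseas
  od_assigned <- character(n)
  od_assigned[cat_nf] <- paste0("NF_", home[cat_nf])
  od_assigned[cat_far] <- paste0("FAR_", home[cat_far])
  fixed_idx <- which(!cat_nf & !cat_far)
  fixed_od <- od[od$dest_type == "fixed", ]
  by_zone <- split(seq_len(nrow(fixed_od)), fixed_od$origin)
  for (z in unique(home[fixed_idx])) {
    rows <- fixed_idx[home[fixed_idx] == z]
    cand <- by_zone[[z]]
    w <- exp(-fixed_od$distance_km[cand] / 12)
    od_assigned[rows] <- sample(fixed_od$od_id[cand], length(rows),
                                replace = TRUE, prob = w)
  }

  commuters <- tibble::tibble(
    id = sprintf("C%07d", seq_len(n)),
    od_id = od_assigned,
    zone_id = home,
    sex = ifelse(runif(n) < config$p_female, "female", "male"),
    age_band = sample(age_band_levels(), n, replace = TRUE,
                      prob = config$p_age)
  ) %>%
    dplyr::left_join(zones[, c("zone_id", "region", "imd_quintile",
                               "urban_rural", "sparse")], by = "zone_id") %>%
    dplyr::left_join(od[, c("od_id", "dest_type", "distance_km",
                            "gradient_pct", "far")], by = "od_id")

  # cycling from the data-generating logit; 30 km+/overseas commutes rarely
  # cycled and never part of scenario uptake
  eta <- cycle_logit(commuters, config$cycle_coef)
  p_cycle <- ifelse(commuters$far, config$far_cycle_prob, plogis(eta))
  is_cyclist <- runif(n) < p_cycle
  other_modes <- names(config$mode_shares_noncycle)
  mode <- character(n)
  mode[is_cyclist] <- "cycle"
  n_other <- sum(!is_cyclist)
  mode[!is_cyclist] <- sample(other_modes, n_other, replace = TRUE,
                              prob = config$mode_shares_noncycle)
  commuters$mode <- mode

  # per-cell marginal counts for the sequential imputation
  cells <- commuters %>%
    dplyr::count(od_id, mode, name = "n_cell")
  car_marginals <- cells %>%
    dplyr::mutate(k_true = rbinom(dplyr::n(), n_cell,
                                  config$p_car_by_mode[mode]))
  eth_marginals <- cells %>%
    dplyr::mutate(k_true = rbinom(dplyr::n(), n_cell,
                                  config$p_nonwhite_by_mode[mode]))
  commuters <- impute_car_then_ethnicity(commuters, car_marginals,
                                         eth_marginals)

  structure(list(zones = zones, od_pairs = od, commuters = commuters,
                 config = config),
            class = "cyclehia_population")
}

#' @export
print.cyclehia_population <- function(x, ...) {
  cm <- x$commuters
  cat("<cyclehia_population> ", nrow(cm), " commuters, ",
      nrow(x$zones), " zones, ", nrow(x$od_pairs), " OD pairs\n", sep = "")
  cat(sprintf("  cycling %.2f%% | no fixed workplace %.1f%% | 30km+/overseas %.1f%%\n",
              100 * mean(cm$mode == "cycle"),
              100 * mean(cm$dest_type == "no_fixed"),
              100 * mean(cm$far)))
  invisible(x)
}

#' Write / read a population as delimited tables
#'
#' `zones.csv`, `od_pairs.csv` and `commuters.csv` under `dir` (UTF-8,
#' header row).
#'
#' @param population A `cyclehia_population`.
#' @param dir Directory.
#' @return `dir` (write) or a `cyclehia_population` without config (read).
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(population$zones, file.path(dir, "zones.csv"), row.names = FALSE)
  write.csv(population$od_pairs, file.path(dir, "od_pairs.csv"),
            row.names = FALSE)
  write.csv(population$commuters, file.path(dir, "commuters.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_population
#' @export
read_population <- function(dir) {
  structure(list(
    zones = tibble::as_tibble(read.csv(file.path(dir, "zones.csv"))),
    od_pairs = tibble::as_tibble(read.csv(file.path(dir, "od_pairs.csv"))),
    commuters = tibble::as_tibble(read.csv(file.path(dir, "commuters.csv"))),
    config = NULL
  ), class = "cyclehia_population")
}
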