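# The five cycling-uptake scenarios. Each returns a per-commuter switch
# probability p_switch in [0, 1], computed in expectation (fractional
# cyclists); existing cyclists always keep cycling (p_switch = 0) and
# 30 km+/overseas commuters never switch in.

new_scenario_result <- function(population, scenario, p_switch,
                                extra = list()) {
  cm <- population$commuters
  stopifnot(length(p_switch) == nrow(cm),
            all(p_switch >= 0), all(p_switch <= 1 + 1e-12))
  p_switch <- pmin(p_switch, 1)
  baseline_cyclist <- cm$mode == "cycle"
  p_switch[baseline_cyclist] <- 0
  p_switch[cm$far] <- 0
  structure(list(
    scenario = scenario,
    result = tibble::tibble(id = cm$id, od_id = cm$od_id,
                            baseline_cyclist = baseline_cyclist,
                            p_switch = p_switch,
                            p_cycle = as.numeric(baseline_cyclist) + p_switch),
    extra = extra
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "<scenario_result: %s>  baseline %.2f%% -> scenario %.2f%% (expected new cyclists %.1f)\n",
    x$scenario, 100 * mean(r$baseline_cyclist), 100 * mean(r$p_cycle),
    sum(r$p_switch)))
  invisible(x)
}

#' Expected new cyclists in a scenario
#'
#' @param x A `scenario_result`.
#' @return Sum of switch probabilities.
#' @export
new_cyclists <- function(x) sum(x$result$p_switch)

#' National cycling mode share implied by a scenario
#'
#' Baseline cyclists plus expected switchers, over all commuters.
#'
#' @param x A `scenario_result`.
#' @return Proportion in \[0, 1\].
#' @export
scenario_mode_share <- function(x) mean(x$result$p_cycle)

# Water-filling calibration: scale propensities r on the eligible set so the
# expected number of switchers equals `target`, capping p at 1 and re-solving
# the scale on the uncapped set while any cap binds.
solve_scaled_uptake <- function(r, target, label) {
  stopifnot(all(r >= 0), target >= 0)
  p <- numeric(length(r))
  if (target == 0) return(list(p = p, lambda = 0))
  capped <- rep(FALSE, length(r))
  lambda <- 0
  repeat {
    resid <- target - sum(capped)
    mass <- sum(r[!capped])
    if (resid > sum(!capped & r > 0) + 1e-9 || (mass <= 0 && resid > 1e-9)) {
      stop("infeasible uptake target in ", label,
           ": required switchers exceed attainable uptake")
    }
    if (resid <= 0) break
    lambda <- resid / mass
    p_new <- lambda * r
    newly <- !capped & p_new >= 1
    p[!capped] <- p_new[!capped]
    if (!any(newly)) break
    p[newly] <- 1
    capped <- capped | newly
  }
  list(p = p, lambda = lambda)
}

#' Government Target (Equality) scenario
#'
#' Doubles cycling nationally in expectation. Each non-cyclist's switch
#' probability is proportional to the baseline distance/hilliness propensity
#' of their route -- identical for everyone in an OD pair regardless of
#' demographics -- with a national scale factor solved so that the expected
#' number of new cyclists equals the number of baseline cyclists.
#'
#' @param population A `cyclehia_population`.
#' @param baseline_model Fitted [fit_baseline()] model.
#' @param multiplier Target ratio of scenario to baseline cyclists (2 =
#'   doubling).
#' @return A `scenario_result`.
#' @export
gov_target_equality <- function(population, baseline_model, multiplier = 2) {
  stopifnot(multiplier > 1)
  cm <- population$commuters
  B <- sum(cm$mode == "cycle")
  if (B == 0) stop("no baseline cyclists: doubling target undefined")
  r <- commuter_propensity(population, baseline_model)
  eligible <- cm$mode != "cycle" & !cm$far
  r[!eligible] <- 0
  sol <- solve_scaled_uptake(r, (multiplier - 1) * B,
                             "Government Target (Equality)")
  new_scenario_result(population, "gov_target_equality", sol$p,
                      extra = list(lambda = sol$lambda))
}

#' Government Target (Near Market) scenario
#'
#' Same regional totals of new cyclists as Government Target (Equality), but
#' distributed within each region in proportion to the demographically
#' enriched stratified propensities, so uptake mirrors current demographic
#' skews.
#'
#' @param population A `cyclehia_population`.
#' @param nm_models Fitted [fit_near_market()] models.
#' @param equality_result The [gov_target_equality()] result to calibrate
#'   against.
#' @return A `scenario_result`.
#' @export
gov_target_near_market <- function(population, nm_models, equality_result) {
  cm <- population$commuters
  r <- commuter_propensity(population, nm_models)
  eligible <- cm$mode != "cycle" & !cm$far
  r[!eligible] <- 0
  p <- numeric(nrow(cm))
  lambdas <- c()
  for (reg in unique(cm$region)) {
    sel <- cm$region == reg
    target <- sum(equality_result$result$p_switch[sel])
    if (target > 0 && sum(r[sel]) <= 0) {
      stop("region ", reg, " has zero demographic propensity mass but a ",
           "positive uptake target")
    }
    sol <- solve_scaled_uptake(r[sel], target,
                               paste0("Near Market region ", reg))
    p[sel] <- sol$p
    lambdas[reg] <- sol$lambda
  }
  new_scenario_result(population, "gov_target_near_market", p,
                      extra = list(lambda = lambdas))
}

#' Gender Equality scenario
#'
#' Within each OD pair, women become as likely to cycle as men currently
#' are: the female cycling share is raised to the male share wherever it is
#' lower (no change where more women than men already cycle), with the
#' required uptake spread equally over the pair's female non-cyclists. All
#' new cyclists are female.
#'
#' @param population A `cyclehia_population`.
#' @return A `scenario_result`.
#' @export
gender_equality <- function(population) {
  cm <- population$commuters
  p <- numeric(nrow(cm))
  stats <- cm %>%
    dplyr::group_by(od_id) %>%
    dplyr::summarise(
      male_n = sum(sex == "male"),
      male_cyc = sum(sex == "male" & mode == "cycle"),
      fem_n = sum(sex == "female"),
      fem_cyc = sum(sex == "female" & mode == "cycle"),
      .groups = "drop") %>%
    dplyr::mutate(
      male_share = ifelse(male_n > 0, male_cyc / male_n, NA_real_),
      fem_share = ifelse(fem_n > 0, fem_cyc / fem_n, 0),
      target_share = pmax(ifelse(is.na(male_share), fem_share, male_share),
                          fem_share),
      need = pmax(0, target_share * fem_n - fem_cyc),
      n_fem_nc = fem_n - fem_cyc
    )
  p_od <- setNames(ifelse(stats$n_fem_nc > 0, stats$need / stats$n_fem_nc, 0),
                   stats$od_id)
  idx <- cm$sex == "female" & cm$mode != "cycle"
  p[idx] <- p_od[cm$od_id[idx]]
  new_scenario_result(population, "gender_equality", p)
}

#' Go Dutch scenario parameters
#'
#' Logit-scale uplift applied to the baseline distance/hilliness propensity
#' to reach Netherlands-equivalent cycling levels for the same distance and
#' hilliness: `logit(target) = logit(baseline) + intercept + per_km * d`.
#'
#' @param intercept Logit intercept shift.
#' @param per_km Additional logit shift per route km.
#' @return Named list.
#' @export
dutch_params <- function(intercept = 2.499, per_km = -0.07384) {
  if (is.null(intercept) || is.null(per_km) ||
      is.na(intercept) || is.na(per_km)) {
    stop("missing Go Dutch uplift parameters")
  }
  list(intercept = intercept, per_km = per_km)
}

# OD-pair level target-share uptake shared by Go Dutch and E-bikes:
# p_switch = max(0, target - current share) * n / n_noncyclists, equal over
# the pair's non-cyclists. The current share is the model's baseline
# propensity for the pair, so that a zero uplift is exactly the identity
# (no new cyclists) rather than reshuffling sampling noise.
target_share_uptake <- function(population, target_by_od, current_by_od,
                                scenario) {
  cm <- population$commuters
  stats <- cm %>%
    dplyr::group_by(od_id) %>%
    dplyr::summarise(n = dplyr::n(), cyc = sum(mode == "cycle"),
                     .groups = "drop")
  tgt <- target_by_od[stats$od_id]
  cur <- current_by_od[stats$od_id]
  need <- pmax(0, (tgt - cur) * stats$n)   # never reduces cycling
  n_nc <- stats$n - stats$cyc
  p_od <- setNames(ifelse(n_nc > 0, pmin(1, need / n_nc), 0), stats$od_id)
  p <- numeric(nrow(cm))
  idx <- cm$mode != "cycle" & !cm$far
  p[idx] <- p_od[cm$od_id[idx]]
  new_scenario_result(population, scenario, p)
}

od_level_propensity <- function(population, baseline_model,
                                attenuate = NULL) {
  od <- population$od_pairs
  usable <- !od$far & od$distance_km < 30
  cf <- baseline_model$coefficients
  if (!is.null(attenuate)) cf <- attenuate(cf)
  eta <- rep(NA_real_, nrow(od))
  eta[usable] <- linpred(cf, distance_basis(od$distance_km[usable],
                                            od$gradient_pct[usable]))
  setNames(eta, od$od_id)
}

#' Go Dutch scenario
#'
#' Applies the Dutch logit uplift to each OD pair's baseline
#' distance/hilliness propensity to obtain a target cycling share, then
#' raises the pair to that share (never reducing cycling), spreading the
#' uptake equally over the pair's non-cyclists.
#'
#' @param population A `cyclehia_population`.
#' @param baseline_model Fitted [fit_baseline()] model.
#' @param dutch [dutch_params()].
#' @return A `scenario_result`.
#' @export
go_dutch <- function(population, baseline_model, dutch = dutch_params()) {
  od <- population$od_pairs
  eta <- od_level_propensity(population, baseline_model)
  d_od <- setNames(od$distance_km, od$od_id)
  target <- plogis(eta + dutch$intercept + dutch$per_km * d_od[names(eta)])
  current <- plogis(eta)
  target[is.na(target)] <- 0
  current[is.na(current)] <- 0
  target_share_uptake(population, target, current, "go_dutch")
}

#' E-bike relief parameters
#'
#' Attenuation of the hilliness and long-distance penalties of the baseline
#' propensity model when electric assistance is available: gradient-related
#' coefficients are multiplied by `1 - hill_relief`, the linear distance
#' penalty by `1 - dist_relief` (only where it is a penalty, i.e. negative).
#'
#' Defaults: half the hill penalty removed (the deterrent effect of hills
#' for e-bike owners is about half that for others) and a modest 10% relief
#' of the linear distance penalty.
#'
#' @param hill_relief Fraction of the gradient penalty removed.
#' @param dist_relief Fraction of the linear distance penalty removed.
#' @return Named list.
#' @export
ebike_relief_params <- function(hill_relief = 0.5, dist_relief = 0.1) {
  if (is.null(hill_relief) || is.null(dist_relief) ||
      is.na(hill_relief) || is.na(dist_relief)) {
    stop("missing e-bike relief parameters")
  }
  stopifnot(hill_relief >= 0, hill_relief <= 1,
            dist_relief >= 0, dist_relief <= 1)
  list(hill_relief = hill_relief, dist_relief = dist_relief)
}

#' E-bikes scenario
#'
#' Builds on [go_dutch()]: the baseline propensity is recomputed with the
#' gradient and long-distance penalty coefficients attenuated per
#' [ebike_relief_params()], the Dutch uplift applied, and the OD-pair target
#' taken as the larger of the e-bike and Go Dutch targets (e-bike uptake is
#' never below Go Dutch).
#'
#' @param population A `cyclehia_population`.
#' @param baseline_model Fitted [fit_baseline()] model.
#' @param dutch [dutch_params()].
#' @param relief [ebike_relief_params()].
#' @return A `scenario_result`.
#' @export
ebikes <- function(population, baseline_model, dutch = dutch_params(),
                   relief = ebike_relief_params()) {
  od <- population$od_pairs
  attenuate <- function(cf) {
    for (term in c("grad", "d_grad", "sqrt_d_grad")) {
      cf[term] <- cf[term] * (1 - relief$hill_relief)
    }
    if (cf["d"] < 0) cf["d"] <- cf["d"] * (1 - relief$dist_relief)
    cf
  }
  d_od <- setNames(od$distance_km, od$od_id)
  eta_eb <- od_level_propensity(population, baseline_model, attenuate)
  eta_gd <- od_level_propensity(population, baseline_model)
  shift <- dutch$intercept + dutch$per_km * d_od[names(eta_eb)]
  target <- pmax(plogis(eta_eb + shift), plogis(eta_gd + shift))
  current <- plogis(eta_gd)
  target[is.na(target)] <- 0
  current[is.na(current)] <- 0
  target_share_uptake(population, target, current, "ebikes")
}

#' Run all five uptake scenarios
#'
#' @param population A `cyclehia_population`.
#' @param baseline_model Fitted [fit_baseline()] model.
#' @param nm_models Fitted [fit_near_market()] models.
#' @param dutch,relief Scenario parameters.
#' @return Named list of `scenario_result`s.
#' @export
run_scenarios <- function(population, baseline_model, nm_models,
                          dutch = dutch_params(),
                          relief = ebike_relief_params()) {
  eq <- gov_target_equality(population, baseline_model)
  list(
    gov_target_equality = eq,
    gov_target_near_market = gov_target_near_market(population, nm_models, eq),
    gender_equality = gender_equality(population),
    go_dutch = go_dutch(population, baseline_model, dutch),
    ebikes = ebikes(population, baseline_model, dutch, relief)
  )
}

#' Seeded Bernoulli realisation of a scenario
#'
#' Converts expected (fractional) uptake into a realised 0/1 switch flag.
#'
#' @param x A `scenario_result`.
#' @param seed Integer seed.
#' @return `x` with a logical `switched` column added.
#' @export
realise_switches <- function(x, seed = 1L) {
  set.seed(seed)
  x$result$switched <- runif(nrow(x$result)) < x$result$p_switch
  x
}
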