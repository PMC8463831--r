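# Uptake scenarios.

test_that("Government Target scale factor matches the closed form on a tiny population", {
  # 5 commuters in one pair, 1 cyclist; propensity r identical for all;
  # lambda = B / sum(r over non-cyclists) when no cap binds
  m <- stub_baseline_model(d = -1)
  od <- tibble::tibble(od_id = "A", distance_km = dist_for_prob(0.2),
                       gradient_pct = 0)
  cm <- tibble::tibble(od_id = rep("A", 5),
                       mode = c("cycle", rep("bus", 4)))
  pop <- manual_population(od, cm)
  res <- gov_target_equality(pop, m)
  lambda <- 1 / (4 * 0.2)
  expect_equal(res$extra$lambda, lambda, tolerance = 1e-9)
  expect_equal(res$result$p_switch, c(0, rep(lambda * 0.2, 4)),
               tolerance = 1e-9)
  expect_equal(sum(res$result$p_switch), 1, tolerance = 1e-12)  # doubling
})

test_that("national doubling holds in expectation and demographics do not matter within a pair", {
  pop <- get_shared_pop()
  bm <- fit_baseline(pop$commuters)
  res <- gov_target_equality(pop, bm)
  B <- sum(pop$commuters$mode == "cycle")
  expect_lt(abs(sum(res$result$p_switch) - B) / B, 1e-9)
  # same OD pair, different sex -> identical switch probability
  cm <- pop$commuters
  chk <- tibble::tibble(od_id = cm$od_id, sex = cm$sex,
                        cyc = cm$mode == "cycle", p = res$result$p_switch) %>%
    dplyr::filter(!cyc, !cm$far) %>%
    dplyr::group_by(od_id) %>%
    dplyr::summarise(spread = max(p) - min(p), .groups = "drop")
  expect_lt(max(chk$spread), 1e-12)
  # existing cyclists and 30 km+ commuters never switch
  expect_true(all(res$result$p_switch[cm$mode == "cycle"] == 0))
  expect_true(all(res$result$p_switch[cm$far] == 0))
})

test_that("capping triggers the iterative re-solve and conserves the target", {
  # one near-certain-propensity non-cyclist among a tiny-propensity pool:
  # model p = plogis(-4.6 + gradient), so pair A (gradient 7.54) has p ~ 0.95
  # and pair B (gradient 0) p ~ 0.01
  m <- stub_baseline_model(intercept = -4.6, grad = 1)
  od <- tibble::tibble(od_id = c("A", "B"), distance_km = 5,
                       gradient_pct = c(7.54, 0))
  cm <- tibble::tibble(od_id = c("A", rep("B", 30), rep("A", 3)),
                       mode = c("bus", rep("bus", 30), rep("cycle", 3)))
  pop <- manual_population(od, cm)
  res <- gov_target_equality(pop, m, multiplier = 2)
  expect_equal(sum(res$result$p_switch), 3, tolerance = 1e-9)
  expect_lte(max(res$result$p_switch), 1)
  expect_equal(max(res$result$p_switch), 1)  # the high-propensity commuter capped
})

test_that("infeasible doubling targets are rejected", {
  m <- stub_baseline_model(d = -1)
  od <- tibble::tibble(od_id = "A", distance_km = 5, gradient_pct = 0)
  cm <- tibble::tibble(od_id = rep("A", 3),
                       mode = c("cycle", "cycle", "bus"))
  pop <- manual_population(od, cm)
  expect_error(gov_target_equality(pop, m, multiplier = 4), "infeasible")
})

test_that("Near Market matches Equality regional totals and favours car-free commuters", {
  pop <- get_shared_pop()
  bm <- fit_baseline(pop$commuters)
  eq <- gov_target_equality(pop, bm)
  # handcrafted stratified models with a negative car-ownership effect
  cf <- c(`(Intercept)` = -3, d = -0.05, sqrt_d = 0, d2 = 0, grad = -0.1,
          d_grad = 0, sqrt_d_grad = 0, age_25_34 = 0, age_35_49 = 0,
          age_65_74 = 0, age_75p = 0, nonwhite = 0, has_car = -0.8,
          imd = 0, ur_minor = 0, ur_city = 0, ur_rural_town = 0,
          ur_rural_village = 0, sparse = 0)
  one <- list(coefficients = cf, se = cf * NA, converged = TRUE,
              dropped = character(0), n = 0, n_events = 0)
  keys <- as.vector(outer(
    as.vector(outer(region_levels(), c("male", "female"), paste, sep = "|")),
    broad_age_levels(), paste, sep = "|"))
  nm <- structure(list(models = setNames(rep(list(one), length(keys)), keys),
                       fallback = character(0), baseline = bm,
                       min_cyclists = 30),
                  class = c("near_market_models", "cyclehia_model"))
  res <- gov_target_near_market(pop, nm, eq)
  reg <- pop$commuters$region
  diff <- tapply(eq$result$p_switch, reg, sum) -
    tapply(res$result$p_switch, reg, sum)
  expect_lt(max(abs(diff)), 1e-6)
  # within an OD pair, otherwise-identical commuters: car owner lower p
  cm <- pop$commuters
  idx <- which(cm$mode != "cycle" & !cm$far & cm$dest_type == "fixed")
  key <- paste(cm$od_id, cm$sex, cm$age_band, cm$region)[idx]
  p <- res$result$p_switch[idx]
  car <- cm$has_car[idx]
  tab <- tibble::tibble(key, p, car) %>%
    dplyr::group_by(key) %>%
    dplyr::filter(dplyr::n_distinct(car) == 2) %>%
    dplyr::summarise(gap = mean(p[!car]) - mean(p[car]), .groups = "drop")
  expect_gt(nrow(tab), 0)
  expect_true(all(tab$gap > 0))
})

test_that("Gender Equality raises female shares to the male share and no further", {
  # male share 10%, female share 2% -> female scenario share 10%
  od <- tibble::tibble(od_id = "A", distance_km = 6, gradient_pct = 1)
  cm <- tibble::tibble(
    od_id = "A",
    sex = c(rep("male", 10), rep("female", 50)),
    mode = c("cycle", rep("bus", 9), "cycle", rep("bus", 49)))
  pop <- manual_population(od, cm)
  res <- gender_equality(pop)
  p <- res$result$p_switch
  expect_true(all(p[1:10] == 0))  # no male uptake
  need <- 0.1 * 50 - 1
  expect_equal(unique(p[cm$sex == "female" & cm$mode != "cycle"]),
               need / 49, tolerance = 1e-12)
  fem_share <- (1 + sum(p[cm$sex == "female"])) / 50
  expect_equal(fem_share, 0.1, tolerance = 1e-12)

  # more women than men already cycling: no change
  cm2 <- tibble::tibble(od_id = "A",
                        sex = c(rep("male", 20), rep("female", 20)),
                        mode = c(rep("bus", 19), "cycle",
                                 rep("cycle", 2), rep("bus", 18)))
  expect_equal(sum(gender_equality(manual_population(od, cm2))$result$p_switch), 0)

  # all-male pair: zero new cyclists
  cm3 <- tibble::tibble(od_id = "A", sex = "male",
                        mode = c("cycle", rep("bus", 4)))
  expect_equal(sum(gender_equality(manual_population(od, cm3))$result$p_switch), 0)
})

test_that("Go Dutch applies the logit uplift and a zero uplift is the identity", {
  pop <- get_shared_pop()
  bm <- fit_baseline(pop$commuters)
  zero <- go_dutch(pop, bm, dutch_params(intercept = 0, per_km = 0))
  expect_equal(sum(zero$result$p_switch), 0)

  # single pair: target 0.30, current 0.10, 9 non-cyclists of 10
  m <- stub_baseline_model(d = -1)
  dA <- dist_for_prob(0.1)
  od <- tibble::tibble(od_id = "A", distance_km = dA, gradient_pct = 0)
  cm <- tibble::tibble(od_id = rep("A", 10),
                       mode = c("cycle", rep("bus", 9)))
  popA <- manual_population(od, cm)
  shift <- qlogis(0.3) - qlogis(0.1)
  res <- go_dutch(popA, m, dutch_params(intercept = shift, per_km = 0))
  expect_equal(unique(res$result$p_switch[-1]), (0.3 - 0.1) * 10 / 9,
               tolerance = 1e-9)
  expect_error(dutch_params(intercept = NULL), "missing")
})

test_that("E-bikes reduce hill and distance penalties, never below Go Dutch", {
  pop <- get_shared_pop()
  bm <- fit_baseline(pop$commuters)
  gd <- go_dutch(pop, bm)
  eb0 <- ebikes(pop, bm, relief = ebike_relief_params(0, 0))
  expect_equal(eb0$result$p_switch, gd$result$p_switch, tolerance = 1e-12)
  eb <- ebikes(pop, bm)
  # per-OD uptake never below Go Dutch
  agg <- function(r) tapply(r$result$p_switch, pop$commuters$od_id, sum)
  expect_true(all(agg(eb) - agg(gd) > -1e-9))

  # a hilly pair gains proportionally more than a flat pair of equal length
  m <- stub_baseline_model(intercept = -2, d = -0.1, grad = -0.4)
  od <- tibble::tibble(od_id = c("flat", "hilly"), distance_km = 8,
                       gradient_pct = c(0.5, 4))
  cm <- tibble::tibble(od_id = rep(c("flat", "hilly"), each = 10),
                       mode = rep(c("cycle", rep("bus", 9)), 2))
  pop2 <- manual_population(od, cm)
  gd2 <- go_dutch(pop2, m)
  eb2 <- ebikes(pop2, m)
  up <- function(r, pair) sum(r$result$p_switch[cm$od_id == pair])
  rel_gain_hilly <- up(eb2, "hilly") / up(gd2, "hilly")
  rel_gain_flat <- up(eb2, "flat") / up(gd2, "flat")
  expect_gt(rel_gain_hilly, rel_gain_flat)
})

test_that("scenario ordering and conservation hold on a common population", {
  pop <- get_shared_pop()
  bm <- fit_baseline(pop$commuters)
  nm <- suppressWarnings(fit_near_market(pop$commuters))
  sc <- run_scenarios(pop, bm, nm)
  shares <- vapply(sc, scenario_mode_share, numeric(1))
  base <- mean(pop$commuters$mode == "cycle")
  expect_lt(base, shares["gender_equality"])
  expect_lte(shares["gender_equality"], shares["gov_target_equality"])
  expect_lt(shares["gov_target_equality"], shares["go_dutch"])
  expect_lt(shares["go_dutch"], shares["ebikes"])
  # conservation: scenario cyclists = baseline + new, per scenario
  for (r in sc) {
    expect_equal(sum(r$result$p_cycle),
                 sum(r$result$baseline_cyclist) + sum(r$result$p_switch),
                 tolerance = 1e-9)
  }
  # a seeded realisation agrees with expectations at population scale
  re <- realise_switches(sc$go_dutch, seed = 4)
  expect_lt(abs(sum(re$result$switched) - sum(re$result$p_switch)) /
              sum(re$result$p_switch), 0.1)
})
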