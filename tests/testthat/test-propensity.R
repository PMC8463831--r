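# Logit propensity models: baseline distance/hilliness and stratified
# demographic models.

test_that("predict equals the hand-computed logit", {
  m <- stub_baseline_model(intercept = -2, d = -0.3, sqrt_d = 0.9,
                           d2 = 0.004, grad = -0.25, d_grad = 0.01,
                           sqrt_d_grad = -0.04)
  nd <- tibble::tibble(distance_km = 7.3, gradient_pct = 2.1)
  eta <- -2 - 0.3 * 7.3 + 0.9 * sqrt(7.3) + 0.004 * 7.3^2 - 0.25 * 2.1 +
    0.01 * 7.3 * 2.1 - 0.04 * sqrt(7.3) * 2.1
  expect_equal(predict(m, nd), plogis(eta), tolerance = 1e-12)

  # all-zero coefficients predict exactly 0.5
  expect_equal(predict(stub_baseline_model(),
                       tibble::tibble(distance_km = 5, gradient_pct = 1)), 0.5)

  # monotone decreasing in gradient under a negative gradient coefficient
  m2 <- stub_baseline_model(grad = -0.3)
  p <- predict(m2, tibble::tibble(distance_km = 5, gradient_pct = c(1, 2)))
  expect_lt(p[2], p[1])

  expect_error(predict(m, tibble::tibble(distance_km = 31, gradient_pct = 1)),
               "30 km")
})

test_that("single-class outcomes raise a separation error", {
  cm <- tibble::tibble(mode = "cycle", distance_km = runif(50, 1, 10),
                       gradient_pct = 1, dest_type = "fixed", far = FALSE)
  expect_error(fit_baseline(cm), "single-class")
})

test_that("duplicating every observation leaves estimates unchanged", {
  pop <- get_shared_pop()
  cm <- pop$commuters
  f1 <- fit_baseline(cm)
  f2 <- fit_baseline(dplyr::bind_rows(cm, cm))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("baseline fit recovers known coefficients within 3 s.e.", {
  coef <- default_cycle_coef()
  coef$female <- 0
  coef$age[] <- 0
  coef$imd <- 0
  coef$urban_rural[] <- 0
  coef$sparse <- 0
  cfg <- population_config(n_commuters = 20000, seed = 31, cycle_coef = coef)
  pop <- generate_population(cfg)
  fit <- fit_baseline(pop$commuters)
  truth <- c(coef$intercept, coef$d, coef$sqrt_d, coef$d2, coef$grad,
             coef$d_grad, coef$sqrt_d_grad)
  z <- (fit$coefficients - truth) / fit$se
  expect_true(all(abs(z) < 3))
  # gradient deters cycling on realistic synthetic data: higher gradient,
  # lower predicted propensity at the mean distance
  p <- predict(fit, tibble::tibble(distance_km = 8, gradient_pct = c(0.5, 4)))
  expect_lt(p[2], p[1])
})

test_that("stratified models recover stratum-specific car effects (weaker in London)", {
  set.seed(77)
  make_stratum <- function(region, car_effect, n = 15000) {
    df <- tibble::tibble(
      region = region, sex = "male",
      age_band = sample(c("16-24", "25-34", "35-49"), n, replace = TRUE),
      ethnicity = sample(c("white", "non-white"), n, replace = TRUE, prob = c(.85, .15)),
      has_car = runif(n) < 0.75,
      imd_quintile = sample(1:5, n, replace = TRUE),
      urban_rural = "Urban major conurbation", sparse = FALSE,
      dest_type = "fixed", far = FALSE,
      distance_km = pmin(29, rlnorm(n, 1.8, 0.6)),
      gradient_pct = runif(n, 0, 4))
    eta <- -2.2 - 0.12 * df$distance_km - 0.2 * df$gradient_pct +
      car_effect * df$has_car - 0.4 * (df$ethnicity == "non-white")
    df$mode <- ifelse(runif(n) < plogis(eta), "cycle", "car_driver")
    df
  }
  cm <- dplyr::bind_rows(make_stratum("Inner London", -0.2),
                         make_stratum("North West", -1.0))
  nm <- suppressWarnings(fit_near_market(cm))
  lon <- nm$models[["Inner London|male|16-49"]]
  nw <- nm$models[["North West|male|16-49"]]
  expect_false(is.null(lon))
  expect_false(is.null(nw))
  expect_gt(lon$coefficients["has_car"], nw$coefficients["has_car"])
  expect_lt(abs(lon$coefficients["has_car"] + 0.2),
            3 * lon$se["has_car"])
  expect_lt(abs(nw$coefficients["has_car"] + 1.0), 3 * nw$se["has_car"])
})

test_that("sparse strata fall back to the pooled baseline model", {
  pop <- get_shared_pop()
  expect_warning(nm <- fit_near_market(pop$commuters, min_cyclists = 1e6),
                 "fell back")
  expect_equal(length(nm$fallback), 44)
  # fallback predictions equal the baseline model's
  bm <- fit_baseline(pop$commuters)
  cm <- head(pop$commuters[pop$commuters$dest_type == "fixed" &
                             !pop$commuters$far &
                             pop$commuters$distance_km < 30, ], 20)
  expect_equal(predict(nm, cm), predict(bm, cm), tolerance = 1e-12)
})

test_that("no-fixed-workplace propensity is the commuter-weighted OD mean", {
  # two OD pairs with 1 and 3 commuters and propensities 0.1 and 0.3
  m <- stub_baseline_model(d = -1)
  od <- tibble::tibble(od_id = c("A", "B"),
                       distance_km = dist_for_prob(c(0.1, 0.3)),
                       gradient_pct = 0)
  cm <- tibble::tibble(od_id = c("A", "B", "B", "B"))
  pop <- manual_population(od, cm)
  expect_equal(no_fixed_workplace_propensity("Z001", pop, m),
               (0.1 + 3 * 0.3) / 4, tolerance = 1e-9)

  # single pair: equals that pair's propensity
  pop1 <- manual_population(od[1, ], tibble::tibble(od_id = "A"))
  expect_equal(no_fixed_workplace_propensity("Z001", pop1, m), 0.1,
               tolerance = 1e-9)

  # empty zone: falls back to the regional mean, with a message
  od2 <- dplyr::bind_rows(od, tibble::tibble(od_id = "C", distance_km = 5,
                                             gradient_pct = 0))
  cm2 <- dplyr::bind_rows(cm, tibble::tibble(od_id = "C"))
  cm2$zone_id <- c(rep("Z001", 4), "Z009")
  pop2 <- manual_population(od2, cm2)
  pop2$zones <- dplyr::bind_rows(
    pop2$zones,
    tibble::tibble(zone_id = "Z777", region = "North West",
                   imd_quintile = 3L, urban_rural = "Urban city and town",
                   sparse = FALSE, mortality_table_key = "North West"))
  expect_message(v <- no_fixed_workplace_propensity("Z777", pop2, m),
                 "regional mean")
  expect_equal(v, mean(predict(m, pop2$commuters)), tolerance = 1e-9)
})

test_that("fitted models serialise to a coefficient table", {
  pop <- get_shared_pop()
  bm <- fit_baseline(pop$commuters)
  path <- withr::local_tempfile(fileext = ".csv")
  write_models(bm, path)
  tab <- read.csv(path)
  expect_equal(names(tab), c("stratum", "term", "estimate", "se"))
  expect_equal(tab$estimate[tab$term == "d"],
               unname(bm$coefficients["d"]))
})
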