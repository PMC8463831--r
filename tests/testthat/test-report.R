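# Grouped report tables.

make_report_inputs <- function() {
  pop <- get_shared_pop()
  bm <- fit_baseline(pop$commuters)
  nm <- suppressWarnings(fit_near_market(pop$commuters))
  sc <- run_scenarios(pop, bm, nm)
  led <- impact_ledger(pop, sc$go_dutch)
  list(pop = pop, sc = sc, led = led)
}

inputs <- make_report_inputs()

test_that("mode-share tables recompute shares from counts consistently", {
  tab <- mode_share_table(inputs$pop, inputs$sc, by = "sex")
  cm <- inputs$pop$commuters
  # shares recomputed from counts match to 0.1 percentage points
  for (nm in names(inputs$sc)) {
    col <- paste0(nm, "_pct")
    recomputed <- 100 * (tab$baseline_cyclists +
                           tab[[paste0(nm, "_new_cyclists")]]) / tab$n
    expect_lt(max(abs(tab[[col]] - recomputed)), 0.1)
  }
  # group rows sum to the whole-sample row
  groups <- tab[tab$group != "Whole sample", ]
  whole <- tab[tab$group == "Whole sample", ]
  expect_equal(sum(groups$n), whole$n)
  expect_equal(sum(groups$go_dutch_new_cyclists),
               whole$go_dutch_new_cyclists, tolerance = 1e-9)
  # Gender Equality: zero new male cyclists, so the male scenario share
  # equals the male baseline share
  male <- tab[tab$group == "male", ]
  expect_equal(male$gender_equality_new_cyclists, 0)
  expect_equal(male$gender_equality_pct, male$baseline_pct)
})

test_that("impact tables are additive over groups and normalise per million", {
  led <- inputs$led
  pop <- inputs$pop
  for (by in c("region", "imd_quintile", "hilliness_band")) {
    tab <- impact_table(led, pop, by = by)
    groups <- tab[tab$group != "Whole sample", ]
    whole <- tab[tab$group == "Whole sample", ]
    expect_equal(sum(groups$ylls_averted), whole$ylls_averted,
                 tolerance = 1e-6)
    expect_equal(sum(groups$co2_kg_saved), whole$co2_kg_saved,
                 tolerance = 1e-6)
    expect_equal(sum(groups$n), whole$n)
  }
  # per-million x (denominator / 1e6) recovers the group totals
  pm <- per_million_table(led, pop, by = "sex")
  tot <- impact_table(led, pop, by = "sex")
  expect_equal(pm$ylls_averted * pm$new_cyclists / 1e6, tot$ylls_averted,
               tolerance = 1e-9)
  pm2 <- per_million_table(led, pop, by = "sex", denominator = "commuters")
  expect_equal(pm2$deaths_averted * pm2$n / 1e6, tot$deaths_averted,
               tolerance = 1e-9)
})

test_that("a one-individual population's table equals its ledger row", {
  od <- tibble::tibble(od_id = "A", distance_km = 8, gradient_pct = 1.5)
  cm <- tibble::tibble(od_id = "A", mode = "car_driver")
  pop <- manual_population(od, cm)
  res <- structure(list(
    scenario = "toy",
    result = tibble::tibble(id = pop$commuters$id, od_id = "A",
                            baseline_cyclist = FALSE, p_switch = 1,
                            p_cycle = 1)),
    class = "scenario_result")
  led <- impact_ledger(pop, res)
  tab <- impact_table(led, pop, by = "sex")
  expect_equal(tab$ylls_averted[tab$group == "male"], led$ylls_averted)
  expect_equal(tab$co2_kg_saved[tab$group == "Whole sample"],
               led$co2_kg_saved)
})

test_that("report generation is pure: identical inputs give identical output", {
  t1 <- mode_share_table(inputs$pop, inputs$sc["go_dutch"], by = "age_band")
  t2 <- mode_share_table(inputs$pop, inputs$sc["go_dutch"], by = "age_band")
  expect_identical(t1, t2)
})

test_that("the hilliness table contrasts gradient-aware and gradient-blind health benefits", {
  tab <- hilliness_table(inputs$pop, inputs$sc$go_dutch)
  expect_true(all(c("ylls_per_1000_no_hilliness",
                    "ylls_per_1000_with_hilliness") %in% names(tab)))
  expect_gt(nrow(tab), 2)
  # uptake declines with hilliness on the synthetic population
  expect_true(all(diff(tab$pct_cycling) < 0))
  # the two columns differ, and factoring hilliness in narrows the
  # flat-vs-hilly benefit ratio
  expect_false(isTRUE(all.equal(tab$ylls_per_1000_no_hilliness,
                                tab$ylls_per_1000_with_hilliness)))
  ratio_no <- tab$ylls_per_1000_no_hilliness[nrow(tab)] /
    tab$ylls_per_1000_no_hilliness[1]
  ratio_with <- tab$ylls_per_1000_with_hilliness[nrow(tab)] /
    tab$ylls_per_1000_with_hilliness[1]
  expect_gt(ratio_with, ratio_no)
})
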