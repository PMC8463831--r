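# Aggregation of per-individual results into grouped report tables: mode
# shares per scenario, impact totals, per-million normalisations, and the
# hilliness-band comparison of health benefits with and without
# gradient-dependent intensities.

grouping_vars <- function() {
  c("sex", "age_band", "ethnicity", "has_car", "imd_quintile",
    "urban_rural", "region", "hilliness_band")
}

#' Hilliness bands
#'
#' Cuts mean route gradients into the bands \[0,1), \[1,2), \[2,3), \[3,4),
#' \[4, max\].
#'
#' @param gradient_pct Gradients, percent.
#' @return Character band labels.
#' @export
hilliness_band <- function(gradient_pct) {
  as.character(cut(gradient_pct, c(0, 1, 2, 3, 4, Inf),
                   labels = c("0-0.99", "1-1.99", "2-2.99", "3-3.99", "4+"),
                   right = FALSE, include.lowest = TRUE))
}

group_column <- function(population, by) {
  by <- match.arg(by, grouping_vars())
  cm <- population$commuters
  if (by == "hilliness_band") hilliness_band(cm$gradient_pct)
  else as.character(cm[[by]])
}

#' Mode-share table by demographic group
#'
#' Per group: commuter count, baseline cyclists and share, and expected new
#' cyclists and total cycling share per scenario (total share = (baseline +
#' new) / n). A `"Whole sample"` row is appended.
#'
#' @param population A `cyclehia_population`.
#' @param scenarios Named list of `scenario_result`s.
#' @param by Grouping variable (one of sex, age_band, ethnicity, has_car,
#'   imd_quintile, urban_rural, region, hilliness_band).
#' @return Tibble.
#' @export
mode_share_table <- function(population, scenarios, by = "sex") {
  cm <- population$commuters
  grp <- group_column(population, by)
  base <- tibble::tibble(group = c(grp, rep("Whole sample", nrow(cm))),
                         cyc = rep(cm$mode == "cycle", 2)) %>%
    dplyr::group_by(group) %>%
    dplyr::summarise(n = dplyr::n(), baseline_cyclists = sum(cyc),
                     baseline_pct = 100 * mean(cyc), .groups = "drop")
  for (nm in names(scenarios)) {
    p <- scenarios[[nm]]$result$p_switch
    add <- tibble::tibble(group = c(grp, rep("Whole sample", length(grp))),
                          p = rep(p, 2)) %>%
      dplyr::group_by(group) %>%
      dplyr::summarise(new = sum(p), .groups = "drop")
    base[[paste0(nm, "_new_cyclists")]] <- add$new[match(base$group, add$group)]
    base[[paste0(nm, "_pct")]] <- base$baseline_pct +
      100 * base[[paste0(nm, "_new_cyclists")]] / base$n
  }
  base
}

#' Impact totals by demographic group
#'
#' Sums every ledger field within groups of `by`, with a `"Whole sample"`
#' row; group rows sum to the whole-sample row (the ledger is additive).
#'
#' @param ledger An [impact_ledger()].
#' @param population The population the ledger was computed on.
#' @param by Grouping variable.
#' @return Tibble.
#' @export
impact_table <- function(ledger, population, by = "sex") {
  grp <- c(group_column(population, by), rep("Whole sample", nrow(ledger)))
  fields <- ledger_fields()
  led2 <- dplyr::bind_rows(ledger[c("p_switch", fields)],
                           ledger[c("p_switch", fields)])
  led2$group <- grp
  led2 %>%
    dplyr::group_by(group) %>%
    dplyr::summarise(n = dplyr::n(), new_cyclists = sum(p_switch),
                     dplyr::across(dplyr::all_of(fields), sum),
                     .groups = "drop")
}

#' Impacts normalised per million new cyclists (or commuters)
#'
#' Divides each group's summed impacts by its expected new cyclists (or its
#' commuter count) and multiplies by 1e6. Groups with a zero denominator get
#' NA, with a message.
#'
#' @param ledger An [impact_ledger()].
#' @param population The population the ledger was computed on.
#' @param by Grouping variable.
#' @param denominator `"new_cyclists"` or `"commuters"`.
#' @return Tibble.
#' @export
per_million_table <- function(ledger, population, by = "sex",
                              denominator = c("new_cyclists", "commuters")) {
  denominator <- match.arg(denominator)
  grp <- c(group_column(population, by), rep("Whole sample", nrow(ledger)))
  fields <- ledger_fields()
  led2 <- dplyr::bind_rows(ledger[c("p_switch", fields)],
                           ledger[c("p_switch", fields)])
  led2$group <- grp
  out <- led2 %>%
    dplyr::group_by(group) %>%
    dplyr::summarise(n = dplyr::n(), new_cyclists = sum(p_switch),
                     dplyr::across(dplyr::all_of(fields), sum),
                     .groups = "drop")
  out$n <- out$n / 1L
  den <- if (denominator == "new_cyclists") out$new_cyclists else out$n
  if (any(den == 0)) {
    message("per-million normalisation: ", sum(den == 0),
            " group(s) with zero denominator left blank")
  }
  for (f in fields) out[[f]] <- ifelse(den > 0, out[[f]] / den * 1e6, NA_real_)
  out
}

#' Health benefits by hilliness band, with and without gradient effects
#'
#' Recomputes the impact ledger twice from the same scenario run: once with
#' each route's own gradient, and once with every gradient forced to the
#' population mean (so hilliness affects uptake but not the health model),
#' and reports YLLs averted per 1000 commuters by hilliness band alongside
#' cycling mode share.
#'
#' @param population A `cyclehia_population`.
#' @param scenario_result A `scenario_result`.
#' @param ... Passed to [impact_ledger()].
#' @return Tibble by hilliness band.
#' @export
hilliness_table <- function(population, scenario_result, ...) {
  cm <- population$commuters
  mean_grad <- mean(cm$gradient_pct)
  with_g <- impact_ledger(population, scenario_result, ...)
  flat_g <- impact_ledger(population, scenario_result,
                          gradient_override = mean_grad, ...)
  band <- hilliness_band(cm$gradient_pct)
  tibble::tibble(
    hilliness_band = band,
    p_cycle = scenario_result$result$p_cycle,
    yll_flat = flat_g$ylls_averted,
    yll_grad = with_g$ylls_averted
  ) %>%
    dplyr::group_by(hilliness_band) %>%
    dplyr::summarise(
      n = dplyr::n(),
      pct_cycling = 100 * mean(p_cycle),
      ylls_per_1000_no_hilliness = 1000 * sum(yll_flat) / dplyr::n(),
      ylls_per_1000_with_hilliness = 1000 * sum(yll_grad) / dplyr::n(),
      .groups = "drop")
}
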