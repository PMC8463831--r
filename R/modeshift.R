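# Former-mode assignment for new cyclists. The former mode gates the
# downstream accounting: ex-walkers are debited displaced walking activity,
# and only ex-car-drivers generate carbon savings.

#' Allocate an OD pair's new cyclists to former modes proportionally
#'
#' Former-mode shares equal the pair's current non-cyclist mode split: if 1/3
#' of the pair's non-cyclists walk and 2/3 use the bus, 1/3 of its new
#' cyclists are ex-walkers and 2/3 ex-bus users.
#'
#' @param mode_counts Named counts of the pair's non-cyclist commuters by
#'   mode.
#' @param n_new Number of new cyclists (may be fractional: expectations are
#'   canonical).
#' @return Named numeric allocation summing to `n_new`.
#' @export
allocate_proportional <- function(mode_counts, n_new) {
  stopifnot(all(mode_counts >= 0), n_new >= 0)
  total <- sum(mode_counts)
  if (n_new > total + 1e-9) {
    stop("n_new (", n_new, ") exceeds the pair's non-cyclist count (",
         total, ")")
  }
  if (total == 0) return(mode_counts * 0)
  n_new * mode_counts / total
}

#' Largest-remainder integerisation of a fractional allocation
#'
#' Display helper only; fractional allocations remain canonical.
#'
#' @param allocation Named non-negative allocation.
#' @return Named integer allocation with the same (rounded) total.
#' @export
integerise_allocation <- function(allocation) {
  target <- round(sum(allocation))
  fl <- floor(allocation)
  rem <- allocation - fl
  short <- target - sum(fl)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[top] <- fl[top] + 1
  }
  fl
}

#' Per-commuter former mode of individual-level scenario uptake
#'
#' When uptake is modelled per individual, each switcher's former mode is
#' their own baseline mode. Returns the scenario result table with
#' `former_mode` attached (NA for baseline cyclists, who do not switch).
#'
#' @param population A `cyclehia_population`.
#' @param scenario_result A `scenario_result`.
#' @return Tibble: scenario result columns plus `former_mode`.
#' @export
allocate_individual <- function(population, scenario_result) {
  cm <- population$commuters
  r <- scenario_result$result
  stopifnot(identical(r$id, cm$id))
  r$former_mode <- ifelse(r$baseline_cyclist, NA_character_, cm$mode)
  r
}

#' Expected mode-shift allocation by OD pair
#'
#' Aggregates per-individual switch probabilities to expected new cyclists by
#' OD pair and former mode; totals conserve each pair's expected new-cyclist
#' count.
#'
#' @param population A `cyclehia_population`.
#' @param scenario_result A `scenario_result`.
#' @return Tibble with `od_id`, `former_mode`, `n_new`.
#' @export
mode_shift_allocation <- function(population, scenario_result) {
  allocate_individual(population, scenario_result) %>%
    dplyr::filter(!baseline_cyclist) %>%
    dplyr::group_by(od_id, former_mode) %>%
    dplyr::summarise(n_new = sum(p_switch), .groups = "drop")
}
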