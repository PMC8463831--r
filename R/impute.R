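# Probabilistic binary-attribute imputation within OD-pair x mode cells.
# Per-cell marginal counts are preserved exactly: exactly k_true individuals
# are flagged, chosen by weighted sampling without replacement (sequential
# draws with renormalisation, as implemented by base R `sample()`).

#' Impute a binary attribute within one cell, preserving the marginal exactly
#'
#' Flags exactly `k_true` of `n` individuals as TRUE. Selection is by
#' weighted sampling without replacement with per-individual `weights`, so
#' e.g. with car-ownership weights increasing in age and male sex, an older
#' male commuter is more likely than a younger female commuter to receive the
#' known car in their cell.
#'
#' @param n Cell size.
#' @param k_true Number of individuals that must be TRUE (0 <= k_true <= n).
#' @param weights Non-negative selection weights, length `n`. Ignored when
#'   `k_true` is 0 or `n`.
#' @return Logical vector of length `n` with exactly `k_true` TRUE entries.
#' @export
impute_binary_attribute <- function(n, k_true, weights = rep(1, n)) {
  stopifnot(length(n) == 1, length(k_true) == 1)
  if (k_true < 0 || k_true > n) {
    stop("k_true (", k_true, ") must be between 0 and the cell size (", n, ")")
  }
  out <- rep(FALSE, n)
  if (k_true == 0) return(out)
  if (k_true == n) return(rep(TRUE, n))
  if (length(weights) != n) stop("weights must have length n")
  if (any(weights < 0)) stop("negative weight in cell")
  if (all(weights == 0)) stop("all weights zero with 0 < k_true < n")
  out[sample.int(n, k_true, prob = weights)] <- TRUE
  out
}

# Default imputation weight models: conditional-probability surrogates on the
# scale of odds. Car ownership rises with age and male sex; non-white
# ethnicity is more likely in London, in younger commuters and in car-free
# households.
car_weights <- function(cell) {
  age_idx <- match(cell$age_band, age_band_levels())
  exp(0.35 * (age_idx - 1) + 0.50 * (cell$sex == "male"))
}

ethnicity_weights <- function(cell) {
  age_idx <- match(cell$age_band, age_band_levels())
  exp(0.80 * (cell$region %in% c("Inner London", "Outer London")) -
        0.15 * (age_idx - 1) + 0.70 * (!cell$has_car))
}

impute_attribute_by_cell <- function(commuters, marginals, weight_fn, what) {
  key <- paste(commuters$od_id, commuters$mode, sep = "\r")
  mkey <- paste(marginals$od_id, marginals$mode, sep = "\r")
  idx_by_cell <- split(seq_len(nrow(commuters)), key)
  k_by_cell <- setNames(marginals$k_true, mkey)
  missing <- setdiff(names(idx_by_cell), mkey)
  if (length(missing) > 0) {
    bad <- strsplit(missing[1], "\r", fixed = TRUE)[[1]]
    stop("missing ", what, " marginal for cell od_id=", bad[1],
         " mode=", bad[2])
  }
  out <- logical(nrow(commuters))
  # deterministic cell order for a reproducible RNG stream
  for (cell_key in sort(names(idx_by_cell), method = "radix")) {
    idx <- idx_by_cell[[cell_key]]
    cell <- commuters[idx, ]
    out[idx] <- impute_binary_attribute(length(idx), k_by_cell[[cell_key]],
                                        weight_fn(cell))
  }
  out
}

#' Sequential imputation of car ownership then ethnicity
#'
#' Car ownership is imputed first, with selection weights based on age and
#' sex; ethnicity second, with weights additionally conditioned on the
#' just-imputed car ownership (and region). Every OD-pair x mode marginal
#' count is satisfied exactly.
#'
#' @param commuters Commuter tibble (columns `od_id`, `mode`, `sex`,
#'   `age_band`, `region`).
#' @param car_marginals,eth_marginals Tibbles with `od_id`, `mode`, `k_true`:
#'   the number of car owners / non-white commuters per cell.
#' @param car_weight_fn,eth_weight_fn Functions mapping a cell's commuter
#'   rows to selection weights.
#' @return `commuters` with logical `has_car` and `ethnicity`
#'   (`"white"`/`"non-white"`) columns.
#' @export
impute_car_then_ethnicity <- function(commuters, car_marginals, eth_marginals,
                                      car_weight_fn = car_weights,
                                      eth_weight_fn = ethnicity_weights) {
  commuters$has_car <- impute_attribute_by_cell(commuters, car_marginals,
                                                car_weight_fn, "car ownership")
  nonwhite <- impute_attribute_by_cell(commuters, eth_marginals,
                                       eth_weight_fn, "ethnicity")
  commuters$ethnicity <- ifelse(nonwhite, "non-white", "white")
  commuters
}
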