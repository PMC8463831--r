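# Logit models of baseline cycling propensity: a national distance/hilliness
# model, and 44 demographically enriched models stratified by region, sex and
# broad age band. Fits use maximum likelihood (stats::glm, binomial) on an
# explicit dummy-coded design matrix; rank-deficient columns get coefficient
# zero at prediction time.

#' Distance/hilliness design basis
#'
#' Non-linear distance terms `d`, `sqrt(d)`, `d^2`, the gradient, and
#' `d x gradient`, `sqrt(d) x gradient` interactions (the deterrent effect of
#' distance varies with hilliness).
#'
#' @param d Route distance, km.
#' @param g Mean uphill route gradient, percent.
#' @return Numeric matrix with named columns.
#' @export
distance_basis <- function(d, g) {
  cbind(d = d, sqrt_d = sqrt(d), d2 = d^2,
        grad = g, d_grad = d * g, sqrt_d_grad = sqrt(d) * g)
}

nm_design <- function(df) {
  ab <- df$age_band
  ur <- df$urban_rural
  cbind(
    distance_basis(df$distance_km, df$gradient_pct),
    age_25_34 = as.numeric(ab == "25-34"),
    age_35_49 = as.numeric(ab == "35-49"),
    age_65_74 = as.numeric(ab == "65-74"),
    age_75p = as.numeric(ab == "75+"),
    nonwhite = as.numeric(df$ethnicity == "non-white"),
    has_car = as.numeric(df$has_car),
    imd = df$imd_quintile - 3,
    ur_minor = as.numeric(ur == "Urban minor conurbation"),
    ur_city = as.numeric(ur == "Urban city and town"),
    ur_rural_town = as.numeric(ur == "Rural town and fringe"),
    ur_rural_village = as.numeric(ur == "Rural village and dispersed"),
    sparse = as.numeric(df$sparse)
  )
}

fit_logit <- function(y, X, label) {
  if (length(unique(y)) < 2) {
    stop("outcome is single-class (separation) in ", label,
         ": cannot fit a logit")
  }
  X1 <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(
    glm.fit(X1, y, family = binomial(), control = list(maxit = 100))
  )
  if (!fit$converged) {
    warning("logit fit did not converge in ", label)
  }
  cf <- fit$coefficients
  # rank-deficient columns: coefficient 0 (column constant in this stratum)
  dropped <- names(cf)[is.na(cf)]
  cf[is.na(cf)] <- 0
  # standard errors from the unscaled covariance of the kept columns
  se <- rep(NA_real_, length(cf))
  names(se) <- names(cf)
  W <- fit$weights
  Xk <- X1[, setdiff(colnames(X1), dropped), drop = FALSE]
  XtWX <- crossprod(Xk * sqrt(W))
  cov_ok <- TRUE
  cv <- tryCatch(solve(XtWX), error = function(e) { cov_ok <<- FALSE; NULL })
  if (cov_ok) se[colnames(Xk)] <- sqrt(diag(cv))
  list(coefficients = cf, se = se, converged = fit$converged,
       dropped = dropped, n = length(y), n_events = sum(y))
}

#' @importFrom stats glm.fit
NULL

#' Fit the baseline distance/hilliness cycling logit
#'
#' Individual-level maximum-likelihood logistic regression of cycling
#' (outcome: main mode is cycle) on the [distance_basis()] terms, fitted on
#' fixed-workplace commuters with route distance under 30 km.
#'
#' @param commuters Commuter tibble (needs `mode`, `distance_km`,
#'   `gradient_pct`, `dest_type`, `far`).
#' @return Object of class `c("baseline_model", "cyclehia_model")`.
#' @export
fit_baseline <- function(commuters) {
  df <- commuters[commuters$dest_type == "fixed" & !commuters$far &
                    commuters$distance_km < 30, ]
  y <- as.numeric(df$mode == "cycle")
  fit <- fit_logit(y, distance_basis(df$distance_km, df$gradient_pct),
                   "baseline model")
  structure(c(fit, list(design = "distance")),
            class = c("baseline_model", "cyclehia_model"))
}

stratum_key <- function(region, sex, broad) paste(region, sex, broad, sep = "|")

#' Fit the 44 stratified demographic cycling models
#'
#' Stratifies fixed-workplace sub-30 km commuters by region (11), sex (2) and
#' broad age band (16-49 / 50+), then fits one logit per stratum with the
#' distance/hilliness basis plus age category, ethnicity, household car,
#' income-deprivation quintile, urban/rural class and sparsity as main-effect
#' predictors. Strata with fewer than `min_cyclists` cyclists (or a
#' single-class outcome) fall back to the pooled baseline model, with a
#' warning.
#'
#' @param commuters Commuter tibble.
#' @param min_cyclists Minimum cyclists required to fit a stratum model.
#' @return Object of class `c("near_market_models", "cyclehia_model")` with
#'   one entry per stratum.
#' @export
fit_near_market <- function(commuters, min_cyclists = 30) {
  df <- commuters[commuters$dest_type == "fixed" & !commuters$far &
                    commuters$distance_km < 30, ]
  baseline <- fit_baseline(commuters)
  strata <- expand.grid(region = region_levels(), sex = c("male", "female"),
                        broad = broad_age_levels(),
                        stringsAsFactors = FALSE)
  df_broad <- broad_age(df$age_band)
  models <- list()
  fallback <- character(0)
  for (i in seq_len(nrow(strata))) {
    key <- stratum_key(strata$region[i], strata$sex[i], strata$broad[i])
    sel <- df$region == strata$region[i] & df$sex == strata$sex[i] &
      df_broad == strata$broad[i]
    sub <- df[sel, ]
    y <- as.numeric(sub$mode == "cycle")
    if (nrow(sub) == 0 || sum(y) < min_cyclists || sum(y) == nrow(sub)) {
      fallback <- c(fallback, key)
      models[[key]] <- NULL
    } else {
      models[[key]] <- fit_logit(y, nm_design(sub), paste("stratum", key))
    }
  }
  if (length(fallback) > 0) {
    warning(length(fallback),
            " strata fell back to the baseline model (too few cyclists): ",
            paste(utils::head(fallback, 5), collapse = ", "),
            if (length(fallback) > 5) ", ..." else "")
  }
  structure(list(models = models, fallback = fallback, baseline = baseline,
                 min_cyclists = min_cyclists),
            class = c("near_market_models", "cyclehia_model"))
}

check_predict_range <- function(d) {
  if (any(d >= 30)) {
    stop("cannot predict for routes of 30 km or more; ",
         "30 km+/overseas commuters are excluded from uptake")
  }
  if (any(d <= 0)) stop("route distance must be positive")
}

linpred <- function(cf, X) {
  X1 <- cbind(`(Intercept)` = 1, X)
  drop(X1[, names(cf), drop = FALSE] %*% cf)
}

#' Predict cycling propensity
#'
#' @param object A fitted `baseline_model` or `near_market_models`.
#' @param newdata Tibble with `distance_km`, `gradient_pct` (and, for the
#'   stratified models, the demographic columns and `region`, `sex`,
#'   `age_band`).
#' @param ... Unused.
#' @return Probabilities in (0, 1).
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  check_predict_range(newdata$distance_km)
  plogis(linpred(object$coefficients,
                 distance_basis(newdata$distance_km, newdata$gradient_pct)))
}

#' @rdname predict.baseline_model
#' @export
predict.near_market_models <- function(object, newdata, ...) {
  check_predict_range(newdata$distance_km)
  keys <- stratum_key(newdata$region, newdata$sex, broad_age(newdata$age_band))
  out <- numeric(nrow(newdata))
  for (key in unique(keys)) {
    idx <- which(keys == key)
    m <- object$models[[key]]
    if (is.null(m)) {
      out[idx] <- plogis(linpred(
        object$baseline$coefficients,
        distance_basis(newdata$distance_km[idx], newdata$gradient_pct[idx])))
    } else {
      out[idx] <- plogis(linpred(m$coefficients, nm_design(newdata[idx, ])))
    }
  }
  out
}

#' Cycling propensity of no-fixed-workplace commuters in a zone
#'
#' The commuter-weighted mean predicted propensity over the zone's fixed
#' sub-30 km commuters. Zones without any such commuter fall back to the
#' regional mean (and to the national mean if the region is empty), with a
#' message.
#'
#' @param zone_id Home zone.
#' @param population A `cyclehia_population`.
#' @param model A fitted propensity model.
#' @return A single probability.
#' @export
no_fixed_workplace_propensity <- function(zone_id, population, model) {
  cm <- population$commuters
  eligible <- cm$dest_type == "fixed" & !cm$far & cm$distance_km < 30
  sel <- eligible & cm$zone_id == zone_id
  if (!any(sel)) {
    region <- population$zones$region[population$zones$zone_id == zone_id]
    sel <- eligible & cm$region == region
    if (!any(sel)) {
      message("zone ", zone_id, ": no fixed-workplace commuters in zone or ",
              "region; using national mean propensity")
      sel <- eligible
    } else {
      message("zone ", zone_id, ": no fixed-workplace commuters; ",
              "using regional mean propensity")
    }
  }
  mean(predict(model, cm[sel, ]))
}

#' Per-commuter baseline cycling propensity
#'
#' Fixed-workplace sub-30 km commuters get an individual model prediction;
#' no-fixed-workplace commuters get their home zone's commuter-weighted mean
#' propensity; 30 km+/overseas commuters get 0 (no uptake).
#'
#' @param population A `cyclehia_population`.
#' @param model A fitted propensity model.
#' @return Numeric vector aligned with `population$commuters`.
#' @export
commuter_propensity <- function(population, model) {
  cm <- population$commuters
  out <- numeric(nrow(cm))
  fixed <- cm$dest_type == "fixed" & !cm$far & cm$distance_km < 30
  out[fixed] <- predict(model, cm[fixed, ])
  nf <- which(cm$dest_type == "no_fixed")
  if (length(nf) > 0) {
    zp <- vapply(unique(cm$zone_id[nf]), no_fixed_workplace_propensity,
                 numeric(1), population = population, model = model)
    out[nf] <- zp[cm$zone_id[nf]]
  }
  out
}

#' Serialise fitted models to a plain-text coefficient table
#'
#' One row per (stratum, term) with estimate and standard error; the pooled
#' baseline model uses stratum `"baseline"`.
#'
#' @param model A `baseline_model` or `near_market_models`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_models <- function(model, path) {
  row <- function(stratum, fit) {
    tibble::tibble(stratum = stratum, term = names(fit$coefficients),
                   estimate = unname(fit$coefficients),
                   se = unname(fit$se))
  }
  tab <- if (inherits(model, "baseline_model")) {
    row("baseline", model)
  } else {
    dplyr::bind_rows(
      row("baseline", model$baseline),
      dplyr::bind_rows(lapply(names(model$models), function(k) {
        row(k, model$models[[k]])
      }))
    )
  }
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
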