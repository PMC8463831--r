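# Gradient-dependent speed and intensity (mMET/h) for cycling, walking and
# e-biking, and the weekly physical-activity dose of a mode switcher.
#
# A route with mean uphill gradient g% is modelled as two equal-distance legs:
# one climbing at g (speed reduced by the sqrt-incline decay), one descending,
# with descending speed and energy expenditure taken equal to riding on the
# flat. Route-level speed and intensity are time-weighted over the two legs.

#' Activity model parameters
#'
#' Constants of the cycling power/speed model and the walking and e-bike
#' adjustment rules. The defaults are effective values calibrated jointly so
#' that, under the default commuter gradient distribution
#' ([default_gradient_dist()]), the model reproduces four route-level anchors:
#' route-average speed 13.9 km/h and intensity 5.39 mMET at a 1.5% mean
#' gradient, a population-mean walking intensity of 3.6 mMET, and a
#' population-mean e-bike intensity of 3.5 mMET. `a_roll` and `m_grav` are
#' calibrated coefficients of the power equation, not measured physical
#' quantities.
#'
#' @param v_flat Flat-ground cycling speed, km/h.
#' @param speed_decay Uphill speed decay per sqrt(percent incline), km/h.
#' @param a_roll Static (rolling + drivetrain) resistance coefficient, N.
#' @param b_air Aerodynamic resistance coefficient, N s^2 m^-2.
#' @param m_grav Effective gravity mass coefficient, kg.
#' @param efficiency Gross mechanical efficiency converting metabolic to
#'   propulsive power, dimensionless in (0, 1).
#' @param resting_watts Resting metabolic rate (1 MET), W.
#' @param min_speed Floor on uphill speed, km/h.
#' @param ebike_flat_reduction Reduction in flat-ground intensity on an
#'   e-bike, mMET.
#' @param ebike_hill_relief Fraction of the extra uphill effort remaining on
#'   an e-bike (0.5 = halved).
#' @param ebike_speed_relief Fraction of the uphill speed penalty remaining
#'   on an e-bike.
#' @param walk_flat_speed Flat-ground walking speed, km/h.
#' @param walk_target_mmet Population-mean walking intensity the calibration
#'   targets, mMET.
#' @return A list of class `activity_params`.
#' @export
activity_params <- function(v_flat = 15,
                            speed_decay = 1.67356442053509,
                            a_roll = 18.1502342027295,
                            b_air = 0.3125,
                            m_grav = 14.1100855102816,
                            efficiency = 0.20,
                            resting_watts = 80,
                            min_speed = 4,
                            ebike_flat_reduction = 1.8,
                            ebike_hill_relief = 0.5,
                            ebike_speed_relief = 0.5,
                            walk_flat_speed = 4.8,
                            walk_target_mmet = 3.6) {
  stopifnot(v_flat > 0, speed_decay >= 0, min_speed > 0,
            efficiency > 0, efficiency < 1, resting_watts > 0,
            ebike_hill_relief >= 0, ebike_hill_relief <= 1,
            ebike_speed_relief >= 0, ebike_speed_relief <= 1,
            walk_flat_speed > 0, walk_target_mmet > 0)
  structure(list(
    v_flat = v_flat, speed_decay = speed_decay,
    a_roll = a_roll, b_air = b_air, m_grav = m_grav,
    efficiency = efficiency, resting_watts = resting_watts,
    min_speed = min_speed,
    ebike_flat_reduction = ebike_flat_reduction,
    ebike_hill_relief = ebike_hill_relief,
    ebike_speed_relief = ebike_speed_relief,
    walk_flat_speed = walk_flat_speed,
    walk_target_mmet = walk_target_mmet
  ), class = "activity_params")
}

#' Default commuter gradient distribution
#'
#' Truncated normal on \[0, 5\]% with mean 1.9% (the urban-weighted mean route
#' hilliness among sub-30 km commutes) and sd 1.0. Used to calibrate the
#' walking and e-bike intensity rules and as the reference distribution for
#' population-mean intensities.
#'
#' @return List with `mean`, `sd`, `lo`, `hi`.
#' @export
default_gradient_dist <- function() {
  list(mean = 1.9, sd = 1.0, lo = 0, hi = 5)
}

#' Quadrature grid over a truncated-normal gradient distribution
#'
#' @param dist A distribution as returned by [default_gradient_dist()].
#' @param n Number of grid points.
#' @return List with gradients `g` and normalised weights `w`.
#' @export
gradient_quadrature <- function(dist = default_gradient_dist(), n = 2001) {
  g <- seq(dist$lo, dist$hi, length.out = n)
  w <- dnorm(g, dist$mean, dist$sd)
  list(g = g, w = w / sum(w))
}

ms <- function(v_kmh) v_kmh / 3.6

#' Cycling power demand
#'
#' Power to propel a bicycle at speed `v_kmh` on slope `gradient_pct`:
#' `(a + b v^2) v + m g0 v s`, with `s = gradient_pct / 100` and
#' `g0 = 9.81 m/s^2` (road resistance, wind resistance, gravity).
#'
#' @param v_kmh Speed, km/h.
#' @param gradient_pct Slope, percent (rise/run * 100).
#' @param params [activity_params()].
#' @return Watts.
#' @export
cycling_power <- function(v_kmh, gradient_pct, params = activity_params()) {
  v <- ms(v_kmh)
  (params$a_roll + params$b_air * v^2) * v +
    params$m_grav * 9.81 * v * (gradient_pct / 100)
}

power_to_mmet <- function(watts, params) {
  watts / (params$efficiency * params$resting_watts) - 1
}

#' Uphill cycling speed
#'
#' `v_flat - k * sqrt(gradient)`, floored at `min_speed` (with a warning if
#' the floor binds).
#'
#' @inheritParams cycling_power
#' @return km/h.
#' @export
uphill_speed <- function(gradient_pct, params = activity_params()) {
  stopifnot(all(gradient_pct >= 0))
  v <- params$v_flat - params$speed_decay * sqrt(gradient_pct)
  if (any(v < params$min_speed)) {
    warning("uphill speed floored at ", params$min_speed, " km/h")
    v <- pmax(v, params$min_speed)
  }
  v
}

#' Route-average cycling speed
#'
#' Combines one leg climbing at [uphill_speed()] and one leg at flat speed
#' over equal distances, i.e. the harmonic (time-weighted) mean of the two
#' leg speeds. Strictly decreasing in gradient.
#'
#' @inheritParams cycling_power
#' @return km/h.
#' @export
cycling_speed <- function(gradient_pct, params = activity_params()) {
  vu <- uphill_speed(gradient_pct, params)
  vf <- params$v_flat
  2 * vu * vf / (vu + vf)
}

# Leg intensities. The climbing leg sustains the flat-ground propulsive power
# and adds the gravity work done at the (reduced) climbing speed; descending
# is taken equal to riding on the flat.
flat_mmet <- function(params) {
  power_to_mmet(cycling_power(params$v_flat, 0, params), params)
}

uphill_mmet <- function(gradient_pct, params) {
  vu <- uphill_speed(gradient_pct, params)
  p <- cycling_power(params$v_flat, 0, params) +
    params$m_grav * 9.81 * ms(vu) * (gradient_pct / 100)
  power_to_mmet(p, params)
}

route_average <- function(x_up, x_flat, v_up, v_flat) {
  tu <- 1 / v_up
  tf <- 1 / v_flat
  (tu * x_up + tf * x_flat) / (tu + tf)
}

#' Route-average cycling intensity
#'
#' Time-weighted mean of the climbing-leg and flat-leg intensities; strictly
#' increasing in gradient. At a 1.5% mean gradient the defaults give
#' 5.39 mMET.
#'
#' @inheritParams cycling_power
#' @return mMET (MET above rest).
#' @export
cycling_mmet <- function(gradient_pct, params = activity_params()) {
  stopifnot(all(gradient_pct >= 0))
  vu <- uphill_speed(gradient_pct, params)
  route_average(uphill_mmet(gradient_pct, params), flat_mmet(params),
                vu, params$v_flat)
}

#' Walking intensity base calibrated to the population mean
#'
#' Walking uphill effort is assumed directly proportional to the relative
#' uphill effort of cycling; the flat-ground base is solved in closed form so
#' that the gradient-weighted mean walking intensity over `quad` equals
#' `params$walk_target_mmet` (3.6 mMET by default).
#'
#' @param params [activity_params()].
#' @param quad Gradient quadrature from [gradient_quadrature()].
#' @return Flat-ground walking intensity, mMET.
#' @export
walking_base_mmet <- function(params = activity_params(),
                              quad = gradient_quadrature()) {
  rel <- cycling_mmet(quad$g, params) / flat_mmet(params)
  base <- params$walk_target_mmet / sum(quad$w * rel)
  if (!is.finite(base) || base <= 0) {
    stop("walking intensity calibration failed: no positive base")
  }
  base
}

#' Walking intensity
#'
#' @inheritParams cycling_power
#' @param base Flat-ground walking intensity; defaults to the calibrated
#'   [walking_base_mmet()].
#' @return mMET.
#' @export
walking_mmet <- function(gradient_pct, params = activity_params(),
                         base = walking_base_mmet(params)) {
  stopifnot(all(gradient_pct >= 0))
  base * cycling_mmet(gradient_pct, params) / flat_mmet(params)
}

#' Walking route speed
#'
#' The relative uphill speed penalty of walking is taken proportional to that
#' of cycling.
#'
#' @inheritParams cycling_power
#' @return km/h.
#' @export
walking_speed <- function(gradient_pct, params = activity_params()) {
  params$walk_flat_speed * cycling_speed(gradient_pct, params) / params$v_flat
}

#' E-bike intensity
#'
#' Flat-ground e-biking is `ebike_flat_reduction` (1.8) mMET below
#' conventional cycling, and the additional effort of riding uphill is
#' multiplied by `ebike_hill_relief` (0.5). With default parameters the
#' population-mean e-bike intensity over [default_gradient_dist()] is
#' 3.5 mMET.
#'
#' @inheritParams cycling_power
#' @return mMET (floored at 0, with a warning if the floor binds).
#' @export
ebike_mmet <- function(gradient_pct, params = activity_params()) {
  stopifnot(all(gradient_pct >= 0))
  cf <- flat_mmet(params)
  ef <- cf - params$ebike_flat_reduction
  out <- ef + params$ebike_hill_relief * (cycling_mmet(gradient_pct, params) - cf)
  if (any(out < 0)) {
    warning("e-bike intensity floored at 0 mMET")
    out <- pmax(out, 0)
  }
  out
}

#' E-bike route speed
#'
#' As [cycling_speed()], with the uphill speed penalty attenuated by
#' `ebike_speed_relief`.
#'
#' @inheritParams cycling_power
#' @return km/h.
#' @export
ebike_speed <- function(gradient_pct, params = activity_params()) {
  stopifnot(all(gradient_pct >= 0))
  vu <- pmax(params$min_speed,
             params$v_flat -
               params$ebike_speed_relief * params$speed_decay * sqrt(gradient_pct))
  2 * vu * params$v_flat / (vu + params$v_flat)
}

#' Default cycle-commute trips per cyclist per week
#'
#' One-way commute stages cycled per cyclist per week, by sex and age band,
#' declining with age and slightly lower for women; the commuter-weighted
#' mean is about 5.
#'
#' @return Tibble with `sex`, `age_band`, `trips_per_week`.
#' @export
default_trips_per_week <- function() {
  tibble::tibble(
    sex = rep(c("male", "female"), each = 6),
    age_band = rep(age_band_levels(), 2),
    trips_per_week = c(5.6, 5.8, 5.6, 5.2, 4.6, 4.0,
                       5.2, 5.4, 5.2, 4.8, 4.2, 3.6)
  )
}

#' Weekly physical-activity dose of a switch to cycling
#'
#' Dose gained = trips/week x one-way duration (distance / route speed) x
#' route intensity. Ex-walkers are debited the walking dose the switch
#' displaces, computed the same way with walking speed and intensity; other
#' former modes displace no physical activity.
#'
#' @param distance_km Route distance, km (vector).
#' @param gradient_pct Mean uphill route gradient, percent (vector).
#' @param trips_per_week Cycle-commute trips per week (vector).
#' @param former_mode Former commute mode (vector; `"walk"` triggers the
#'   displacement debit).
#' @param params [activity_params()].
#' @param cycle_mode `"bike"` or `"ebike"` (the E-bikes scenario).
#' @param walk_base Calibrated walking base intensity.
#' @return Tibble with `mmeth_gain`, `mmeth_displaced` (<= 0), `mmeth_net`.
#' @export
weekly_dose <- function(distance_km, gradient_pct, trips_per_week,
                        former_mode, params = activity_params(),
                        cycle_mode = c("bike", "ebike"),
                        walk_base = walking_base_mmet(params)) {
  cycle_mode <- match.arg(cycle_mode)
  stopifnot(all(distance_km > 0), all(gradient_pct >= 0),
            all(trips_per_week >= 0))
  if (cycle_mode == "bike") {
    v <- cycling_speed(gradient_pct, params)
    intensity <- cycling_mmet(gradient_pct, params)
  } else {
    v <- ebike_speed(gradient_pct, params)
    intensity <- ebike_mmet(gradient_pct, params)
  }
  gain <- trips_per_week * (distance_km / v) * intensity
  disp <- ifelse(
    former_mode == "walk",
    -trips_per_week * (distance_km / walking_speed(gradient_pct, params)) *
      walking_mmet(gradient_pct, params, walk_base),
    0
  )
  tibble::tibble(mmeth_gain = gain, mmeth_displaced = disp,
                 mmeth_net = gain + disp)
}

#' Speed and intensity table by mode and gradient
#'
#' Regression-test style table of route speed (km/h) and intensity (mMET) for
#' cycling, walking and e-biking over a gradient grid.
#'
#' @param params [activity_params()].
#' @param gradients Gradient grid, percent.
#' @return Tibble.
#' @export
activity_table <- function(params = activity_params(),
                           gradients = seq(0, 5, by = 0.1)) {
  wb <- walking_base_mmet(params)
  tibble::tibble(
    gradient_pct = gradients,
    cycle_speed_kmh = cycling_speed(gradients, params),
    cycle_mmet = cycling_mmet(gradients, params),
    walk_speed_kmh = walking_speed(gradients, params),
    walk_mmet = walking_mmet(gradients, params, wb),
    ebike_speed_kmh = ebike_speed(gradients, params),
    ebike_mmet = ebike_mmet(gradients, params)
  )
}
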