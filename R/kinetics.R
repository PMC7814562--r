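# Two-pool transport kinetics with diurnally modulated uptake rate.
#
# The tracer model is dA_leaf/dt = k(t) * A_pool(t) with
# A_pool = A_total - A_leaf and A_leaf(0) = 0, where k(t) is piecewise
# constant over light/dark intervals. The exact solution is
#   A_leaf(t) = A_total * (1 - exp(-K(t))),  K(t) = integral of k over [0, t],
# and K accumulates in closed form over the light/dark segments.

#' Sodium-22 physical decay constants
#'
#' Half-life 2.605 years, with one year taken as 8766 h (365.25 days).
#' @name na22
NULL

NA22_HALF_LIFE_Y <- 2.605
HOURS_PER_YEAR <- 8766

#' Physical decay factor
#'
#' Fraction of activity remaining after `t_h` hours for a nuclide with the
#' given half-life: `2^(-t_h / (half_life_y * 8766 h))`.
#'
#' @param t_h elapsed time in hours (vectorised).
#' @param half_life_y half-life in years; defaults to sodium-22 (2.605 y).
#' @return Numeric vector of decay factors in (0, 1].
#' @export
decay_factor <- function(t_h, half_life_y = NA22_HALF_LIFE_Y) {
  if (half_life_y <= 0) stop_("decay_factor: half-life must be positive")
  2^(-t_h / (half_life_y * HOURS_PER_YEAR))
}

#' Kinetic parameters of one plant grouping
#'
#' The uptake rate applied at time t is
#' `k_base * f_nutrient * f_inhibitor * (1 +/- a_diurnal)`, the sign chosen
#' by whether the *anticipated* clock `t + phase_advance` falls in a light
#' interval of the schedule. `f_nutrient > 1` encodes the faster sodium
#' uptake of nutrient-deprived plants; `f_inhibitor < 1` encodes suppression
#' by a cation-channel blocker such as barium chloride; `phase_advance > 0`
#' makes the plant adjust its rate ahead of the actual light transition.
#'
#' @param k_base base uptake-rate constant, per hour; >= 0.
#' @param f_nutrient dimensionless nutrient multiplier, > 0.
#' @param f_inhibitor dimensionless inhibitor multiplier, > 0.
#' @param a_diurnal light-modulation amplitude in `[0, 1)`.
#' @param phase_advance hours by which the rate transition anticipates the
#'   light transition; >= 0.
#' @param A_total administered activity, MBq; > 0.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_base, f_nutrient = 1, f_inhibitor = 1,
                           a_diurnal = 0, phase_advance = 0, A_total = 1) {
  if (k_base < 0) stop_("kinetic_params: k_base must be >= 0")
  if (f_nutrient <= 0 || f_inhibitor <= 0)
    stop_("kinetic_params: treatment factors must be > 0")
  if (a_diurnal < 0 || a_diurnal >= 1)
    stop_("kinetic_params: a_diurnal must lie in [0, 1)")
  if (phase_advance < 0) stop_("kinetic_params: phase_advance must be >= 0")
  if (A_total <= 0) stop_("kinetic_params: A_total must be > 0")
  structure(list(k_base = k_base, f_nutrient = f_nutrient,
                 f_inhibitor = f_inhibitor, a_diurnal = a_diurnal,
                 phase_advance = phase_advance, A_total = A_total),
            class = "kinetic_params")
}

#' Light schedule
#'
#' Periodic light/dark cycle: light for `period_light` hours starting at
#' `t0`, then dark for `period_dark` hours, repeating. The periods need not
#' sum to 24 h (a 12 h light / 8 h dark growth-chamber cycle has a 20-h
#' period and is represented verbatim).
#'
#' @param period_light hours of light per cycle; > 0.
#' @param period_dark hours of dark per cycle; > 0.
#' @param t0 start of the first light interval, hours.
#' @return An object of class `light_schedule`.
#' @export
light_schedule <- function(period_light = 12, period_dark = 8, t0 = 0) {
  if (period_light <= 0 || period_dark <= 0)
    stop_("light_schedule: both periods must be > 0")
  structure(list(period_light = period_light, period_dark = period_dark,
                 t0 = t0), class = "light_schedule")
}

#' Is a time point in a light interval?
#'
#' @param t hours (vectorised).
#' @param light a [light_schedule()].
#' @return Logical vector; `TRUE` where `t` falls in light.
#' @export
is_light <- function(t, light) {
  period <- light$period_light + light$period_dark
  ((t - light$t0) %% period) < light$period_light
}

#' Uptake rate at a time point
#'
#' Evaluates the piecewise-constant rate
#' `k(t) = k_base * f_nutrient * f_inhibitor * (1 + a_diurnal)` when the
#' shifted clock `t + phase_advance` is in light, and with `(1 - a_diurnal)`
#' otherwise.
#'
#' @param t hours since administration (vectorised); >= 0.
#' @param params a [kinetic_params()].
#' @param light a [light_schedule()].
#' @return Numeric vector of rates, per hour.
#' @export
uptake_rate_at <- function(t, params, light) {
  k0 <- params$k_base * params$f_nutrient * params$f_inhibitor
  lit <- is_light(t + params$phase_advance, light)
  k0 * (1 + ifelse(lit, params$a_diurnal, -params$a_diurnal))
}

# Exact integral of the piecewise-constant rate over [0, t_end], accumulated
# segment by segment between light/dark breakpoints of the shifted clock.
rate_integral <- function(t_end, params, light) {
  if (t_end <= 0) return(0)
  period <- light$period_light + light$period_dark
  base <- light$t0 - params$phase_advance
  m <- seq(floor((0 - base) / period) - 1, ceiling((t_end - base) / period) + 1)
  cand <- sort(c(base + m * period, base + light$period_light + m * period))
  bp <- c(0, cand[cand > 1e-12 & cand < t_end - 1e-12], t_end)
  mids <- (bp[-1] + bp[-length(bp)]) / 2
  k <- uptake_rate_at(mids, params, light)
  sum(k * diff(bp))
}

#' Simulate two-pool tracer kinetics for one plant grouping
#'
#' Solves `dA_leaf/dt = k(t) * A_pool`, `A_pool = A_total - A_leaf`,
#' `A_leaf(0) = 0` exactly via the closed form
#' `A_leaf(t) = A_total * (1 - exp(-K(t)))` with `K(t)` the rate integral
#' accumulated over light/dark segments. Values are reported at frame
#' midpoints and are *undecayed* physical amounts: radioactive decay is a
#' property of the rendered image, applied at render time, so
#' `A_pool + A_leaf = A_total` holds exactly at every frame.
#'
#' @param params a [kinetic_params()].
#' @param frames a [frame_schedule()].
#' @param light a [light_schedule()].
#' @return An object of class `compartment_series`: list with `t` (frame
#'   midpoints, h), `A_pool`, `A_leaf` (MBq), `k_true` (rate applied at each
#'   midpoint, per hour), `A_total` and `params`.
#' @export
simulate_kinetics <- function(params, frames, light) {
  t <- frame_midpoints(frames)
  K <- vapply(t, rate_integral, numeric(1), params = params, light = light)
  A_leaf <- params$A_total * (1 - exp(-K))
  structure(list(t = t,
                 A_pool = params$A_total - A_leaf,
                 A_leaf = A_leaf,
                 k_true = uptake_rate_at(t, params, light),
                 A_total = params$A_total,
                 params = params),
            class = "compartment_series")
}

#' @export
print.compartment_series <- function(x, ...) {
  cat(sprintf("<compartment_series> %d frames, A_total %.4g MBq, final leaf fraction %.3f\n",
              length(x$t), x$A_total, x$A_leaf[length(x$A_leaf)] / x$A_total))
  invisible(x)
}
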