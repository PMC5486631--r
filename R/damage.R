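# Arrhenius first-order thermal damage: Omega(t) = A int exp(-E/(R T)) dt
# with T in kelvin, and the derived kill probability
# P(%) = 100 (1 - exp(-Omega)).

DAMAGE_PRESETS <- list(
  protein_coagulation = c(a_factor = 7.39e39, e_activation = 2.577e5),
  microvascular_stasis = c(a_factor = 1.98e106, e_activation = 6.67e5),
  cell_death = c(a_factor = 2.984e80, e_activation = 5.064e5))

#' Arrhenius damage kinetics
#'
#' Named presets for protein coagulation (the default damage process),
#' microvascular blood-flow stasis and cell death, or custom kinetics via
#' `a_factor` / `e_activation`.
#'
#' @param process preset name.
#' @param a_factor pre-exponential factor A (1/s); overrides the preset.
#' @param e_activation activation energy E (J/mol); overrides the preset.
#' @param r_gas universal gas constant (J mol^-1 K^-1).
#' @return object of class `damage_params`.
#' @export
damage_params <- function(process = c("protein_coagulation",
                                      "microvascular_stasis", "cell_death"),
                          a_factor = NULL, e_activation = NULL,
                          r_gas = 8.314) {
  process <- match.arg(process)
  p <- DAMAGE_PRESETS[[process]]
  a <- if (is.null(a_factor)) p[["a_factor"]] else a_factor
  e <- if (is.null(e_activation)) p[["e_activation"]] else e_activation
  if (a <= 0) validation_error("a_factor", "must be positive")
  if (e <= 0) validation_error("e_activation", "must be positive")
  structure(list(process = process, a_factor = a, e_activation = e,
                 r_gas = r_gas), class = "damage_params")
}

#' Arrhenius damage rate at a temperature
#'
#' `A exp(-E / (R (T + 273.15)))`, the integrand of the damage integral.
#'
#' @param temperature temperature in degC (vectorised).
#' @param params a [damage_params()].
#' @return damage accumulation rate (1/s).
#' @export
arrhenius_rate <- function(temperature, params = damage_params()) {
  stopifnot(all(temperature > -273.15))
  params$a_factor *
    exp(-params$e_activation / (params$r_gas * (temperature + 273.15)))
}

#' Integrate the Arrhenius damage over a temperature history
#'
#' Trapezoidal accumulation of [arrhenius_rate()] over a strictly
#' increasing time sequence, per voxel.
#'
#' @param times strictly increasing times (s).
#' @param temperatures matrix with one row per voxel and one column per
#'   time (or a vector for a single voxel).
#' @param params a [damage_params()].
#' @return object of class `damage_field`: accumulated `omega` per voxel
#'   and the time reached.
#' @export
integrate_damage <- function(times, temperatures, params = damage_params()) {
  if (is.null(dim(temperatures)))
    temperatures <- matrix(temperatures, nrow = 1)
  if (length(times) != ncol(temperatures))
    fail("pulseheat_input_error",
         "need one temperature column per time point")
  if (length(times) > 1 && any(diff(times) <= 0))
    fail("pulseheat_input_error", "times must be strictly increasing")
  state <- new_damage_state(params, nrow(temperatures))
  for (j in seq_along(times))
    state <- accumulate_damage(state, times[j], temperatures[, j])
  structure(list(omega = state$omega, t = state$t), class = "damage_field")
}

#' Streaming damage accumulator
#'
#' `new_damage_state()` initialises a per-voxel accumulator;
#' [accumulate_damage()] folds in one time point at a time. Streaming
#' accumulation equals batch [integrate_damage()] on the same
#' discretisation.
#'
#' @param params a [damage_params()].
#' @param n_voxels number of voxels tracked.
#' @return accumulator state (list with `omega`, `rate_prev`, `t`).
#' @export
new_damage_state <- function(params = damage_params(), n_voxels = 1) {
  list(params = params, omega = numeric(n_voxels), rate_prev = NULL, t = NA)
}

#' @rdname new_damage_state
#' @param state accumulator from `new_damage_state()`.
#' @param t time of this sample (s); must exceed the previous time.
#' @param temperature per-voxel temperatures at `t` (degC).
#' @export
accumulate_damage <- function(state, t, temperature) {
  rate <- arrhenius_rate(temperature, state$params)
  if (!is.null(state$rate_prev)) {
    if (t <= state$t)
      fail("pulseheat_input_error", "times must be strictly increasing")
    state$omega <- state$omega + 0.5 * (t - state$t) * (state$rate_prev + rate)
  }
  state$rate_prev <- rate
  state$t <- t
  state
}

#' Kill probability from accumulated damage
#'
#' `P(%) = 100 (1 - exp(-Omega))`: Omega = 1 corresponds to 63%
#' probability of cell death and Omega = 4.6 to 99%.
#'
#' @param omega accumulated damage (dimensionless, non-negative).
#' @return percentage in `[0, 100)`.
#' @export
kill_probability <- function(omega) {
  if (any(omega < 0))
    fail("pulseheat_input_error", "omega must be non-negative")
  100 * (1 - exp(-omega))
}

#' Classify damage against the standard thresholds
#'
#' Labels each voxel: `below_threshold` for Omega < 0.53 (the thermal
#' damage threshold), `damaged` for 0.53 <= Omega < 1, `p63` for
#' 1 <= Omega < 4.6 and `p99` for Omega >= 4.6. Boundaries are inclusive
#' upward.
#'
#' @param omega accumulated damage (vectorised, non-negative).
#' @return factor with levels `below_threshold`, `damaged`, `p63`, `p99`.
#' @export
classify_damage <- function(omega) {
  if (any(omega < 0))
    fail("pulseheat_input_error", "omega must be non-negative")
  cut(omega, breaks = c(-Inf, 0.53, 1, 4.6, Inf), right = FALSE,
      labels = c("below_threshold", "damaged", "p63", "p99"))
}
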