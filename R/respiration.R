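#' Arrhenius temperature factor
#'
#' Evaluates `pre_exp * exp(-ea / (rg * (temp_c + kelvin_offset)))`, the
#' temperature-dependent rate shared by both respiration terms. Strictly
#' increasing in temperature for `ea > 0`. Vectorised over `temp_c`.
#'
#' @param pre_exp Pre-exponential factor (same unit as the returned rate).
#' @param ea Activation energy (J mol-1), non-negative.
#' @param temp_c Temperature (deg C).
#' @param kelvin_offset Celsius-to-Kelvin offset; 273 by default because the
#'   kinetic constants were fitted with `T + 273` (see [ma_constants()]).
#' @return Rate in the unit of `pre_exp`.
#' @export
#' @examples
#' arrhenius_factor(2.76e17, 8.63e4, 10)  # ~32.5 mL kg-1 h-1
arrhenius_factor <- function(pre_exp, ea, temp_c,
                             kelvin_offset = ma_constants()$kelvin_offset) {
  if (!all(is.finite(c(pre_exp, ea, temp_c)))) {
    stop("arrhenius_factor() requires finite inputs", call. = FALSE)
  }
  if (pre_exp <= 0) stop("pre_exp must be positive", call. = FALSE)
  if (ea < 0) stop("ea must be non-negative", call. = FALSE)
  pre_exp * exp(-ea / (ma_constants()$rg * (temp_c + kelvin_offset)))
}

#' Specific respiration rate of the produce
#'
#' O2 uptake per kilogram: a Michaelis-Menten term in O2 with
#' uncompetitive-style CO2 inhibition, plus a residual low-O2 term, both
#' Arrhenius-scaled:
#' \deqn{r = \frac{V_{max}(T)\,O_2}{k_m + (1 + CO_2/k_i)\,O_2} + R_{min}(T)}
#' where \eqn{V_{max}(T)} and \eqn{R_{min}(T)} are [arrhenius_factor()]
#' evaluations of the two pre-exponential factors. The rate increases with
#' O2 and temperature and decreases with CO2.
#'
#' @param p [respiration_params()].
#' @param g [gas_conditions()].
#' @return O2 uptake rate, mL kg-1 h-1.
#' @export
#' @examples
#' respiration_specific(respiration_params(), gas_conditions(3, 15, 10))
respiration_specific <- function(p, g) {
  stopifnot(inherits(p, "respiration_params"), inherits(g, "gas_conditions"))
  vmax <- arrhenius_factor(p$r_max_pre, p$ea_max, g$temp_c)
  rmin <- arrhenius_factor(p$r_min_pre, p$ea_min, g$temp_c)
  vmax * g$o2 / (p$km + (1 + g$co2 / p$ki) * g$o2) + rmin
}

#' Whole-box respiration rate
#'
#' Scales the specific rate by the product weight. `respiration_box()`
#' reports mL per hour; `respiration_box_s()` reports the same quantity in
#' mL per second (the two differ by exactly 3600 — the controller uses both
#' forms).
#'
#' @inheritParams respiration_specific
#' @param wp Product weight (kg), strictly positive.
#' @return O2 uptake of the whole box, mL h-1 (or mL s-1).
#' @export
respiration_box <- function(p, g, wp) {
  if (!is.finite(wp) || wp <= 0) stop("wp must be a positive weight in kg", call. = FALSE)
  respiration_specific(p, g) * wp
}

#' @rdname respiration_box
#' @export
respiration_box_s <- function(p, g, wp) {
  respiration_box(p, g, wp) / ma_constants()$seconds_per_hour
}

# fast kernel used by the simulator and the vectorised sensitivity paths:
# specific respiration from raw numbers, no object dispatch.
resp_rate_raw <- function(r_max_pre, ea_max, r_min_pre, ea_min, km, ki,
                          o2, co2, temp_c, rg = 8.314, koff273 = 273) {
  tk <- temp_c + koff273
  vmax <- r_max_pre * exp(-ea_max / (rg * tk))
  rmin <- r_min_pre * exp(-ea_min / (rg * tk))
  vmax * o2 / (km + (1 + co2 / ki) * o2) + rmin
}
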