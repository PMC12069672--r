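#' Blower-ON frequency (BOF) for one control cycle
#'
#' Seconds per cycle the blower must run so that forced plus passive O2
#' supply balances the respiratory O2 demand at the operating point
#' (`o2_set`, `co2_ref`, current temperature):
#' \deqn{BOF = \frac{D - c\,r_{off}}{r_{on} - r_{off}}}
#' where `D` is the whole-box respiration demand (mL per cycle of length
#' `c` seconds) and `r_on`, `r_off` are the forced and passive exchange
#' rates (mL s-1) evaluated at the set point. The controller is
#' feed-forward: it uses only temperature, never a measured O2. The result
#' is clamped to `[0, cycle_s]` and the `clamped` flag records saturation.
#'
#' @param p [respiration_params()].
#' @param geom [box_geometry()].
#' @param diff [diffusion_params()].
#' @param ctl [control_settings()].
#' @param temp_c Product temperature (deg C).
#' @return An object of class `bof_result`: list with `bof_s`,
#'   `demand_ml_h`, `natural_supply_ml_h`, `on_rate_ml_s`, `off_rate_ml_s`,
#'   `clamped`, `temp_c`.
#' @export
#' @examples
#' compute_bof(respiration_params(), box_geometry(), diffusion_params(),
#'             control_settings(), temp_c = 10)  # ~48 s
compute_bof <- function(p, geom, diff, ctl, temp_c) {
  stopifnot(inherits(ctl, "control_settings"), inherits(diff, "diffusion_params"),
            inherits(geom, "box_geometry"))
  g <- gas_conditions(ctl$o2_set, ctl$co2_ref, temp_c)
  demand_h <- respiration_box(p, g, geom$wp)             # mL h-1
  r_on <- exchange_rate(diff$k_on, ctl$o2_set)           # mL s-1
  r_off <- exchange_rate(diff$k_off, ctl$o2_set)
  if (r_on <= r_off) stop("degenerate controller: forced rate must exceed passive rate", call. = FALSE)
  cycle_s <- ctl$cycle_s
  demand_cycle <- demand_h * cycle_s / ma_constants()$seconds_per_hour  # mL per cycle
  bof <- (demand_cycle - cycle_s * r_off) / (r_on - r_off)
  clamped <- bof < 0 || bof > cycle_s
  bof <- min(max(bof, 0), cycle_s)
  structure(
    list(bof_s = bof,
         demand_ml_h = demand_h,
         natural_supply_ml_h = r_off * ma_constants()$seconds_per_hour,
         on_rate_ml_s = r_on,
         off_rate_ml_s = r_off,
         clamped = clamped,
         temp_c = temp_c),
    class = "bof_result"
  )
}

#' @export
print.bof_result <- function(x, ...) {
  cat(sprintf("BOF: %.2f s per cycle%s (T = %g degC)\n", x$bof_s,
              if (x$clamped) " [clamped]" else "", x$temp_c))
  cat(sprintf("  demand %.1f mL/h | natural supply %.1f mL/h | rates ON %.4g / OFF %.4g mL/s\n",
              x$demand_ml_h, x$natural_supply_ml_h, x$on_rate_ml_s, x$off_rate_ml_s))
  invisible(x)
}

# raw BOF kernel, vectorised over parameter draws (rows of named columns);
# same algebra as compute_bof() without object construction.
bof_raw <- function(R_max, Ea_max, R_min, Ea_min, k_m, k_i,
                    k_O2_ON, k_O2_OFF, W_p,
                    o2_set = 3, co2_ref = 15, cycle_s = 3600, temp_c = 10) {
  demand_h <- resp_rate_raw(R_max, Ea_max, R_min, Ea_min, k_m, k_i,
                            o2_set, co2_ref, temp_c) * W_p
  r_on <- k_O2_ON * (21 - o2_set) / 100 * 1e6
  r_off <- k_O2_OFF * (21 - o2_set) / 100 * 1e6
  bof <- (demand_h * cycle_s / 3600 - cycle_s * r_off) / (r_on - r_off)
  pmin(pmax(bof, 0), cycle_s)
}

#' Within-cycle blower actuation schedule
#'
#' Expands a BOF into the (phase, duration) segments of one control cycle.
#' The burst is contiguous; `position` places it at the start of the cycle
#' (firmware default) or at its end (the convention under which the blower
#' tops the box back up to the set point after the hour's consumption, used
#' by the simulator's default trajectory; see [sim_config()]).
#'
#' @param bof_s Blower-ON seconds, in `[0, cycle_s]`.
#' @param ctl [control_settings()].
#' @param position `"start"` or `"end"`.
#' @return Data frame with columns `phase` ("ON"/"OFF") and `duration_s`;
#'   durations sum to `cycle_s`, zero-length segments dropped.
#' @export
#' @examples
#' control_schedule(48, control_settings())
control_schedule <- function(bof_s, ctl, position = c("start", "end")) {
  stopifnot(inherits(ctl, "control_settings"))
  position <- match.arg(position)
  if (!is.finite(bof_s) || bof_s < 0 || bof_s > ctl$cycle_s) {
    stop("bof_s must lie in [0, cycle_s]", call. = FALSE)
  }
  segs <- if (position == "start") {
    data.frame(phase = c("ON", "OFF"),
               duration_s = c(bof_s, ctl$cycle_s - bof_s),
               stringsAsFactors = FALSE)
  } else {
    data.frame(phase = c("OFF", "ON"),
               duration_s = c(ctl$cycle_s - bof_s, bof_s),
               stringsAsFactors = FALSE)
  }
  segs[segs$duration_s > 0, , drop = FALSE]
}
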