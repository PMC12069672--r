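#' Piecewise-constant temperature profile
#'
#' @param duration_h Segment durations (h), strictly positive.
#' @param temp_c Segment temperatures (deg C), same length.
#' @return An object of class `temperature_profile`: data frame with
#'   `start_h`, `duration_h`, `temp_c`; attribute `total_h`.
#' @export
#' @examples
#' temperature_profile(c(8, 16), c(20, 5))
temperature_profile <- function(duration_h, temp_c) {
  if (length(duration_h) != length(temp_c) || length(duration_h) == 0) {
    stop("duration_h and temp_c must be non-empty and of equal length", call. = FALSE)
  }
  if (!all(is.finite(duration_h)) || any(duration_h <= 0)) {
    stop("segment durations must be positive and finite", call. = FALSE)
  }
  if (!all(is.finite(temp_c)) || any(temp_c < -30) || any(temp_c > 60)) {
    stop("segment temperatures must lie in [-30, 60] degC", call. = FALSE)
  }
  prof <- data.frame(
    start_h = cumsum(c(0, duration_h[-length(duration_h)])),
    duration_h = duration_h,
    temp_c = temp_c
  )
  attr(prof, "total_h") <- sum(duration_h)
  class(prof) <- c("temperature_profile", "data.frame")
  prof
}

#' Temperature lookup on a profile
#'
#' Half-open piecewise-constant lookup: segment `i` covers
#' `[start_h, start_h + duration_h)`. Times at or beyond the profile end
#' return the last segment's temperature.
#'
#' @param profile [temperature_profile()].
#' @param t_h Time(s) in hours, non-negative. Vectorised.
#' @return Temperature(s) in deg C.
#' @export
temp_at <- function(profile, t_h) {
  stopifnot(inherits(profile, "temperature_profile"))
  if (any(t_h < 0)) stop("t_h must be non-negative", call. = FALSE)
  ends <- cumsum(profile$duration_h)
  idx <- findInterval(t_h, c(0, ends), rightmost.closed = FALSE)
  idx <- pmin(idx, nrow(profile))
  profile$temp_c[idx]
}

#' Simulation configuration
#'
#' @param dt Euler time step (s), in (0, 60].
#' @param rq Respiratory quotient (mol CO2 per mol O2) used when
#'   `co2_mode = "dynamic"`.
#' @param co2_mode `"fixed"` holds CO2 at `co2_fixed` (the convention of the
#'   variability analyses); `"dynamic"` integrates CO2 with production
#'   `rq * respiration` and passive/forced efflux reusing the O2 exchange
#'   coefficients (exploratory only — the system has no measured CO2
#'   transport constants).
#' @param co2_fixed CO2 level (%) for the fixed mode.
#' @param pulldown If `TRUE` (default) the blower stays OFF until O2 first
#'   reaches the set point; if `FALSE` control cycles start at time zero.
#' @param control_kinetics Rate evaluation during the controlled phase.
#'   `"setpoint"` (default) evaluates respiration and exchange at the
#'   controller's operating point (`o2_set`, `co2_ref`), i.e. integrates the
#'   same linearised model the firmware embeds; this reproduces the
#'   predicted sawtooth whose peak returns to the set point after each
#'   burst. `"state"` evaluates both rates at the actual gas state (full
#'   mass balance); its limit cycle settles with mean near the set point and
#'   peak above it. See the methods vignette.
#' @param burst Placement of the contiguous blower burst within each cycle:
#'   `"end"` (default; the burst replaces the hour's consumption and tops
#'   the box back up to the set point) or `"start"`.
#' @param o2_init,co2_init Initial headspace gas (%); CO2 defaults to
#'   `co2_fixed` in fixed mode and ambient otherwise.
#' @param temp_noise_sd Gaussian noise (deg C, sd) added to the temperature
#'   read by the controller at each cycle; 0 disables (default).
#' @param seed Optional integer seed for the noise stream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1, rq = 1, co2_mode = c("fixed", "dynamic"),
                       co2_fixed = 15, pulldown = TRUE,
                       control_kinetics = c("setpoint", "state"),
                       burst = c("end", "start"),
                       o2_init = 21, co2_init = NULL,
                       temp_noise_sd = 0, seed = NULL) {
  co2_mode <- match.arg(co2_mode)
  control_kinetics <- match.arg(control_kinetics)
  burst <- match.arg(burst)
  if (!is.finite(dt) || dt <= 0 || dt > 60) stop("dt must lie in (0, 60] s", call. = FALSE)
  if (!is.finite(rq) || rq <= 0) stop("rq must be positive", call. = FALSE)
  if (o2_init < 0 || o2_init > 21) stop("o2_init must lie in [0, 21] %", call. = FALSE)
  if (is.null(co2_init)) {
    co2_init <- if (co2_mode == "fixed") co2_fixed else ma_constants()$co2_ambient
  }
  if (temp_noise_sd < 0) stop("temp_noise_sd must be non-negative", call. = FALSE)
  structure(list(dt = dt, rq = rq, co2_mode = co2_mode, co2_fixed = co2_fixed,
                 pulldown = pulldown, control_kinetics = control_kinetics,
                 burst = burst, o2_init = o2_init, co2_init = co2_init,
                 temp_noise_sd = temp_noise_sd, seed = seed),
            class = "sim_config")
}

#' Single Euler step of the headspace mass balance
#'
#' Advances the gas state by `dt` seconds with rates evaluated at the
#' actual state: O2 changes by exchange influx minus respiration,
#' expressed in percentage points of the free volume; CO2 follows the
#' configured mode. O2 is clipped to `[0, 21]`.
#'
#' @param state List with `o2`, `co2`, `temp_c`.
#' @param dt Step (s), positive.
#' @param blower_on Logical (or duty fraction in `[0, 1]`).
#' @param p,geom,diff,cfg Model objects ([respiration_params()],
#'   [box_geometry()], [diffusion_params()], [sim_config()]).
#' @return Updated state list (`o2`, `co2`, `temp_c`).
#' @export
step_gas <- function(state, dt, blower_on, p, geom, diff, cfg = sim_config()) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  duty <- as.numeric(blower_on)
  stopifnot(duty >= 0, duty <= 1)
  vf_ml <- free_volume(geom) * 1e6
  k_eff <- duty * diff$k_on + (1 - duty) * diff$k_off
  supply <- k_eff * (21 - state$o2) / 100 * 1e6 * dt
  respired <- resp_rate_raw(p$r_max_pre, p$ea_max, p$r_min_pre, p$ea_min,
                            p$km, p$ki, state$o2, state$co2, state$temp_c) *
    geom$wp * dt / 3600
  o2 <- state$o2 + (supply - respired) / vf_ml * 100
  o2 <- min(max(o2, 0), 21)
  co2 <- if (cfg$co2_mode == "fixed") {
    cfg$co2_fixed
  } else {
    efflux <- k_eff * (state$co2 - ma_constants()$co2_ambient) / 100 * 1e6 * dt
    min(max(state$co2 + (cfg$rq * respired - efflux) / vf_ml * 100, 0), 100)
  }
  list(o2 = o2, co2 = co2, temp_c = state$temp_c)
}

#' Simulate the controlled storage box over a temperature profile
#'
#' Time-stepped (explicit Euler) integration of the headspace O2 (and
#' optionally CO2) mass balance. The run starts at ambient (or
#' `cfg$o2_init`); during pulldown the blower is OFF and respiration is
#' evaluated at the actual state. When O2 first reaches the set point the
#' hourly control cycles begin: at each cycle boundary the BOF is recomputed
#' from the current temperature ([compute_bof()]) and a single contiguous
#' blower burst is applied per [sim_config()]'s `burst` placement.
#' Fractional burst lengths are integrated exactly (the boundary step uses
#' the partial duty fraction), so the per-cycle supply matches the BOF to
#' machine precision rather than to the step size.
#'
#' @param profile [temperature_profile()].
#' @param p,geom,diff,ctl,cfg Model objects; defaults are the broccoli base
#'   configuration.
#' @return An object of class `ma_trajectory`: list with
#'   \describe{
#'     \item{steps}{data frame `time_s`, `temp_c`, `o2`, `co2`, `duty`,
#'       `supplied_ml`, `respired_ml` (cumulative, one row per step end).}
#'     \item{cycles}{data frame of completed control cycles: `cycle`,
#'       `start_s`, `temp_c`, `bof_s`, `clamped`, `o2_min`, `o2_max`,
#'       `o2_mean`.}
#'     \item{pulldown_end_s}{time at which control became active (NA if
#'       never).}
#'     \item{clip_ml}{O2 volume discarded by clipping to `[0, 21]` (0 in
#'       normal operation).}
#'   }
#' @export
#' @examples
#' prof <- temperature_profile(3, 10)
#' cfg <- sim_config(dt = 30, o2_init = 3.2)
#' traj <- simulate_box(prof, cfg = cfg)
#' tail(traj$cycles)
simulate_box <- function(profile, p = respiration_params(),
                         geom = box_geometry(), diff = diffusion_params(),
                         ctl = control_settings(), cfg = sim_config()) {
  stopifnot(inherits(profile, "temperature_profile"), inherits(cfg, "sim_config"))
  dt <- cfg$dt
  cycle_s <- ctl$cycle_s
  if (abs(cycle_s / dt - round(cycle_s / dt)) > 1e-9) {
    stop("cycle_s must be an integer multiple of dt", call. = FALSE)
  }
  total_s <- attr(profile, "total_h") * 3600
  n <- floor(total_s / dt + 1e-9)
  if (n < 1) stop("profile shorter than one time step", call. = FALSE)
  if (total_s < cycle_s) warning("profile shorter than one control cycle")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  vf_ml <- free_volume(geom) * 1e6
  o2_set <- ctl$o2_set
  r_on_set <- exchange_rate(diff$k_on, o2_set)
  r_off_set <- exchange_rate(diff$k_off, o2_set)
  setpoint_mode <- cfg$control_kinetics == "setpoint"
  burst_end <- cfg$burst == "end"

  temp_step <- temp_at(profile, (seq_len(n) - 1) * dt / 3600)

  o2 <- cfg$o2_init
  co2 <- cfg$co2_init
  active <- !cfg$pulldown
  anchor <- if (active) 0 else NA_real_
  tin <- 0            # seconds into current cycle
  bof <- 0
  resp_set_h <- 0     # controller-model respiration demand, mL h-1
  cum_sup <- 0
  cum_resp <- 0
  clip_ml <- 0
  pulldown_end <- if (active) 0 else NA_real_

  # cached actual-state Arrhenius factors (recomputed when temp changes)
  t_cache <- NA_real_
  vmax_t <- 0
  rmin_t <- 0
  wp <- geom$wp
  km <- p$km
  ki <- p$ki

  out_o2 <- numeric(n); out_co2 <- numeric(n); out_duty <- numeric(n)
  out_sup <- numeric(n); out_resp <- numeric(n)

  cyc_rows <- list()
  cyc_i <- 0L
  cyc_min <- Inf; cyc_max <- -Inf; cyc_sum <- 0; cyc_n <- 0L
  cyc_start <- NA_real_; cyc_temp <- NA_real_; cyc_bof <- NA_real_; cyc_clamp <- NA

  close_cycle <- function() {
    cyc_rows[[length(cyc_rows) + 1L]] <<- data.frame(
      cycle = cyc_i, start_s = cyc_start, temp_c = cyc_temp, bof_s = cyc_bof,
      clamped = cyc_clamp, o2_min = cyc_min, o2_max = cyc_max,
      o2_mean = cyc_sum / cyc_n)
  }

  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    temp <- temp_step[i]

    if (!active && o2 <= o2_set) {
      active <- TRUE
      anchor <- t
      pulldown_end <- t
      tin <- 0
    }

    if (active && tin == 0) {
      if (cyc_i > 0L && cyc_n > 0L) close_cycle()
      cyc_i <- cyc_i + 1L
      temp_ctl <- temp
      if (cfg$temp_noise_sd > 0) temp_ctl <- temp + stats::rnorm(1, 0, cfg$temp_noise_sd)
      br <- compute_bof(p, geom, diff, ctl, temp_ctl)
      bof <- br$bof_s
      resp_set_h <- br$demand_ml_h
      cyc_start <- t; cyc_temp <- temp_ctl; cyc_bof <- bof; cyc_clamp <- br$clamped
      cyc_min <- Inf; cyc_max <- -Inf; cyc_sum <- 0; cyc_n <- 0L
    }

    # duty fraction of this step inside the burst window (exact fractional overlap)
    duty <- 0
    if (active && bof > 0) {
      win_lo <- if (burst_end) cycle_s - bof else 0
      win_hi <- if (burst_end) cycle_s else bof
      ov <- min(tin + dt, win_hi) - max(tin, win_lo)
      if (ov > 0) duty <- ov / dt
    }

    if (active && setpoint_mode) {
      supply <- (duty * r_on_set + (1 - duty) * r_off_set) * dt
      respired <- resp_set_h * dt / 3600
    } else {
      if (!identical(temp, t_cache)) {
        vmax_t <- p$r_max_pre * exp(-p$ea_max / (8.314 * (temp + 273)))
        rmin_t <- p$r_min_pre * exp(-p$ea_min / (8.314 * (temp + 273)))
        t_cache <- temp
      }
      k_eff <- duty * diff$k_on + (1 - duty) * diff$k_off
      supply <- k_eff * (21 - o2) / 100 * 1e6 * dt
      respired <- (vmax_t * o2 / (km + (1 + co2 / ki) * o2) + rmin_t) * wp * dt / 3600
    }

    o2_new <- o2 + (supply - respired) / vf_ml * 100
    if (o2_new < 0) { clip_ml <- clip_ml + (0 - o2_new) * vf_ml / 100; o2_new <- 0 }
    if (o2_new > 21) { clip_ml <- clip_ml - (o2_new - 21) * vf_ml / 100; o2_new <- 21 }
    o2 <- o2_new
    if (cfg$co2_mode == "dynamic") {
      k_eff_c <- duty * diff$k_on + (1 - duty) * diff$k_off
      efflux <- k_eff_c * (co2 - 0.04) / 100 * 1e6 * dt
      co2 <- min(max(co2 + (cfg$rq * respired - efflux) / vf_ml * 100, 0), 100)
    }
    cum_sup <- cum_sup + supply
    cum_resp <- cum_resp + respired

    if (active) {
      if (o2 < cyc_min) cyc_min <- o2
      if (o2 > cyc_max) cyc_max <- o2
      cyc_sum <- cyc_sum + o2
      cyc_n <- cyc_n + 1L
      tin <- tin + dt
      if (tin >= cycle_s - 1e-9) tin <- 0
    }

    out_o2[i] <- o2; out_co2[i] <- co2; out_duty[i] <- duty
    out_sup[i] <- cum_sup; out_resp[i] <- cum_resp
  }
  # close the final cycle only if complete
  if (cyc_i > 0L && cyc_n > 0L && tin == 0) close_cycle()

  steps <- data.frame(time_s = seq_len(n) * dt, temp_c = temp_step,
                      o2 = out_o2, co2 = out_co2, duty = out_duty,
                      supplied_ml = out_sup, respired_ml = out_resp)
  cycles <- if (length(cyc_rows)) do.call(rbind, cyc_rows) else
    data.frame(cycle = integer(), start_s = numeric(), temp_c = numeric(),
               bof_s = numeric(), clamped = logical(), o2_min = numeric(),
               o2_max = numeric(), o2_mean = numeric())
  structure(list(steps = steps, cycles = cycles,
                 pulldown_end_s = pulldown_end, clip_ml = clip_ml,
                 profile = profile, ctl = ctl, cfg = cfg),
            class = "ma_trajectory")
}

#' @export
print.ma_trajectory <- function(x, ...) {
  cat(sprintf("MA trajectory: %.1f h, %d steps, %d complete control cycles\n",
              max(x$steps$time_s) / 3600, nrow(x$steps), nrow(x$cycles)))
  if (is.na(x$pulldown_end_s)) {
    cat("  pulldown: set point never reached\n")
  } else {
    cat(sprintf("  control active from %.2f h; final O2 %.3f%%\n",
                x$pulldown_end_s / 3600, x$steps$o2[nrow(x$steps)]))
  }
  invisible(x)
}

#' Limit-cycle summary of a trajectory
#'
#' Summarises the O2 oscillation over the complete control cycles whose
#' start falls within the trailing `window_h` hours of the run.
#'
#' @param traj [simulate_box()] result.
#' @param window_h Trailing window (h).
#' @return List with `o2_mean`, `o2_min`, `o2_max`, `amplitude`
#'   (`o2_max - o2_min`) and `n_cycles`.
#' @export
limit_cycle_stats <- function(traj, window_h) {
  stopifnot(inherits(traj, "ma_trajectory"))
  cyc <- traj$cycles
  t_end <- max(traj$steps$time_s)
  sel <- cyc[cyc$start_s >= t_end - window_h * 3600, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop("window contains no complete control cycle", call. = FALSE)
  }
  list(o2_mean = mean(sel$o2_mean),
       o2_min = min(sel$o2_min),
       o2_max = max(sel$o2_max),
       amplitude = max(sel$o2_max) - min(sel$o2_min),
       n_cycles = nrow(sel))
}
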