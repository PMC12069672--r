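#' Sample parameter draws from the registry
#'
#' Each parameter is drawn independently from a normal distribution with
#' mean `base` and standard deviation `abs_error` (the registry's absolute
#' error), truncated at zero by redrawing. Truncation is essentially never
#' triggered at the broccoli scales (all parameters sit 8 sigma or more
#' above zero) but is logged via the `n_redrawn` attribute.
#'
#' @param registry Registry data frame ([broccoli_params()]).
#' @param n Number of draws, at least 1.
#' @param seed Optional integer seed (fixed seed gives bit-identical draws).
#' @return An `n` x 10 numeric matrix, columns named by parameter.
#' @export
#' @examples
#' sample_parameters(broccoli_params(), 5, seed = 1)
sample_parameters <- function(registry, n, seed = NULL) {
  validate_registry(registry)
  if (!is.finite(n) || n < 1) stop("n must be at least 1", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  n_redrawn <- 0L
  draws <- vapply(seq_len(nrow(registry)), function(i) {
    x <- stats::rnorm(n, registry$base[i], registry$abs_error[i])
    bad <- which(x <= 0)
    while (length(bad)) {
      n_redrawn <<- n_redrawn + length(bad)
      x[bad] <- stats::rnorm(length(bad), registry$base[i], registry$abs_error[i])
      bad <- bad[x[bad] <= 0]
    }
    x
  }, numeric(n))
  draws <- matrix(draws, nrow = n,
                  dimnames = list(NULL, registry$name))
  attr(draws, "n_redrawn") <- n_redrawn
  draws
}

#' Monte Carlo variability analysis of the BOF
#'
#' Propagates the registry's parameter uncertainties through the controller:
#' `n` independent draws ([sample_parameters()]), one BOF per draw at fixed
#' storage conditions (defaults: 10 degC, CO2 15%, O2 set point 3% — the
#' optimal broccoli storage point).
#'
#' @param registry Registry data frame; defaults to [broccoli_params()].
#' @param n Number of iterations (default 10000).
#' @param seed Optional integer seed.
#' @param ctl [control_settings()].
#' @param temp_c Storage temperature (deg C).
#' @return An object of class `mc_result`: list with `draws` (matrix),
#'   `bof` (vector, s), `mean`, `sd`, `n`, `seed`, `n_clamped`, `ctl`,
#'   `temp_c`.
#' @export
#' @examples
#' mc <- monte_carlo_bof(n = 500, seed = 7)
#' c(mc$mean, mc$sd)
monte_carlo_bof <- function(registry = broccoli_params(), n = 10000,
                            seed = NULL, ctl = control_settings(),
                            temp_c = 10) {
  draws <- sample_parameters(registry, n, seed)
  bof <- bof_raw(R_max = draws[, "R_max"], Ea_max = draws[, "Ea_max"],
                 R_min = draws[, "R_min"], Ea_min = draws[, "Ea_min"],
                 k_m = draws[, "k_m"], k_i = draws[, "k_i"],
                 k_O2_ON = draws[, "k_O2_ON"], k_O2_OFF = draws[, "k_O2_OFF"],
                 W_p = draws[, "W_p"],
                 o2_set = ctl$o2_set, co2_ref = ctl$co2_ref,
                 cycle_s = ctl$cycle_s, temp_c = temp_c)
  n_clamped <- sum(bof <= 0 | bof >= ctl$cycle_s)
  structure(list(draws = draws, bof = bof,
                 mean = mean(bof), sd = stats::sd(bof),
                 n = as.integer(n), seed = seed, n_clamped = n_clamped,
                 ctl = ctl, temp_c = temp_c),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo BOF: n = %d, mean = %.2f s, sd = %.2f s (T = %g degC)\n",
              x$n, x$mean, x$sd, x$temp_c))
  if (x$n_clamped > 0) cat("  clamped draws:", x$n_clamped, "\n")
  invisible(x)
}

#' One-at-a-time BOF sensitivity range of a single parameter
#'
#' Signed difference `BOF(base + abs_error) - BOF(base - abs_error)` with
#' every other parameter held at its base value.
#'
#' @inheritParams monte_carlo_bof
#' @param name Registry abbreviation of the parameter to vary.
#' @return Signed range in seconds.
#' @export
#' @examples
#' oat_bof_range(broccoli_params(), "W_p")  # ~ +5.1 s
oat_bof_range <- function(registry = broccoli_params(), name,
                          ctl = control_settings(), temp_c = 10) {
  validate_registry(registry)
  if (!name %in% registry$name) {
    stop("unknown parameter '", name, "'", call. = FALSE)
  }
  base <- param_values(registry)
  err <- registry$abs_error[match(name, registry$name)]
  bof_at <- function(vals) {
    bof_raw(R_max = vals[["R_max"]], Ea_max = vals[["Ea_max"]],
            R_min = vals[["R_min"]], Ea_min = vals[["Ea_min"]],
            k_m = vals[["k_m"]], k_i = vals[["k_i"]],
            k_O2_ON = vals[["k_O2_ON"]], k_O2_OFF = vals[["k_O2_OFF"]],
            W_p = vals[["W_p"]],
            o2_set = ctl$o2_set, co2_ref = ctl$co2_ref,
            cycle_s = ctl$cycle_s, temp_c = temp_c)
  }
  plus <- base; plus[[name]] <- base[[name]] + err
  minus <- base; minus[[name]] <- base[[name]] - err
  bof_at(plus) - bof_at(minus)
}

#' One-at-a-time sensitivity table for all registry parameters
#'
#' @inheritParams monte_carlo_bof
#' @return An object of class `oat_result`: data frame sorted by decreasing
#'   `abs_range`, with columns `name`, `bof_plus`, `bof_minus`, `range_s`
#'   (signed), `abs_range`, `rank`.
#' @export
#' @examples
#' head(oat_bof_all(), 3)  # W_p, R_min, k_m lead the ranking
oat_bof_all <- function(registry = broccoli_params(),
                        ctl = control_settings(), temp_c = 10) {
  validate_registry(registry)
  base <- param_values(registry)
  bof_at <- function(vals) {
    bof_raw(R_max = vals[["R_max"]], Ea_max = vals[["Ea_max"]],
            R_min = vals[["R_min"]], Ea_min = vals[["Ea_min"]],
            k_m = vals[["k_m"]], k_i = vals[["k_i"]],
            k_O2_ON = vals[["k_O2_ON"]], k_O2_OFF = vals[["k_O2_OFF"]],
            W_p = vals[["W_p"]],
            o2_set = ctl$o2_set, co2_ref = ctl$co2_ref,
            cycle_s = ctl$cycle_s, temp_c = temp_c)
  }
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    nm <- registry$name[i]
    err <- registry$abs_error[i]
    plus <- base; plus[[nm]] <- base[[nm]] + err
    minus <- base; minus[[nm]] <- base[[nm]] - err
    bp <- bof_at(plus); bm <- bof_at(minus)
    data.frame(name = nm, bof_plus = bp, bof_minus = bm,
               range_s = bp - bm, abs_range = abs(bp - bm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$abs_range), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("oat_result", "data.frame")
  out
}

#' Pareto contributions of the OAT sensitivity ranges
#'
#' Variance-based shares under independent symmetric perturbations: each
#' parameter contributes `(range/2)^2`, normalised so the shares sum to 1.
#' The cumulative curve over the ranking identifies the smallest subset of
#' parameters explaining a given fraction of the BOF variability (the 80/20
#' reading).
#'
#' @param oat An [oat_bof_all()] result.
#' @return Data frame ordered by decreasing share: `name`, `abs_range`,
#'   `share`, `cumulative`.
#' @export
#' @examples
#' pareto_contributions(oat_bof_all())
pareto_contributions <- function(oat) {
  stopifnot(inherits(oat, "oat_result"))
  v <- (oat$abs_range / 2)^2
  if (sum(v) == 0) stop("all sensitivity ranges are zero", call. = FALSE)
  out <- data.frame(name = oat$name, abs_range = oat$abs_range,
                    share = v / sum(v), stringsAsFactors = FALSE)
  out <- out[order(-out$share), , drop = FALSE]
  out$cumulative <- cumsum(out$share)
  rownames(out) <- NULL
  out
}

#' Pearson correlations between parameter draws and BOF
#'
#' @param mc A [monte_carlo_bof()] result with at least 100 draws.
#' @return Data frame `name`, `r`, `constant` (TRUE where the draw column
#'   had zero variance, in which case `r` is reported as 0).
#' @export
#' @examples
#' mc <- monte_carlo_bof(n = 1000, seed = 1)
#' bof_correlations(mc)
bof_correlations <- function(mc) {
  stopifnot(inherits(mc, "mc_result"))
  if (mc$n < 100) stop("need at least 100 draws for stable correlations", call. = FALSE)
  r <- vapply(colnames(mc$draws), function(nm) {
    x <- mc$draws[, nm]
    if (stats::sd(x) == 0 || stats::sd(mc$bof) == 0) NA_real_
    else stats::cor(x, mc$bof)
  }, numeric(1))
  data.frame(name = colnames(mc$draws),
             r = ifelse(is.na(r), 0, r),
             constant = is.na(r),
             stringsAsFactors = FALSE)
}

#' One-at-a-time effect of parameter variation on controlled O2
#'
#' Runs the simulator at baseline and at perturbed parameters (one named
#' parameter, or `"all"` shifted together) over a temperature profile and
#' summarises the trajectory difference
#' `delta O2 = O2(varied) - O2(baseline)`.
#'
#' @inheritParams monte_carlo_bof
#' @param name Registry abbreviation, or `"all"` to shift every parameter
#'   simultaneously by `sign * abs_error`.
#' @param profile [temperature_profile()]; defaults to the supply-chain
#'   preset ([preset_profile()]).
#' @param sign `+1` or `-1`: direction of the perturbation.
#' @param cfg [sim_config()] shared by both runs.
#' @param density Product density (kg m-3).
#' @return List with `delta` (data frame `time_s`, `delta_o2`), `baseline`
#'   and `varied` trajectories, and `summary`: per-arm time-to-set-point (h)
#'   and post-pulldown mean and sd of O2.
#' @export
oat_o2_delta <- function(registry = broccoli_params(), name = "all",
                         profile = preset_profile(), sign = 1,
                         ctl = control_settings(), cfg = sim_config(),
                         density = 1050) {
  validate_registry(registry)
  if (!identical(name, "all") && !name %in% registry$name) {
    stop("unknown parameter '", name, "'", call. = FALSE)
  }
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1", call. = FALSE)
  base <- param_values(registry)
  varied <- base
  if (identical(name, "all")) {
    varied <- base + sign * stats::setNames(registry$abs_error, registry$name)
  } else {
    err <- registry$abs_error[match(name, registry$name)]
    varied[[name]] <- base[[name]] + sign * err
  }
  run <- function(vals) {
    m <- model_from_values(vals, density = density)
    simulate_box(profile, m$p, m$geom, m$diff, ctl, cfg)
  }
  tb <- run(base)
  tv <- run(varied)
  post_stats <- function(tr) {
    if (is.na(tr$pulldown_end_s)) return(c(NA_real_, NA_real_))
    o2 <- tr$steps$o2[tr$steps$time_s > tr$pulldown_end_s]
    c(mean(o2), stats::sd(o2))
  }
  sb <- post_stats(tb); sv <- post_stats(tv)
  list(
    delta = data.frame(time_s = tb$steps$time_s,
                       delta_o2 = tv$steps$o2 - tb$steps$o2),
    baseline = tb, varied = tv,
    summary = data.frame(
      arm = c("baseline", "varied"),
      time_to_setpoint_h = c(tb$pulldown_end_s, tv$pulldown_end_s) / 3600,
      o2_mean = c(sb[1], sv[1]),
      o2_sd = c(sb[2], sv[2]),
      stringsAsFactors = FALSE
    )
  )
}
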