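#' Supply-chain temperature preset
#'
#' Six-stage cold chain emulating a broccoli supply chain: field and
#' transportation (20 degC), precooling (7), transport to warehouse (3),
#' warehouse storage (1), transport to distribution centre (5), storage at
#' the distribution centre (10). The stage temperatures and their order are
#' the documented chain; the default durations are synthetic (no published
#' values exist) and freely overridable.
#'
#' @param kind Preset name; only `"supply_chain"` is defined.
#' @param durations_h Optional six positive stage durations (h); defaults
#'   to `c(8, 12, 24, 48, 12, 36)`.
#' @return A [temperature_profile()].
#' @export
#' @examples
#' preset_profile()
preset_profile <- function(kind = "supply_chain", durations_h = NULL) {
  if (!identical(kind, "supply_chain")) {
    stop("unknown preset '", kind, "'", call. = FALSE)
  }
  temps <- c(20, 7, 3, 1, 5, 10)
  if (is.null(durations_h)) durations_h <- c(8, 12, 24, 48, 12, 36)
  if (length(durations_h) != length(temps)) {
    stop("supply_chain preset needs ", length(temps), " durations", call. = FALSE)
  }
  temperature_profile(durations_h, temps)
}

#' Random piecewise-constant profiles for property testing
#'
#' @param n Number of profiles (0 allowed).
#' @param seed Optional integer seed; a fixed seed reproduces the profiles.
#' @param temp_range Length-2 range of segment temperatures (deg C).
#' @param duration_range Length-2 range of segment durations (h).
#' @param segments Number of segments per profile.
#' @return List of [temperature_profile()] objects.
#' @export
fixture_profiles <- function(n, seed = NULL, temp_range = c(0, 25),
                             duration_range = c(1, 12), segments = 4) {
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  if (diff(temp_range) <= 0 || diff(duration_range) <= 0 || duration_range[1] <= 0) {
    stop("degenerate temperature or duration range", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    temperature_profile(
      stats::runif(segments, duration_range[1], duration_range[2]),
      stats::runif(segments, temp_range[1], temp_range[2])
    )
  })
}

#' Read / write temperature profiles as CSV
#'
#' The CSV has columns `time_h, temp_C`: each row starts a segment at
#' `time_h` (0-based, half-open) holding `temp_C`; the final row is a
#' terminal sentinel marking the profile end (its temperature is ignored
#' on read and repeats the last segment on write).
#'
#' @param profile [temperature_profile()].
#' @param path CSV file path.
#' @return `write_profile_csv()` returns `path` invisibly;
#'   `read_profile_csv()` returns a [temperature_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "temperature_profile"))
  df <- data.frame(
    time_h = c(profile$start_h, attr(profile, "total_h")),
    temp_C = c(profile$temp_c, profile$temp_c[nrow(profile)])
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_h", "temp_C") %in% names(df))) {
    stop("profile CSV needs columns time_h, temp_C", call. = FALSE)
  }
  if (nrow(df) < 2) stop("profile CSV needs at least a segment and a terminal row", call. = FALSE)
  if (is.unsorted(df$time_h, strictly = TRUE)) {
    stop("time_h must be strictly increasing", call. = FALSE)
  }
  if (df$time_h[1] != 0) stop("profile must start at time_h = 0", call. = FALSE)
  temperature_profile(diff(df$time_h), df$temp_C[-nrow(df)])
}

# ---- run configuration -----------------------------------------------------

.config_sections <- c("parameters", "density", "control", "sim", "seed")

#' Default run configuration
#'
#' The full model state as a serialisable list: the parameter registry
#' (Table-style keys, each `base` + `abs_error`), the product density, the
#' controller settings, the simulator configuration and a seed. Defaults are
#' the broccoli base case.
#'
#' @return A named list (class `ma_config`).
#' @seealso [load_config()], [save_config()], [config_objects()]
#' @export
default_config <- function() {
  reg <- broccoli_params()
  structure(list(
    parameters = stats::setNames(
      lapply(seq_len(nrow(reg)), function(i) {
        list(base = reg$base[i], abs_error = reg$abs_error[i])
      }), reg$name),
    density = 1050,
    control = list(o2_set = 3, co2_ref = 15, cycle_s = 3600),
    sim = list(dt = 1, rq = 1, co2_mode = "fixed", co2_fixed = 15,
               pulldown = TRUE, control_kinetics = "setpoint",
               burst = "end", o2_init = 21, temp_noise_sd = 0),
    seed = NULL
  ), class = "ma_config")
}

#' Load and validate a run configuration (JSON or YAML)
#'
#' Missing keys fall back to [default_config()]; unknown keys anywhere are
#' rejected with a message naming them. An empty file yields the full
#' default configuration. Validation instantiates every model object, so
#' unit-violating values (e.g. a product that does not fit the box) fail
#' here with the constructor's message.
#'
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return Validated configuration list (class `ma_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  fmt <- infer_format(path)
  raw <- if (fmt == "json") {
    if (file.size(path) == 0) NULL else jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  cfg <- default_config()
  unknown <- setdiff(names(raw), .config_sections)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$parameters)) {
    bad <- setdiff(names(raw$parameters), names(cfg$parameters))
    if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(raw$parameters)) {
      entry <- raw$parameters[[nm]]
      extra <- setdiff(names(entry), c("base", "abs_error"))
      if (length(extra)) stop("unknown keys under parameters$", nm, ": ",
                              paste(extra, collapse = ", "), call. = FALSE)
      for (k in names(entry)) cfg$parameters[[nm]][[k]] <- as.numeric(entry[[k]])
    }
  }
  if (!is.null(raw$density)) cfg$density <- as.numeric(raw$density)
  for (section in c("control", "sim")) {
    if (!is.null(raw[[section]])) {
      bad <- setdiff(names(raw[[section]]), names(cfg[[section]]))
      if (length(bad)) stop("unknown keys under ", section, ": ",
                            paste(bad, collapse = ", "), call. = FALSE)
      for (k in names(raw[[section]])) cfg[[section]][[k]] <- raw[[section]][[k]]
    }
  }
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  config_objects(cfg)  # full validation through the constructors
  cfg
}

#' Save a run configuration (JSON or YAML)
#'
#' @param cfg Configuration list (class `ma_config`).
#' @param path Output path; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ma_config"))
  fmt <- infer_format(path)
  obj <- unclass(cfg)
  if (is.null(obj$seed)) obj$seed <- NULL
  if (fmt == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' Instantiate model objects from a configuration
#'
#' @param cfg Configuration list ([default_config()] layout).
#' @return List with `registry`, `p`, `geom`, `diff`, `ctl`, `sim`.
#' @export
config_objects <- function(cfg) {
  reg <- data.frame(
    name = names(cfg$parameters),
    base = vapply(cfg$parameters, function(x) as.numeric(x$base), numeric(1)),
    abs_error = vapply(cfg$parameters, function(x) as.numeric(x$abs_error), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(reg) <- NULL
  reg$pct_error <- reg$abs_error / reg$base * 100
  class(reg) <- c("param_registry", "data.frame")
  validate_registry(reg)
  m <- model_from_values(param_values(reg), density = cfg$density)
  ctl <- do.call(control_settings, cfg$control)
  sim <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  list(registry = reg, p = m$p, geom = m$geom, diff = m$diff,
       ctl = ctl, sim = sim)
}

#' Write a trajectory's step records to CSV
#'
#' @param traj [simulate_box()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "ma_trajectory"))
  utils::write.csv(traj$steps, path, row.names = FALSE)
  invisible(path)
}
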