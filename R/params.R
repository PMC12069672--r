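#' Physical constants shared by the gas-exchange model
#'
#' Returns the fixed constants used throughout the package. The Kelvin
#' offset is 273 (not 273.15): the kinetic parameters were fitted with
#' `T + 273`, so the offset is part of the parameterisation and must not be
#' changed independently of the pre-exponential factors. It is exposed here
#' (and threaded through [arrhenius_factor()]) so that a reparameterised
#' data set can flip it deliberately.
#'
#' @return A named list: `rg` universal gas constant (J K-1 mol-1),
#'   `o2_ambient` ambient O2 (%), `co2_ambient` ambient CO2 (%),
#'   `kelvin_offset` (K), `seconds_per_hour`.
#' @export
#' @examples
#' ma_constants()$rg
ma_constants <- function() {
  list(
    rg = 8.314,
    o2_ambient = 21,
    co2_ambient = 0.04,
    kelvin_offset = 273,
    seconds_per_hour = 3600
  )
}

# canonical registry column order / key set (Table-style abbreviations)
.registry_keys <- c(
  "Ea_max", "Ea_min", "R_max", "R_min", "k_m", "k_i",
  "k_O2_OFF", "k_O2_ON", "W_p", "V_T"
)

#' Reference parameter registry for broccoli MA storage
#'
#' Base values and absolute errors of the ten model parameters used for all
#' variability analyses: activation energies (J mol-1), pre-exponential
#' respiration factors (mL kg-1 h-1), Michaelis-Menten and CO2 inhibition
#' constants (%), O2 exchange coefficients with the blower OFF/ON (m3 s-1),
#' product weight (kg) and total box volume (m3). `pct_error` is the
#' relative error implied by `abs_error/base` (in %).
#'
#' @return A data frame with columns `name`, `base`, `abs_error`,
#'   `pct_error`, one row per parameter.
#' @seealso [param_values()], [sample_parameters()], [oat_bof_all()]
#' @export
#' @examples
#' broccoli_params()
broccoli_params <- function() {
  reg <- data.frame(
    name = .registry_keys,
    base = c(8.63e4, 1.03e5, 2.76e17, 9.90e19, 19.6, 8.07,
             2.00e-8, 2.28e-5, 16, 0.07),
    abs_error = c(22.9, 43.6, 1.38e16, 4.95e18, 2.4, 2.2,
                  1.00e-9, 6.00e-8, 0.8, 0.0035),
    stringsAsFactors = FALSE
  )
  reg$pct_error <- reg$abs_error / reg$base * 100
  class(reg) <- c("param_registry", "data.frame")
  reg
}

#' Extract a named base-value vector from a registry
#'
#' @param registry A registry data frame as returned by [broccoli_params()].
#' @return Named numeric vector of base values.
#' @export
param_values <- function(registry) {
  validate_registry(registry)
  stats::setNames(registry$base, registry$name)
}

#' @keywords internal
validate_registry <- function(registry) {
  if (!is.data.frame(registry) ||
      !all(c("name", "base", "abs_error") %in% names(registry))) {
    stop("registry must be a data frame with columns name, base, abs_error",
         call. = FALSE)
  }
  missing <- setdiff(.registry_keys, registry$name)
  extra <- setdiff(registry$name, .registry_keys)
  if (length(missing) || length(extra)) {
    stop("registry must contain exactly the parameters ",
         paste(.registry_keys, collapse = ", "),
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(registry$name)) stop("duplicated registry parameter names", call. = FALSE)
  if (!all(is.finite(registry$base)) || !all(is.finite(registry$abs_error))) {
    stop("registry values must be finite", call. = FALSE)
  }
  if (any(registry$base <= 0)) stop("registry base values must be positive", call. = FALSE)
  if (any(registry$abs_error < 0)) stop("registry absolute errors must be non-negative", call. = FALSE)
  invisible(registry)
}

#' Respiration kinetic parameters
#'
#' Bundles the six constants of the respiration model: Michaelis-Menten
#' O2 kinetics with uncompetitive-style CO2 inhibition, plus a residual
#' low-O2 term, each with its own Arrhenius temperature dependence.
#'
#' @param r_max_pre Pre-exponential factor under abundant O2 (mL kg-1 h-1).
#' @param r_min_pre Pre-exponential factor under low O2 (mL kg-1 h-1).
#' @param ea_max Activation energy under abundant O2 (J mol-1).
#' @param ea_min Activation energy under low O2 (J mol-1).
#' @param km Michaelis-Menten constant (% O2).
#' @param ki CO2 inhibition constant (%).
#' @return An object of class `respiration_params`.
#' @export
#' @examples
#' respiration_params()  # broccoli defaults
respiration_params <- function(r_max_pre = 2.76e17, r_min_pre = 9.90e19,
                               ea_max = 8.63e4, ea_min = 1.03e5,
                               km = 19.6, ki = 8.07) {
  vals <- c(r_max_pre = r_max_pre, r_min_pre = r_min_pre, ea_max = ea_max,
            ea_min = ea_min, km = km, ki = ki)
  if (!all(is.finite(vals))) stop("respiration parameters must be finite", call. = FALSE)
  if (!all(vals > 0)) stop("respiration parameters must be strictly positive", call. = FALSE)
  structure(as.list(vals), class = "respiration_params")
}

#' Gas conditions in the headspace
#'
#' @param o2 O2 concentration (% v/v), in \[0, 100\].
#' @param co2 CO2 concentration (% v/v), in \[0, 100\].
#' @param temp_c Temperature (deg C), in \[-30, 60\].
#' @return An object of class `gas_conditions`.
#' @export
gas_conditions <- function(o2, co2, temp_c) {
  if (!all(is.finite(c(o2, co2, temp_c)))) stop("gas conditions must be finite", call. = FALSE)
  if (o2 < 0 || o2 > 100) stop("o2 must lie in [0, 100] %", call. = FALSE)
  if (co2 < 0 || co2 > 100) stop("co2 must lie in [0, 100] %", call. = FALSE)
  if (temp_c < -30 || temp_c > 60) stop("temp_c must lie in [-30, 60] degC", call. = FALSE)
  structure(list(o2 = o2, co2 = co2, temp_c = temp_c), class = "gas_conditions")
}

#' Storage box geometry
#'
#' The free (headspace) volume is the total box volume minus the produce
#' volume `wp / density`; it must be strictly positive.
#'
#' @param v_total Total box volume (m3).
#' @param wp Product weight (kg).
#' @param density Product density (kg m-3); default 1050.
#' @return An object of class `box_geometry`.
#' @seealso [free_volume()]
#' @export
box_geometry <- function(v_total = 0.07, wp = 16, density = 1050) {
  if (!all(is.finite(c(v_total, wp, density)))) stop("geometry must be finite", call. = FALSE)
  if (wp < 0) stop("wp must be non-negative", call. = FALSE)
  if (density <= 0) stop("density must be positive", call. = FALSE)
  if (v_total - wp / density <= 0) {
    stop("product volume wp/density (", format(wp / density),
         " m3) leaves no free volume in a ", format(v_total), " m3 box",
         call. = FALSE)
  }
  structure(list(v_total = v_total, wp = wp, density = density),
            class = "box_geometry")
}

#' O2 exchange coefficients of the blower system
#'
#' @param k_on Exchange coefficient with the blower ON (m3 s-1).
#' @param k_off Exchange coefficient with the blower OFF, i.e. passive
#'   diffusion through the tube (m3 s-1).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(k_on = 2.28e-5, k_off = 2.00e-8) {
  if (!all(is.finite(c(k_on, k_off)))) stop("diffusion coefficients must be finite", call. = FALSE)
  if (!(k_on > k_off && k_off > 0)) {
    stop("require k_on > k_off > 0 (forced exchange must dominate passive)",
         call. = FALSE)
  }
  structure(list(k_on = k_on, k_off = k_off), class = "diffusion_params")
}

#' Controller settings
#'
#' @param o2_set O2 set point (%), strictly between 0 and the ambient 21.
#' @param co2_ref CO2 concentration (%) used in the controller's respiration
#'   term (the MA operating point).
#' @param cycle_s Control cycle length (s); the blower schedule repeats each
#'   cycle. Default one hour.
#' @return An object of class `control_settings`.
#' @export
control_settings <- function(o2_set = 3, co2_ref = 15, cycle_s = 3600) {
  if (!all(is.finite(c(o2_set, co2_ref, cycle_s)))) stop("control settings must be finite", call. = FALSE)
  if (o2_set <= 0 || o2_set >= 21) stop("o2_set must lie strictly in (0, 21) %", call. = FALSE)
  if (co2_ref < 0 || co2_ref > 100) stop("co2_ref must lie in [0, 100] %", call. = FALSE)
  if (cycle_s <= 0) stop("cycle_s must be positive", call. = FALSE)
  structure(list(o2_set = o2_set, co2_ref = co2_ref, cycle_s = cycle_s),
            class = "control_settings")
}

#' Build model objects from a named parameter vector
#'
#' Convenience used by the sensitivity analyses: maps a vector keyed by the
#' registry abbreviations onto [respiration_params()], [box_geometry()] and
#' [diffusion_params()].
#'
#' @param values Named numeric vector with the registry keys.
#' @param density Product density (kg m-3).
#' @return List with elements `p`, `geom`, `diff`.
#' @export
model_from_values <- function(values, density = 1050) {
  stopifnot(all(.registry_keys %in% names(values)))
  list(
    p = respiration_params(r_max_pre = values[["R_max"]],
                           r_min_pre = values[["R_min"]],
                           ea_max = values[["Ea_max"]],
                           ea_min = values[["Ea_min"]],
                           km = values[["k_m"]], ki = values[["k_i"]]),
    geom = box_geometry(v_total = values[["V_T"]], wp = values[["W_p"]],
                        density = density),
    diff = diffusion_params(k_on = values[["k_O2_ON"]],
                            k_off = values[["k_O2_OFF"]])
  )
}

#' Write / read a parameter registry (JSON or YAML)
#'
#' The registry is serialised as a mapping keyed by the parameter
#' abbreviations, each entry holding `base` and `abs_error`. The format is
#' chosen from the file extension (`.json`, `.yaml`/`.yml`) unless given.
#'
#' @param registry Registry data frame ([broccoli_params()] layout).
#' @param path File path.
#' @param format `"json"`, `"yaml"`, or `NULL` to infer from `path`.
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   returns a validated registry data frame.
#' @export
write_registry <- function(registry, path, format = NULL) {
  validate_registry(registry)
  format <- format %||% infer_format(path)
  obj <- stats::setNames(
    lapply(seq_len(nrow(registry)), function(i) {
      list(base = registry$base[i], abs_error = registry$abs_error[i])
    }),
    registry$name
  )
  if (format == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path, format = NULL) {
  format <- format %||% infer_format(path)
  obj <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  reg <- data.frame(
    name = names(obj),
    base = vapply(obj, function(x) as.numeric(x$base), numeric(1)),
    abs_error = vapply(obj, function(x) as.numeric(x$abs_error), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(reg) <- NULL
  reg$pct_error <- reg$abs_error / reg$base * 100
  reg <- reg[match(.registry_keys, reg$name), , drop = FALSE]
  rownames(reg) <- NULL
  validate_registry(reg)
  class(reg) <- c("param_registry", "data.frame")
  reg
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") return("json")
  if (ext %in% c("yaml", "yml")) return("yaml")
  stop("cannot infer serialisation format from '", path,
       "'; use format = \"json\" or \"yaml\"", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
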