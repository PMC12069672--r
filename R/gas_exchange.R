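#' Free (headspace) volume of the storage box
#'
#' @param geom [box_geometry()].
#' @return Free volume in m3 (`v_total - wp/density`).
#' @export
#' @examples
#' free_volume(box_geometry(0.07, 16, 1050))  # ~0.0548 m3
free_volume <- function(geom) {
  stopifnot(inherits(geom, "box_geometry"))
  geom$v_total - geom$wp / geom$density
}

#' Instantaneous O2 exchange rate
#'
#' The O2 influx into the box driven by the concentration gradient to
#' ambient air: `k * (o2_ambient - o2) / 100`, converted from m3 s-1 to
#' mL s-1. Zero at ambient; negative (efflux) above ambient.
#'
#' @param k Exchange coefficient (m3 s-1): `k_on` with the blower running,
#'   `k_off` for passive diffusion through the tube.
#' @param o2 Current headspace O2 (%).
#' @param o2_ambient Ambient O2 (%), default 21.
#' @return O2 influx, mL s-1.
#' @export
#' @examples
#' exchange_rate(2.28e-5, 3)   # forced, ~4.1 mL s-1
#' exchange_rate(2.00e-8, 3)   # passive, ~0.0036 mL s-1
exchange_rate <- function(k, o2, o2_ambient = ma_constants()$o2_ambient) {
  if (!all(is.finite(c(k, o2)))) stop("exchange_rate() requires finite inputs", call. = FALSE)
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  k * (o2_ambient - o2) / 100 * 1e6
}

#' Headspace O2 after an exchange interval
#'
#' Closed-form solution of the exchange mass balance
#' `dO2/dt = k (o2_ambient - O2) / vf` over `t` seconds (respiration
#' excluded): an exponential relaxation towards ambient,
#' `o2_ambient + (o2_start - o2_ambient) exp(-k t / vf)`.
#'
#' @inheritParams exchange_rate
#' @param vf Free volume (m3).
#' @param o2_start O2 at the start of the interval (%).
#' @param t Interval length (s), non-negative.
#' @return O2 (%) after `t` seconds.
#' @export
o2_after_interval <- function(k, vf, o2_start, t,
                              o2_ambient = ma_constants()$o2_ambient) {
  if (!all(is.finite(c(k, vf, o2_start, t)))) {
    stop("o2_after_interval() requires finite inputs", call. = FALSE)
  }
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (vf <= 0) stop("vf must be positive", call. = FALSE)
  o2_ambient + (o2_start - o2_ambient) * exp(-k * t / vf)
}

#' Volume of O2 exchanged over an interval
#'
#' Integral of [exchange_rate()] along the exponential relaxation: the O2
#' volume (mL) that entered the box in `t` seconds,
#' `vf * (o2_after_interval - o2_start) / 100`. Its derivative at `t = 0`
#' equals `exchange_rate(k, o2_start)`, and it saturates at
#' `vf * (o2_ambient - o2_start) / 100` as `t` grows.
#'
#' @inheritParams o2_after_interval
#' @return O2 volume diffused into the box, mL.
#' @export
o2_volume_exchanged <- function(k, vf, o2_start, t,
                                o2_ambient = ma_constants()$o2_ambient) {
  o2_end <- o2_after_interval(k, vf, o2_start, t, o2_ambient)
  vf * (o2_end - o2_start) / 100 * 1e6
}
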