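#' Pulse protocol
#'
#' An electroporation pulse train, e.g. the ESOPE standard: 8
#' rectangular pulses of 100 microseconds separated by 1 s.
#'
#' @param U pulse voltage, V.
#' @param I pulse current, A (may be 0 for a null protocol).
#' @param n_pulses number of pulses.
#' @param pulse_duration seconds; must be shorter than `period`.
#' @param period pulse repetition period, seconds (default 1).
#' @param field nominal field amplitude, V/cm (informational).
#' @return list of class `pulse_protocol`.
#' @export
pulse_protocol <- function(U, I, n_pulses = 8, pulse_duration = 100e-6,
                           period = 1, field = NA_real_) {
  if (!(U > 0 && I >= 0 && n_pulses > 0 && pulse_duration > 0 && period > 0)) {
    stop("protocol parameters must be positive (I may be zero)")
  }
  if (pulse_duration >= period) stop("pulse_duration must be < period")
  structure(list(U = U, I = I, n_pulses = as.integer(n_pulses),
                 pulse_duration = pulse_duration, period = period,
                 field = field),
            class = "pulse_protocol")
}

#' Sample thermal properties
#'
#' @param rho mass density, kg/m^3.
#' @param c_p specific heat capacity, J/(kg K).
#' @param k_th thermal conductivity, W/(m K).
#' @param diameter,height cylindrical sample dimensions, m.
#' @param alpha_T conductivity temperature coefficient, 1/K (0.025-0.03
#'   for intact to fully damaged potato tissue).
#' @return list of class `sample_thermal`.
#' @export
sample_thermal <- function(rho = 1062, c_p = 3770, k_th = 0.55,
                           diameter = 0.01, height = 0.0045,
                           alpha_T = 0.025) {
  vals <- c(rho, c_p, k_th, diameter, height, alpha_T)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thermal parameters must be positive")
  }
  structure(list(rho = rho, c_p = c_p, k_th = k_th, diameter = diameter,
                 height = height, alpha_T = alpha_T),
            class = "sample_thermal")
}

#' Energy absorbed by a pulse train
#'
#' \eqn{E = U I \Delta t} with \eqn{\Delta t} the cumulative on-time of
#' the pulses. Joule heating only; the result is an upper bound on the
#' energy deposited in the sample.
#'
#' @param p a [pulse_protocol()].
#' @return energy, J.
#' @export
absorbed_energy <- function(p) {
  stopifnot(inherits(p, "pulse_protocol"))
  p$U * p$I * (p$n_pulses * p$pulse_duration)
}

#' Sample heat capacity
#'
#' \eqn{C = \rho c_p V} for a cylinder of the given diameter and height.
#'
#' @param s a [sample_thermal()].
#' @return heat capacity, J/K.
#' @export
heat_capacity <- function(s) {
  stopifnot(inherits(s, "sample_thermal"))
  s$rho * s$c_p * (pi * (s$diameter / 2)^2 * s$height)
}

#' Adiabatic temperature rise
#'
#' \eqn{\Delta T = E / C}: an adiabatic upper bound — the real rise is
#' lower because heat is conducted away, mainly through the electrodes.
#'
#' @param E absorbed energy, J.
#' @param C heat capacity, J/K.
#' @return temperature rise, K (adiabatic upper bound).
#' @export
adiabatic_rise <- function(E, C) {
  stopifnot(E >= 0, C > 0)
  E / C
}

#' Thermal diffusion time
#'
#' \eqn{t_d = l^2 \rho c_p / k}: the time scale on which heat diffuses
#' over the characteristic length l (e.g. half the sample height for
#' cooling through the electrodes).
#'
#' @param l characteristic length, m.
#' @param s a [sample_thermal()].
#' @return time, seconds.
#' @export
diffusion_time <- function(l, s) {
  stopifnot(l > 0, inherits(s, "sample_thermal"))
  l^2 * s$rho * s$c_p / s$k_th
}

#' Temperature-driven conductivity change
#'
#' Fractional conductivity increase \eqn{\alpha_T \Delta T} for a
#' temperature rise \eqn{\Delta T}.
#'
#' @param alpha_T conductivity temperature coefficient, 1/K.
#' @param dT temperature rise, K.
#' @return dimensionless fraction.
#' @export
conductivity_change <- function(alpha_T, dT) {
  stopifnot(alpha_T > 0, dT >= 0)
  alpha_T * dT
}
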