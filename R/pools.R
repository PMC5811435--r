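#' Proton frequency per ppm at 9.4 T
#'
#' Conversion constant between chemical-shift offsets (ppm) and frequency
#' offsets (Hz) for protons at 9.4 T. All functions taking a `hz_per_ppm`
#' argument default to this value; override it for other field strengths.
#'
#' @format Numeric scalar, 400.2 Hz/ppm.
#' @export
HZ_PER_PPM_9T4 <- 400.2

#' Define an exchanging proton pool
#'
#' A pool is one population of protons in the Bloch-McConnell exchange model:
#' bulk water, or a solute whose labile protons (amine, amide, guanidinium)
#' exchange with water and can be saturated selectively.
#'
#' @param name Pool label.
#' @param chemical_shift Resonance offset from water, ppm (positive =
#'   downfield; glutamate amine protons sit at +3 ppm).
#' @param proton_concentration Concentration of exchangeable protons, mM
#'   (molecule concentration times protons per molecule; pure water is
#'   2 x 55.5 M = 111000 mM).
#' @param exchange_rate Proton exchange rate pool -> water, s^-1. 0 for water.
#' @param T1,T2 Longitudinal / transverse relaxation times, s.
#' @return A `cest_pool` object (named list).
#' @examples
#' cest_pool("glu", 3, 3 * 10, 5500, 1.0, 0.008)
#' @export
cest_pool <- function(name, chemical_shift, proton_concentration,
                      exchange_rate, T1, T2) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(chemical_shift))
    stop("chemical_shift must be finite")
  if (proton_concentration < 0)
    stop("proton_concentration must be >= 0")
  if (exchange_rate < 0)
    stop("exchange_rate must be >= 0")
  if (T1 <= 0 || T2 <= 0)
    stop("relaxation times must be positive")
  if (T2 > T1)
    stop("T2 must not exceed T1")
  structure(list(name = name, chemical_shift = chemical_shift,
                 proton_concentration = proton_concentration,
                 exchange_rate = exchange_rate, T1 = T1, T2 = T2),
            class = "cest_pool")
}

#' Default pools for brain tissue at 9.4 T
#'
#' Convenience constructors with literature-typical parameters. The glutamate
#' amine pool carries 3 exchangeable protons per molecule at +3 ppm exchanging
#' at 5500 s^-1; creatine contributes a slower background pool at +1.9 ppm.
#' Water relaxation defaults are typical of mouse brain parenchyma at 9.4 T.
#'
#' @param T1,T2 Relaxation times, s.
#' @param concentration_mM Molecule concentration, mM.
#' @param exchange_rate Exchange rate, s^-1.
#' @param protons_per_molecule Exchangeable protons per molecule.
#' @param chemical_shift Offset from water, ppm.
#' @return A [cest_pool()].
#' @name default_pools
NULL

#' @rdname default_pools
#' @export
water_pool <- function(T1 = 1.8, T2 = 0.05) {
  cest_pool("water", 0, 2 * 55.5e3, 0, T1, T2)
}

#' @rdname default_pools
#' @export
glutamate_pool <- function(concentration_mM = 10, exchange_rate = 5500,
                           protons_per_molecule = 3, chemical_shift = 3,
                           T1 = 1.0, T2 = 0.008) {
  cest_pool("glutamate", chemical_shift,
            protons_per_molecule * concentration_mM, exchange_rate, T1, T2)
}

#' @rdname default_pools
#' @export
creatine_pool <- function(concentration_mM = 8, exchange_rate = 950,
                          protons_per_molecule = 4, chemical_shift = 1.9,
                          T1 = 1.0, T2 = 0.010) {
  cest_pool("creatine", chemical_shift,
            protons_per_molecule * concentration_mM, exchange_rate, T1, T2)
}

#' Saturation pulse scheme
#'
#' Describes the frequency-selective saturation preparation: a train of
#' square pulses followed by readout, repeated at each offset. The default is
#' the GluCEST scheme: four 250 ms square pulses with <10 us gaps (duty cycle
#' effectively 100%, i.e. 1 s continuous saturation) at peak B1 of 250 Hz
#' (5.87 uT), offsets +/-2.5 to +/-3.5 ppm in 0.25 ppm steps, 8 s recovery.
#'
#' @param pulse_count Number of square pulses.
#' @param pulse_duration Duration of each pulse, s.
#' @param inter_pulse_delay Gap between pulses, s.
#' @param peak_b1 Peak saturation amplitude, Hz (gamma*B1/2pi).
#' @param offsets Saturation offsets, ppm.
#' @param recovery_delay T1 recovery delay before saturation, s.
#' @return A `saturation_scheme` object.
#' @export
saturation_scheme <- function(pulse_count = 4, pulse_duration = 0.25,
                              inter_pulse_delay = 10e-6, peak_b1 = 250,
                              offsets = default_offsets(),
                              recovery_delay = 8) {
  stopifnot(pulse_count >= 1, pulse_duration > 0, inter_pulse_delay >= 0,
            peak_b1 >= 0, recovery_delay >= 0)
  duty <- pulse_duration / (pulse_duration + inter_pulse_delay)
  if (duty <= 0 || duty > 1) stop("duty cycle must be in (0, 1]")
  if (anyDuplicated(offsets)) stop("offsets must be unique")
  if (any(!is.finite(offsets))) stop("offsets must be finite")
  structure(list(pulse_count = as.integer(pulse_count),
                 pulse_duration = pulse_duration,
                 inter_pulse_delay = inter_pulse_delay,
                 peak_b1 = peak_b1, offsets = as.numeric(offsets),
                 recovery_delay = recovery_delay, duty_cycle = duty),
            class = "saturation_scheme")
}

#' @rdname saturation_scheme
#' @export
default_offsets <- function() {
  c(-3.5, -3.25, -3, -2.75, -2.5, 2.5, 2.75, 3, 3.25, 3.5)
}

#' Offsets for a full z-spectrum sweep
#'
#' 0 to +/-`max_ppm` in `step` ppm increments, as used for asymmetry plots.
#'
#' @param max_ppm Largest absolute offset, ppm.
#' @param step Step size, ppm.
#' @export
zspectrum_offsets <- function(max_ppm = 5, step = 0.2) {
  pos <- seq(step, max_ppm, by = step)
  c(rev(-pos), 0, pos)
}

#' @export
print.cest_pool <- function(x, ...) {
  cat(sprintf("<cest_pool> %s: %+.2f ppm, %.1f mM protons, k = %g /s, T1 = %g s, T2 = %g s\n",
              x$name, x$chemical_shift, x$proton_concentration,
              x$exchange_rate, x$T1, x$T2))
  invisible(x)
}

#' @export
print.saturation_scheme <- function(x, ...) {
  cat(sprintf("<saturation_scheme> %d x %g ms pulses (duty %.4f) at B1 = %g Hz; %d offsets; recovery %g s\n",
              x$pulse_count, 1e3 * x$pulse_duration, x$duty_cycle, x$peak_b1,
              length(x$offsets), x$recovery_delay))
  invisible(x)
}
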