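#' Physical constants and unit conversions
#'
#' All quantities in the package use eV (energy), Angstrom (length),
#' amu (mass), ps (time), K (temperature) and degrees (angles).
#' `k_boltzmann` is the Boltzmann constant in eV/K. `ev_per_kjmol_nm`
#' converts a force quoted in kJ mol^-1 nm^-1 (the usual MD unit for a
#' steering force) into eV/Angstrom.
#'
#' @format A named list with elements `k_boltzmann` (eV/K),
#'   `ev_per_kjmol` (eV per kJ/mol), `time_unit_fs` (the internal
#'   dynamics time unit sqrt(amu * A^2 / eV) expressed in fs).
#' @examples
#' physical_constants$k_boltzmann * 310  # thermal energy at body temperature
#' @export
physical_constants <- list(
  k_boltzmann  = 8.617333262e-5,          # eV/K
  ev_per_kjmol = 1 / 96.48533212331,      # 1 kJ/mol in eV
  time_unit_fs = 10.180505710774743       # sqrt(amu A^2 / eV) in fs
)

#' Convert a steering force from kJ mol^-1 nm^-1 to eV per Angstrom
#'
#' @param f Force in kJ mol^-1 nm^-1.
#' @return Force in eV/Angstrom.
#' @examples
#' force_kjmolnm_to_ev_a(25)  # ~0.025911
#' @export
force_kjmolnm_to_ev_a <- function(f) {
  f * physical_constants$ev_per_kjmol / 10
}

#' Temperature at which thermal energy matches a barrier
#'
#' Inverts E = kB * T: the temperature whose thermal energy equals a given
#' barrier height, used as a coarse bound on when a trapped state can escape.
#'
#' @param energy Barrier height in eV, must be >= 0.
#' @return Temperature in K.
#' @examples
#' barrier_temperature(0.0267)  # close to 310 K
#' @export
barrier_temperature <- function(energy) {
  stopifnot(is.numeric(energy))
  if (any(energy < 0)) stop("barrier_temperature(): energy must be non-negative")
  energy / physical_constants$k_boltzmann
}

#' Minimum tautomer lifetime implied by a separation speed
#'
#' Time for the strands to reach a critical separation at a given speed;
#' a tautomer formed at the onset of separation must outlive this time to
#' be carried past the point of no return.
#'
#' @param d_critical Critical separation distance in Angstrom.
#' @param separation_speed Separation speed in Angstrom/ps, must be > 0.
#' @return Lifetime in ps.
#' @examples
#' min_lifetime(2.0, 1.25)  # 1.6 ps
#' @export
min_lifetime <- function(d_critical, separation_speed) {
  stopifnot(is.numeric(d_critical), is.numeric(separation_speed))
  if (any(separation_speed <= 0)) {
    stop("min_lifetime(): separation_speed must be positive")
  }
  d_critical / separation_speed
}
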