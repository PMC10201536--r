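#' Calibration parameters of the model proton-transfer surface
#'
#' Bundles the full calibration of the surrogate double-proton-transfer
#' surface as functions of the strand-separation distance d. Step 1 is the
#' transfer of the B2 proton (thymine donates, producing the zwitterion
#' A+/T-); step 2 is the transfer of the B1 proton (producing the neutral
#' tautomer A*/T*). The step-1 reverse barrier follows a power law
#' `Er1(d) = step1_reverse_base + step1_reverse_prefactor * d^step1_exponent`;
#' both reaction asymmetries are linear in d; the step-2 reverse barrier is
#' `step2_slope * (d - step2_onset)` and is reported as unbound when it does
#' not exceed `stability_epsilon`.
#'
#' The numeric defaults are package calibration conventions chosen to
#' reproduce the qualitative landscape orderings (zwitterion metastable at
#' every separation, no double-transfer well at the first two grid
#' increments, a well from 0.444 Angstrom on, second barrier far below the
#' first, quasi-linear asymmetries); only the power-law exponents carry the
#' literature values for A-T and G-C.
#'
#' @param preset "AT" (exponent 1.894) or "GC" (exponent 1.783).
#' @param step1_reverse_base eV; step-1 reverse barrier at d = 0.
#' @param step1_reverse_prefactor eV * A^-p; growth prefactor.
#' @param step1_exponent dimensionless power-law exponent p.
#' @param step2_slope eV/A; growth rate of the step-2 reverse barrier.
#' @param step2_onset A; separation at which the step-2 well would appear.
#' @param spt_asymmetry_intercept,spt_asymmetry_slope eV and eV/A; linear law
#'   for the single-transfer (zwitterion) asymmetry.
#' @param dpt_asymmetry_intercept,dpt_asymmetry_slope eV and eV/A; linear law
#'   for the double-transfer (tautomer) asymmetry.
#' @param sequential_penalty eV; quadratic penalty that suppresses B1 proton
#'   transfer before the B2 proton has moved (enforces the stepwise
#'   mechanism).
#' @param stability_epsilon eV; a well shallower than this is reported as
#'   "no stable minimum".
#' @return An object of class `surface_params` (a validated named list).
#' @examples
#' p <- surface_params("AT")
#' p$step1_exponent
#' @export
surface_params <- function(preset = c("AT", "GC"),
                           step1_reverse_base = 0.10,
                           step1_reverse_prefactor = 0.70,
                           step1_exponent = NULL,
                           step2_slope = 0.50,
                           step2_onset = 0.30,
                           spt_asymmetry_intercept = 0.55,
                           spt_asymmetry_slope = 0.25,
                           dpt_asymmetry_intercept = 0.45,
                           dpt_asymmetry_slope = 0.35,
                           sequential_penalty = 3.0,
                           stability_epsilon = 0.005) {
  preset <- match.arg(preset)
  if (is.null(step1_exponent)) {
    step1_exponent <- if (preset == "AT") 1.894 else 1.783
  }
  p <- list(
    preset_label = preset,
    step1_reverse_base = step1_reverse_base,
    step1_reverse_prefactor = step1_reverse_prefactor,
    step1_exponent = step1_exponent,
    step2_slope = step2_slope,
    step2_onset = step2_onset,
    spt_asymmetry_intercept = spt_asymmetry_intercept,
    spt_asymmetry_slope = spt_asymmetry_slope,
    dpt_asymmetry_intercept = dpt_asymmetry_intercept,
    dpt_asymmetry_slope = dpt_asymmetry_slope,
    sequential_penalty = sequential_penalty,
    stability_epsilon = stability_epsilon
  )
  class(p) <- "surface_params"
  validate_surface_params(p)
  p
}

validate_surface_params <- function(p) {
  num <- setdiff(names(p), "preset_label")
  ok <- vapply(p[num], function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
               logical(1))
  if (!all(ok)) {
    stop("surface_params: non-numeric field(s): ", paste(num[!ok], collapse = ", "))
  }
  if (!p$preset_label %in% c("AT", "GC")) stop("surface_params: preset_label must be AT or GC")
  pos <- c("step1_reverse_base", "step1_reverse_prefactor", "step1_exponent",
           "step2_slope", "sequential_penalty", "stability_epsilon")
  bad <- pos[vapply(pos, function(f) p[[f]] <= 0, logical(1))]
  if (length(bad)) stop("surface_params: field(s) must be positive: ", paste(bad, collapse = ", "))
  if (p$step2_onset < 0) stop("surface_params: step2_onset must be >= 0")
  invisible(p)
}

#' @export
print.surface_params <- function(x, ...) {
  cat("<surface_params> preset", x$preset_label, "\n")
  cat(sprintf("  Er1(d) = %.3f + %.3f d^%.3f eV\n",
              x$step1_reverse_base, x$step1_reverse_prefactor, x$step1_exponent))
  cat(sprintf("  Er2(d) = %.3f (d - %.3f) eV; unbound below %.3f eV\n",
              x$step2_slope, x$step2_onset, x$stability_epsilon))
  cat(sprintf("  A_spt(d) = %.3f + %.3f d; A_dpt(d) = %.3f + %.3f d eV\n",
              x$spt_asymmetry_intercept, x$spt_asymmetry_slope,
              x$dpt_asymmetry_intercept, x$dpt_asymmetry_slope))
  invisible(x)
}

#' Parameters of the coarse-grained duplex model
#'
#' Mechanical description of a double-stranded DNA ladder: each nucleotide is
#' a stiff triangle of three beads (backbone attachment, B1 hydrogen-bond
#' site, B2 hydrogen-bond site), inter-strand hydrogen bonds are breakable
#' Morse bonds, and consecutive backbone beads on a strand are joined by
#' stacking springs. B1 is the stronger of the two hydrogen bonds.
#'
#' @param n_pairs Number of base pairs (>= 2).
#' @param morse_depth_B1,morse_depth_B2 Morse well depths, eV; B1 must be
#'   deeper than B2.
#' @param morse_width Morse width parameter, 1/Angstrom.
#' @param hbond_eq_length Equilibrium hydrogen-bond (heavy-atom) length, A.
#' @param stacking_k Stacking spring constant, eV/A^2.
#' @param lever_arm Distance between the B1 and B2 attachment sites on one
#'   base, A; sets the lever converting differential bond extension into an
#'   opening angle.
#' @param bead_mass Mass of one nucleotide, amu (split evenly over its beads).
#' @param temperature Thermostat temperature, K.
#' @param friction Langevin friction, 1/ps.
#' @param timestep Integration time step, ps.
#' @return An object of class `duplex_params`.
#' @examples
#' duplex_params(n_pairs = 4)
#' @export
duplex_params <- function(n_pairs = 14,
                          morse_depth_B1 = 0.28,
                          morse_depth_B2 = 0.22,
                          morse_width = 2.0,
                          hbond_eq_length = 2.9,
                          stacking_k = 2.0,
                          lever_arm = 4.5,
                          bead_mass = 150,
                          temperature = 310,
                          friction = 1.0,
                          timestep = 0.001) {
  p <- list(
    n_pairs = as.integer(n_pairs), morse_depth_B1 = morse_depth_B1,
    morse_depth_B2 = morse_depth_B2, morse_width = morse_width,
    hbond_eq_length = hbond_eq_length, stacking_k = stacking_k,
    lever_arm = lever_arm, bead_mass = bead_mass, temperature = temperature,
    friction = friction, timestep = timestep
  )
  class(p) <- "duplex_params"
  validate_duplex_params(p)
  p
}

validate_duplex_params <- function(p) {
  if (p$n_pairs < 2) stop("duplex_params: n_pairs must be >= 2")
  if (p$morse_depth_B1 <= p$morse_depth_B2) {
    stop("duplex_params: morse_depth_B1 must exceed morse_depth_B2 (B1 is the stronger bond)")
  }
  pos <- c("morse_depth_B1", "morse_depth_B2", "morse_width", "hbond_eq_length",
           "stacking_k", "lever_arm", "bead_mass", "temperature", "friction",
           "timestep")
  bad <- pos[vapply(pos, function(f) !is.numeric(p[[f]]) || p[[f]] <= 0, logical(1))]
  if (length(bad)) stop("duplex_params: field(s) must be positive: ", paste(bad, collapse = ", "))
  invisible(p)
}

#' @export
print.duplex_params <- function(x, ...) {
  cat("<duplex_params>", x$n_pairs, "bp; Morse depths B1/B2 =",
      x$morse_depth_B1, "/", x$morse_depth_B2, "eV;",
      x$temperature, "K;", x$timestep * 1000, "fs step\n")
  invisible(x)
}

#' Separation-scan protocol configuration
#'
#' @param increment_spacing Spacing between imposed separations, A.
#' @param n_increments Number of increments (the first is d = 0).
#' @param ts_scan_limit Number of increments used for transition-state
#'   (path-search) scans.
#' @param force_tolerance Relaxation force tolerance, eV/A.
#' @param max_steps Maximum relaxation steps per increment.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(increment_spacing = 0.222,
                        n_increments = 13,
                        ts_scan_limit = min(8, n_increments),
                        force_tolerance = 0.01,
                        max_steps = 500) {
  if (increment_spacing <= 0) stop("scan_config: increment_spacing must be positive")
  if (force_tolerance <= 0) stop("scan_config: force_tolerance must be positive")
  if (ts_scan_limit > n_increments) stop("scan_config: ts_scan_limit must be <= n_increments")
  structure(list(increment_spacing = increment_spacing,
                 n_increments = as.integer(n_increments),
                 ts_scan_limit = as.integer(ts_scan_limit),
                 force_tolerance = force_tolerance,
                 max_steps = as.integer(max_steps)),
            class = "scan_config")
}

#' Surrogate-accelerated path-search configuration
#'
#' @param n_images Number of path images, including endpoints.
#' @param force_tolerance Perpendicular-force convergence tolerance
#'   (eV per unit reduced coordinate).
#' @param uncertainty_tolerance Maximum admissible surrogate predictive
#'   standard deviation along the path, eV.
#' @param max_true_evaluations Budget of true-model evaluations.
#' @param seed Integer seed recorded in the evaluation log.
#' @param climbing_image Let the highest image converge onto the saddle.
#' @param spring_k NEB spring constant (eV per unit coordinate^2).
#' @return An object of class `mlneb_config`.
#' @export
mlneb_config <- function(n_images = 15,
                         force_tolerance = 0.01,
                         uncertainty_tolerance = 0.02,
                         max_true_evaluations = 200,
                         seed = 1L,
                         climbing_image = TRUE,
                         spring_k = 1.0) {
  if (n_images < 3) stop("mlneb_config: n_images must be >= 3")
  if (force_tolerance <= 0 || uncertainty_tolerance <= 0) {
    stop("mlneb_config: tolerances must be positive")
  }
  structure(list(n_images = as.integer(n_images),
                 force_tolerance = force_tolerance,
                 uncertainty_tolerance = uncertainty_tolerance,
                 max_true_evaluations = as.integer(max_true_evaluations),
                 seed = as.integer(seed),
                 climbing_image = isTRUE(climbing_image),
                 spring_k = spring_k),
            class = "mlneb_config")
}

#' Constant-force steering protocol
#'
#' @param force Steering force magnitude in kJ mol^-1 nm^-1 (the
#'   conventional MD unit); converted internally to eV/A.
#' @param target_pair Index of the pulled base pair (default 1, the
#'   terminal pair).
#' @param equilibration_time,production_time ps.
#' @param n_replicas Number of independent replicas.
#' @param seed Base seed; replica seeds are `seed + replica index`.
#' @param sampling_interval ps between recorded frames.
#' @return An object of class `steering_protocol`.
#' @export
steering_protocol <- function(force = 25,
                              target_pair = 1L,
                              equilibration_time = 500,
                              production_time = 200,
                              n_replicas = 8L,
                              seed = 1L,
                              sampling_interval = 0.01) {
  if (force < 0) stop("steering_protocol: force must be >= 0")
  if (equilibration_time <= 0 || production_time <= 0) {
    stop("steering_protocol: times must be positive")
  }
  structure(list(force = force,
                 force_ev_a = force_kjmolnm_to_ev_a(force),
                 target_pair = as.integer(target_pair),
                 equilibration_time = equilibration_time,
                 production_time = production_time,
                 n_replicas = as.integer(n_replicas),
                 seed = as.integer(seed),
                 sampling_interval = sampling_interval),
            class = "steering_protocol")
}
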