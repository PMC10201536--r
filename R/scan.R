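# Reduced-coordinate model of one base pair under imposed separation.
#
# State vector: (px_A, px_T, phi_A, phi_T, q1, q2) — the two backbone pivot
# positions along the opening axis (frozen during relaxation), the rotation
# angle of each base about its pivot, and the two proton-transfer
# coordinates. Each base is a rigid arm carrying its B1 site (upper) and B2
# site (lower); rotation lets the two hydrogen bonds extend at different
# rates, which is what produces the signed opening angle. A harmonic
# rotational restraint stands in for the stacking/steric forces that pull a
# base back into the duplex plane once its hydrogen bonds have let go.

#' Build the base-pair scan model at a fixed separation
#'
#' @param params A [duplex_params()] object (supplies Morse depths, width,
#'   equilibrium bond length and the lever arm).
#' @param surface A [surface_params()] object for the proton coordinates.
#' @param d Imposed separation, Angstrom.
#' @param form "canonical" or "tautomeric". The tautomeric form carries a
#'   stronger B1 bond (depth scaled by `taut_b1_scale`); where the tautomer
#'   well is unbound the zwitterionic product is used instead.
#' @param rot_k Rotational restraint stiffness, eV/rad^2.
#' @param taut_b1_scale Multiplier on the B1 Morse depth in the tautomeric
#'   form.
#' @param base_depth Pivot to bond-site distance, Angstrom.
#' @return Model list with `energy(x)`, `gradient(x)` (finite-difference),
#'   `start` (suggested start vector), `geometry(x)` returning bond
#'   lengths/extensions and theta, and metadata.
#' @export
pair_scan_model <- function(params = duplex_params(),
                            surface = surface_params("AT"),
                            d = 0, form = c("canonical", "tautomeric"),
                            rot_k = 0.8, taut_b1_scale = 1.3,
                            base_depth = .duplex_base_depth) {
  form <- match.arg(form)
  hb <- params$hbond_eq_length; w <- params$lever_arm
  px0 <- hb / 2 + base_depth
  smod <- surface_model(surface, d)
  bound <- smod$dpt_bound
  D1 <- params$morse_depth_B1 * if (form == "tautomeric" && bound) taut_b1_scale else 1
  D2 <- params$morse_depth_B2
  a <- params$morse_width

  sites <- function(x) {
    pxA <- x[1]; pxT <- x[2]; phiA <- x[3]; phiT <- x[4]
    rot <- function(phi, v) c(cos(phi) * v[1] - sin(phi) * v[2],
                              sin(phi) * v[1] + cos(phi) * v[2])
    # arm vectors from pivot to bond sites (x = bond axis, z = stack axis)
    a1 <- c(pxA, 0) + rot(phiA, c(base_depth,  w / 2))
    a2 <- c(pxA, 0) + rot(phiA, c(base_depth, -w / 2))
    t1 <- c(pxT, 0) + rot(phiT, c(-base_depth,  w / 2))
    t2 <- c(pxT, 0) + rot(phiT, c(-base_depth, -w / 2))
    list(a1 = a1, a2 = a2, t1 = t1, t2 = t2,
         r1 = sqrt(sum((a1 - t1)^2)), r2 = sqrt(sum((a2 - t2)^2)))
  }

  energy <- function(x) {
    s <- sites(x)
    morse_energy(s$r1, D1, a, hb) + morse_energy(s$r2, D2, a, hb) +
      0.5 * rot_k * (x[3]^2 + x[4]^2) + smod$energy(x[5:6])
  }
  gradient <- function(x) {
    h <- 1e-6
    vapply(seq_along(x), function(i) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      (energy(xp) - energy(xm)) / (2 * h)
    }, numeric(1))
  }
  geometry <- function(x) {
    s <- sites(x)
    e1 <- s$r1 - hb; e2 <- s$r2 - hb
    tibble::tibble(B1_length = s$r1, B2_length = s$r2,
                   B1_extension = e1, B2_extension = e2,
                   theta = opening_angle(e1, e2, w))
  }
  qstart <- if (form == "canonical") c(0, 0) else if (bound) c(1, 1) else c(0, 1)
  start <- c(-(px0 + d / 2), px0 + d / 2, 0, 0, qstart)
  # basin box bounds on the proton coordinates: the scan tracks one
  # configuration, so the relaxation must not hop a low barrier into a
  # neighbouring (deeper) well
  qbox <- function(q) if (q < 0.5) c(-0.2, 0.5) else c(0.5, 1.2)
  b1 <- qbox(qstart[1]); b2 <- qbox(qstart[2])
  lower <- c(-Inf, -Inf, -Inf, -Inf, b1[1], b2[1])
  upper <- c( Inf,  Inf,  Inf,  Inf, b1[2], b2[2])
  list(energy = energy, gradient = gradient, geometry = geometry,
       start = start, d = d, form = form, bound = bound,
       lower = lower, upper = upper,
       surface = smod, params = params)
}

#' Run the constrained separation scan
#'
#' Imposes the separation across `n_increments` systematic increments of
#' `increment_spacing` (default 0.222 A, giving the landmark grid 0, 0.222,
#' 0.444, ...). At each increment the pivot positions are frozen at
#' plus/minus d/2 and all remaining coordinates (base rotations and proton
#' coordinates) are relaxed by L-BFGS to the configured force tolerance,
#' continuing from the previous increment's relaxed state. Geometry
#' observables are computed per record.
#'
#' For the tautomeric form at increments where the double-transfer well is
#' unbound, the record is a flagged placeholder relaxed in the zwitterionic
#' (single-transfer) product instead, with `bound_flag = FALSE`.
#'
#' @param config A [scan_config()].
#' @param params A [duplex_params()] for the mechanical pair model.
#' @param surface A [surface_params()] for the proton landscape.
#' @param form "canonical" or "tautomeric".
#' @param ... Passed to [pair_scan_model()] (e.g. `rot_k`).
#' @return A tibble of class `separation_scan`, one row per increment:
#'   `d`, `B1_extension`, `B2_extension`, `theta` (degrees), `energy` (eV),
#'   `grad_norm`, `phi_A`, `phi_T`, `q1`, `q2`, `form`, `bound_flag`.
#' @examples
#' \donttest{
#' run_separation_scan(scan_config(n_increments = 3))
#' }
#' @export
run_separation_scan <- function(config = scan_config(),
                                params = duplex_params(),
                                surface = surface_params("AT"),
                                form = c("canonical", "tautomeric"), ...) {
  form <- match.arg(form)
  stopifnot(inherits(config, "scan_config"))
  d_grid <- (seq_len(config$n_increments) - 1) * config$increment_spacing
  prev <- NULL
  rows <- vector("list", length(d_grid))
  for (k in seq_along(d_grid)) {
    d <- d_grid[k]
    model <- pair_scan_model(params, surface, d = d, form = form, ...)
    x0 <- model$start
    if (!is.null(prev)) {
      # continuation: keep relaxed angles/protons, move the pivots
      x0[3:6] <- prev[3:6]
      # when the tautomer well first binds, hop the proton state across
      if (form == "tautomeric" && model$bound && prev[5] < 0.5) x0[5] <- 1
    }
    res <- tryCatch(
      relax_constrained(x0, fixed = 1:2, model = model,
                        tol = config$force_tolerance,
                        max_steps = config$max_steps,
                        lower = model$lower, upper = model$upper),
      error = function(e) stop("separation scan failed at d = ", d, " A: ",
                               conditionMessage(e)))
    prev <- res$x
    geo <- model$geometry(res$x)
    rows[[k]] <- dplyr::bind_cols(
      tibble::tibble(d = d), geo,
      tibble::tibble(energy = res$energy, grad_norm = res$grad_norm,
                     phi_A = res$x[3], phi_T = res$x[4],
                     q1 = res$x[5], q2 = res$x[6],
                     form = form, bound_flag = model$bound | form == "canonical"))
  }
  out <- dplyr::bind_rows(rows)
  # energies relative to the first (equilibrium) increment
  out$energy <- out$energy - out$energy[1]
  class(out) <- c("separation_scan", class(out))
  attr(out, "config") <- config
  out
}
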