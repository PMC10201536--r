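#' Surface state: one point on the proton-transfer landscape
#'
#' A point is described by two dimensionless transfer-progress coordinates
#' and the strand-separation distance: `(q1, q2) = (0, 0)` is the canonical
#' Watson-Crick pair, `(0, 1)` the zwitterion (B2 proton transferred),
#' `(1, 1)` the neutral tautomer (both protons transferred). `d = 0` is the
#' equilibrium separation.
#'
#' @param q1 B1-proton transfer progress, in `[-0.2, 1.2]`.
#' @param q2 B2-proton transfer progress, in `[-0.2, 1.2]`.
#' @param d Strand-separation distance, Angstrom, >= 0.
#' @return An object of class `surface_state`.
#' @examples
#' surface_state(0, 1, d = 0.444)  # the zwitterion at the third increment
#' @export
surface_state <- function(q1, q2, d) {
  stopifnot(is.numeric(q1), is.numeric(q2), is.numeric(d),
            length(q1) == 1, length(q2) == 1, length(d) == 1)
  if (d < 0) stop("surface_state: d must be >= 0")
  structure(list(q1 = q1, q2 = q2, d = d), class = "surface_state")
}

# coordinate bounds of the physical region; quadratic walls outside keep
# optimizers in range when they overshoot
.q_lo <- -0.2
.q_hi <- 1.2
.wall_k <- 10       # eV per unit^2
.unbound_ramp <- 1  # eV; quadratic cost of B1 transfer when no tautomer well

# switch between the "B2 proton not yet moved" and "B2 proton moved"
# branches of the surface: quintic smoothstep, clamped to [0, 1]. The
# clamped quintic is C^2 everywhere (its first and second derivatives
# vanish at both ends), stays bounded outside the physical box, and its
# flat ends decouple the penalty term from both proton wells.
smoothstep <- function(q) {
  q <- pmin(pmax(q, 0), 1)
  q^3 * (10 - 15 * q + 6 * q^2)
}
smoothstep_deriv <- function(q) {
  ifelse(q <= 0 | q >= 1, 0, {
    qc <- pmin(pmax(q, 0), 1)
    30 * qc^2 * (1 - qc)^2
  })
}

check_surface_coords <- function(q1, q2) {
  if (q1 < .q_lo || q1 > .q_hi) {
    stop("coordinate q1 = ", format(q1), " outside [", .q_lo, ", ", .q_hi, "]")
  }
  if (q2 < .q_lo || q2 > .q_hi) {
    stop("coordinate q2 = ", format(q2), " outside [", .q_lo, ", ", .q_hi, "]")
  }
  invisible(TRUE)
}

#' Per-separation barrier and asymmetry targets of the calibration
#'
#' Evaluates the calibration laws at one or more separations: the step-1
#' (B2 proton) reverse barrier power law, the linear single- and
#' double-transfer asymmetries, and the step-2 (B1 proton) barriers. The
#' step-2 well is flagged unbound whenever its reverse barrier does not
#' exceed `stability_epsilon` (and, as a guard against an unrealisable well,
#' whenever its forward barrier does not either); unbound rows carry NA
#' barriers.
#'
#' @param d Strand separation(s), Angstrom, >= 0. Vectorized.
#' @param params A [surface_params()] object.
#' @return A tibble with columns `d`, `Ef1`, `Er1`, `Ef2`, `Er2`, `A_spt`,
#'   `A_dpt`, `dpt_bound`.
#' @examples
#' barrier_targets(c(0, 0.222, 0.444), surface_params("AT"))
#' @export
barrier_targets <- function(d, params = surface_params("AT")) {
  stopifnot(inherits(params, "surface_params"), all(d >= 0))
  er1 <- params$step1_reverse_base + params$step1_reverse_prefactor * d^params$step1_exponent
  a_spt <- params$spt_asymmetry_intercept + params$spt_asymmetry_slope * d
  a_dpt <- params$dpt_asymmetry_intercept + params$dpt_asymmetry_slope * d
  ef1 <- a_spt + er1
  er2_raw <- params$step2_slope * (d - params$step2_onset)
  ef2_raw <- (a_dpt + er2_raw) - a_spt
  eps <- params$stability_epsilon
  bound <- er2_raw > eps & ef2_raw > eps
  tibble::tibble(
    d = d, Ef1 = ef1, Er1 = er1,
    Ef2 = ifelse(bound, ef2_raw, NA_real_),
    Er2 = ifelse(bound, er2_raw, NA_real_),
    A_spt = a_spt, A_dpt = a_dpt, dpt_bound = bound
  )
}

#' Materialize the model surface at a fixed separation
#'
#' Calibrates both proton-transfer steps at separation `d` (exact stationary
#' analysis of each tilted quartic, via [calibrate_tilted_quartic()]) and
#' returns a model object with fast `energy(q)` / `gradient(q)` functions in
#' the reduced coordinates `q = c(q1, q2)`. These internal evaluators apply
#' quadratic walls outside the physical box `[-0.2, 1.2]^2` instead of
#' erroring, so optimizers and path searches can overshoot safely; the
#' exported [potential_energy()] enforces the bounds strictly.
#'
#' The functional form is
#' `V(q1, q2) = S(q2; h1, delta1) + s(q2) T2(q1) + (1 - s(q2)) P q1^2`
#' with the clamped quintic smoothstep switch
#' `s(q) = q^3 (10 - 15 q + 6 q^2)` on `[0, 1]`: the B1 proton sees its
#' own step potential `T2` only once the B2 proton has moved, and a stiff
#' quadratic penalty `P q1^2` otherwise. This enforces the asynchronous
#' stepwise mechanism (B2 proton first). When the step-2 well is unbound,
#' `T2` is a smooth quadratic ramp with no product well.
#'
#' @param params A [surface_params()] object.
#' @param d Strand separation, Angstrom.
#' @return An object of class `surface_model`: list with `d`, `params`,
#'   `targets` (one-row tibble), calibrations `cal1`/`cal2`, and functions
#'   `energy`, `gradient`.
#' @examples
#' m <- surface_model(surface_params("AT"), d = 0.444)
#' m$energy(c(0, 0))
#' @export
surface_model <- function(params, d) {
  stopifnot(inherits(params, "surface_params"), length(d) == 1, d >= 0)
  tg <- barrier_targets(d, params)
  cal1 <- calibrate_tilted_quartic(tg$Ef1, tg$Er1)
  bound <- tg$dpt_bound
  cal2 <- if (bound) calibrate_tilted_quartic(tg$Ef2, tg$Er2) else NULL
  h1 <- cal1$h; d1 <- cal1$delta
  P <- params$sequential_penalty
  cu <- .unbound_ramp
  if (bound) { h2 <- cal2$h; d2 <- cal2$delta }

  wall <- function(q) {
    lo <- pmin(q - .q_lo, 0); hi <- pmax(q - .q_hi, 0)
    .wall_k * sum(lo^2 + hi^2)
  }
  wall_grad <- function(q) {
    2 * .wall_k * (pmin(q - .q_lo, 0) + pmax(q - .q_hi, 0))
  }

  energy <- function(q) {
    q1 <- q[1]; q2 <- q[2]
    s <- smoothstep(q2)
    t2 <- if (bound) tilted_quartic(q1, h2, d2) else cu * q1^2
    tilted_quartic(q2, h1, d1) + s * t2 + (1 - s) * P * q1^2 + wall(q)
  }
  gradient <- function(q) {
    q1 <- q[1]; q2 <- q[2]
    s <- smoothstep(q2)
    sp <- smoothstep_deriv(q2)
    if (bound) {
      t2 <- tilted_quartic(q1, h2, d2); t2p <- tilted_quartic_deriv(q1, h2, d2)
    } else {
      t2 <- cu * q1^2; t2p <- 2 * cu * q1
    }
    g1 <- s * t2p + (1 - s) * 2 * P * q1
    g2 <- tilted_quartic_deriv(q2, h1, d1) + sp * (t2 - P * q1^2)
    c(g1, g2) + wall_grad(q)
  }

  structure(list(d = d, params = params, targets = tg, cal1 = cal1,
                 cal2 = cal2, dpt_bound = bound,
                 energy = energy, gradient = gradient),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat("<surface_model>", x$params$preset_label, "at d =", x$d, "A;",
      if (x$dpt_bound) "tautomer well bound" else "tautomer well unbound", "\n")
  invisible(x)
}

#' Potential energy of a surface state
#'
#' Energy in eV relative to the canonical reference `V(0, 0, d) = 0` at the
#' same separation. Errors if a coordinate leaves the physical region
#' `[-0.2, 1.2]`, naming the offending coordinate.
#'
#' @param state A [surface_state()].
#' @param params A [surface_params()] object.
#' @param model Optional pre-built [surface_model()] at `state$d` (avoids
#'   re-calibration in tight loops).
#' @return Energy, eV.
#' @examples
#' potential_energy(surface_state(0, 0, 0.444))
#' @export
potential_energy <- function(state, params = surface_params("AT"), model = NULL) {
  stopifnot(inherits(state, "surface_state"))
  check_surface_coords(state$q1, state$q2)
  if (is.null(model)) model <- surface_model(params, state$d)
  model$energy(c(state$q1, state$q2))
}

#' Gradient of the surface energy in the transfer coordinates
#'
#' @inheritParams potential_energy
#' @return Numeric vector `c(dV/dq1, dV/dq2)`, eV per unit coordinate.
#' @examples
#' surface_gradient(surface_state(0.5, 0.5, 1.0))
#' @export
surface_gradient <- function(state, params = surface_params("AT"), model = NULL) {
  stopifnot(inherits(state, "surface_state"))
  check_surface_coords(state$q1, state$q2)
  if (is.null(model)) model <- surface_model(params, state$d)
  model$gradient(c(state$q1, state$q2))
}

#' Evaluate the surface over a table of states
#'
#' Tidy vectorized wrapper: takes a data frame with columns `q1`, `q2`, `d`
#' and appends the energy (and optionally the gradient components).
#'
#' @param states Data frame with columns `q1`, `q2`, `d`.
#' @param params A [surface_params()] object.
#' @param gradient Also compute gradient components?
#' @return The input as a tibble with `energy` (and `g1`, `g2`) appended.
#' @export
evaluate_surface <- function(states, params = surface_params("AT"), gradient = FALSE) {
  stopifnot(all(c("q1", "q2", "d") %in% names(states)))
  states <- tibble::as_tibble(states)
  models <- lapply(unique(states$d), function(dd) surface_model(params, dd))
  names(models) <- as.character(unique(states$d))
  rows <- purrr::pmap(states[c("q1", "q2", "d")], function(q1, q2, d) {
    m <- models[[as.character(d)]]
    e <- m$energy(c(q1, q2))
    if (gradient) {
      g <- m$gradient(c(q1, q2))
      tibble::tibble(energy = e, g1 = g[1], g2 = g[2])
    } else tibble::tibble(energy = e)
  })
  dplyr::bind_cols(states, dplyr::bind_rows(rows))
}
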