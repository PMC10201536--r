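#' Relax the three characteristic states of the surface at separation d
#'
#' Basin-restricted quasi-Newton relaxation of the canonical, zwitterionic
#' and tautomeric configurations on the model surface. Where the tautomer
#' well is unbound, relaxing from the nominal tautomer start slides into
#' the zwitterion basin, which is exactly how the pipeline discovers that
#' the double-transfer product does not exist at that separation.
#'
#' @param model A [surface_model()].
#' @param which One of "canonical", "zwitterion", "tautomer".
#' @param tol Gradient-norm tolerance.
#' @return Relaxed coordinate vector `c(q1, q2)`.
#' @export
relax_surface_state <- function(model, which = c("canonical", "zwitterion",
                                                 "tautomer"),
                                tol = 1e-6) {
  which <- match.arg(which)
  # the 1-D calibration knows its stationary points analytically; seed the
  # 2-D relaxation there so only the (small) inter-step coupling remains
  q2_r <- model$cal1$stationary$q_reactant
  q2_p <- model$cal1$stationary$q_product
  if (which == "canonical") {
    q0 <- c(0, q2_r); lower <- c(-0.2, -0.2); upper <- c(0.3, 0.45)
  } else if (which == "zwitterion") {
    q0 <- c(0, q2_p); lower <- c(-0.2, 0.55); upper <- c(0.3, 1.2)
  } else if (model$dpt_bound) {
    q0 <- c(model$cal2$stationary$q_product, q2_p)
    lower <- c(0.5, 0.55); upper <- c(1.2, 1.2)
  } else {
    # no tautomer well: the nominal start slides down the ramp into the
    # zwitterion basin (there is no barrier along q1), which is how the
    # pipeline discovers the product does not exist at this separation
    q0 <- c(1, q2_p); lower <- c(-0.2, 0.55); upper <- c(1.2, 1.2)
  }
  relax_constrained(q0, integer(0), model, tol = tol, max_steps = 2000,
                    lower = lower, upper = upper)$x
}

#' Per-separation barrier analysis over the scan grid
#'
#' The analysis backbone of the pipeline: for each scanned separation the
#' canonical and product states are relaxed on the model surface, the
#' minimum energy path between them is converged (climbing-image elastic
#' band on the true surface by default, or the surrogate-accelerated
#' variant), barriers and asymmetries are read off the profile, and the
#' double-transfer stability is classified. The product endpoint is the
#' relaxed tautomer where it exists; where the relaxation slides into the
#' zwitterion basin the row is classified from the single-hump profile.
#'
#' @param params A [surface_params()] object.
#' @param d_grid Separations, Angstrom (default the scan grid restricted to
#'   the transition-state scan limit).
#' @param config An [mlneb_config()].
#' @param method "neb" (climbing-image band on the true surface) or "mlneb"
#'   (Gaussian-process surrogate acceleration).
#' @param epsilon Unbound threshold for classification, eV.
#' @return Tibble with one row per separation: the BarrierSet columns plus
#'   `classification` and `n_evaluations`.
#' @examples
#' \donttest{
#' barrier_table(surface_params("AT"), d_grid = c(0.222, 0.444))
#' }
#' @export
barrier_table <- function(params = surface_params("AT"),
                          d_grid = (seq_len(scan_config()$ts_scan_limit) - 1) *
                            scan_config()$increment_spacing,
                          config = mlneb_config(),
                          method = c("neb", "mlneb"),
                          epsilon = params$stability_epsilon) {
  method <- match.arg(method)
  rows <- lapply(d_grid, function(d) {
    model <- surface_model(params, d)
    ra <- relax_surface_state(model, "canonical")
    pr <- relax_surface_state(model, "tautomer")
    if (method == "mlneb") {
      run <- mlneb_run(ra, pr, model, config)
      path <- run$path; nev <- run$n_true_evaluations
    } else {
      path <- neb_relax(interpolate_path(ra, pr, config$n_images), model,
                        config)
      nev <- path$n_force_calls
    }
    bar <- extract_barriers(as_energy_profile(path), d = d,
                            prominence = epsilon)
    bar$classification <- classify_stability(bar, epsilon = epsilon)
    bar$n_evaluations <- nev
    bar
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("barrier_table", class(out))
  attr(out, "params") <- params
  out
}

#' Full landscape report: barriers, onset, power law, lifetime bounds
#'
#' Runs [barrier_table()] on the default grid and summarizes the paper-level
#' analytics: the onset separation of double-transfer stability, the
#' power-law exponent of the baseline-subtracted step-1 reverse barrier, the
#' minimum tautomer lifetime at the critical separation, and the temperature
#' equivalent of the largest reverse barrier.
#'
#' @inheritParams barrier_table
#' @param separation_speed Assumed strand-separation speed, Angstrom/ps.
#' @param d_critical Critical separation for the lifetime bound, Angstrom.
#' @return List of class `landscape_report`: `barriers` (tibble), `onset`
#'   (A), `power_law` (a [fit_power_law()] object on the calibration
#'   series), `min_lifetime` (ps), `barrier_temperature` (K).
#' @export
landscape_report <- function(params = surface_params("AT"),
                             d_grid = (seq_len(scan_config()$ts_scan_limit) - 1) *
                               scan_config()$increment_spacing,
                             config = mlneb_config(),
                             method = c("neb", "mlneb"),
                             separation_speed = 1.25, d_critical = 2.0) {
  method <- match.arg(method)
  bt <- barrier_table(params, d_grid = d_grid, config = config,
                      method = method)
  onset <- detect_onset(bt)
  # power law on the calibration series over the full default grid
  full_grid <- (seq_len(scan_config()$n_increments) - 1) *
    scan_config()$increment_spacing
  pl <- reverse_barrier_power_law(params, d_grid = full_grid[-1])
  er_max <- max(bt$Er1, na.rm = TRUE)
  structure(list(
    barriers = bt, onset = onset, power_law = pl,
    min_lifetime = min_lifetime(d_critical, separation_speed),
    barrier_temperature = barrier_temperature(er_max),
    params = params
  ), class = "landscape_report")
}

#' Power-law fit of the baseline-subtracted step-1 reverse barrier
#'
#' Generates the step-1 reverse barrier over the nonzero grid points from
#' the calibration, subtracts the d = 0 baseline (a pure power law must
#' vanish at zero separation, but the reverse barrier has a finite offset
#' there), and fits the exponent in log-log space.
#'
#' @param params A [surface_params()] object.
#' @param d_grid Nonzero separations, Angstrom. Default: grid points
#'   `k * 0.222` for `k = 1..9`, the range over which the scan analyses
#'   barriers.
#' @return A [fit_power_law()] object.
#' @examples
#' reverse_barrier_power_law(surface_params("AT"))$exponent
#' @export
reverse_barrier_power_law <- function(params = surface_params("AT"),
                                      d_grid = 0.222 * (1:9)) {
  stopifnot(all(d_grid > 0))
  tg <- barrier_targets(d_grid, params)
  base <- barrier_targets(0, params)$Er1
  fit_power_law(d_grid, tg$Er1 - base)
}

#' @export
print.landscape_report <- function(x, ...) {
  cat("<landscape_report>", x$params$preset_label, "preset\n")
  cat("  onset separation:", x$onset, "A\n")
  cat(sprintf("  reverse-barrier power law: exponent %.4f (R^2 %.5f)\n",
              x$power_law$exponent, x$power_law$r_squared))
  cat(sprintf("  minimum tautomer lifetime: %.3f ps\n", x$min_lifetime))
  cat(sprintf("  temperature equivalent of largest reverse barrier: %.3g K\n",
              x$barrier_temperature))
  invisible(x)
}
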