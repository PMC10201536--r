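# BAOAB Langevin splitting for the coarse-grained duplex.
#
# Internal dynamics units: Angstrom, eV, amu; the natural time unit is
# sqrt(amu A^2 / eV) ~ 10.18 fs, so user-facing times in ps are converted on
# entry. In the zero-friction, zero-noise limit the scheme reduces to
# velocity Verlet, which is what the energy-drift test exercises.
#
# The ladder model is planar: bases are plates in the pairing plane, so the
# out-of-plane (y) coordinate is frozen. This removes the azimuthal spin of
# a base about its bond-site axis, a mode the distance-spring topology
# cannot restrain without coupling the two bond sites to the stack
# asymmetrically.

.ps_to_internal <- function(t_ps) t_ps * 1000 / physical_constants$time_unit_fs

#' Integrate Langevin dynamics of a duplex
#'
#' BAOAB splitting: half-kick (B), half-drift (A), Ornstein-Uhlenbeck
#' velocity refresh (O), half-drift (A), half-kick (B). An optional
#' constant-magnitude steering force acts on the backbone beads of one
#' base pair, equal and opposite, along their current separation vector
#' (recomputed every step).
#'
#' @param sys A [build_duplex()] system.
#' @param coords Starting coordinates (defaults to the built equilibrium).
#' @param velocities Starting velocities (default: Maxwell-Boltzmann draw at
#'   the configured temperature, or zeros if `temperature = 0`).
#' @param time_ps Simulated time, ps.
#' @param temperature Thermostat temperature, K (0 disables noise).
#' @param friction Langevin friction, 1/ps (0 disables drag).
#' @param steering_force Force magnitude, eV/A (0 = plain dynamics).
#' @param target_pair Pulled base pair index.
#' @param sample_every_ps Observable sampling interval, ps.
#' @param seed Integer seed for the thermostat noise and initial velocities.
#' @return List of class `duplex_trajectory`: `frames` tibble (time series
#'   of per-pair observables at the target pair: `time`, `B1_extension`,
#'   `B2_extension`, `theta`, `separation`, plus energies), final `coords`,
#'   `velocities`, and metadata.
#' @export
integrate_duplex <- function(sys, coords = sys$coords, velocities = NULL,
                             time_ps = 10, temperature = sys$params$temperature,
                             friction = sys$params$friction,
                             steering_force = 0,
                             target_pair = 1L,
                             sample_every_ps = 0.01,
                             seed = 1L) {
  set.seed(seed)
  nsite <- nrow(coords)
  mass <- sys$masses
  dt <- .ps_to_internal(sys$params$timestep)
  gamma <- friction / .ps_to_internal(1)          # per internal time unit
  kbt <- physical_constants$k_boltzmann * temperature
  nsteps <- max(1L, round(time_ps / sys$params$timestep))
  sample_every <- max(1L, round(sample_every_ps / sys$params$timestep))

  if (is.null(velocities)) {
    velocities <- if (kbt > 0) {
      matrix(stats::rnorm(nsite * 3, sd = rep(sqrt(kbt / mass), 3)), nsite, 3)
    } else matrix(0, nsite, 3)
  }
  # planar model: freeze the out-of-plane coordinate
  velocities[, 2] <- 0

  # constant per-step OU coefficients
  c1 <- exp(-gamma * dt)
  c2 <- if (kbt > 0 && gamma > 0) sqrt((1 - c1^2) * kbt / mass) else rep(0, nsite)

  # steering bookkeeping: backbone beads of the target pair
  bb <- sys$sites$index[sys$sites$pair == target_pair & sys$sites$role == "bb"]
  stopifnot(length(bb) == 2)
  mo <- sys$morse
  tb1 <- which(mo$pair == target_pair & mo$label == "B1")
  tb2 <- which(mo$pair == target_pair & mo$label == "B2")
  hb <- sys$params$hbond_eq_length
  w <- sys$params$lever_arm

  total_force <- function(x) {
    f <- duplex_forces(sys, x)
    if (steering_force > 0) {
      u <- x[bb[1], ] - x[bb[2], ]
      u <- u / sqrt(sum(u^2))
      f[bb[1], ] <- f[bb[1], ] + steering_force * u
      f[bb[2], ] <- f[bb[2], ] - steering_force * u
    }
    f
  }

  n_samples <- nsteps %/% sample_every
  out_t <- numeric(n_samples); out_b1 <- numeric(n_samples)
  out_b2 <- numeric(n_samples); out_sep <- numeric(n_samples)
  out_pe <- numeric(n_samples); out_ke <- numeric(n_samples)
  si <- 0L

  x <- coords; v <- velocities
  f <- total_force(x)
  inv_m <- 1 / mass
  half <- dt / 2
  for (step in seq_len(nsteps)) {
    v <- v + half * f * inv_m
    x <- x + half * v
    if (gamma > 0) {
      v <- c1 * v + c2 * matrix(stats::rnorm(nsite * 3), nsite, 3)
      v[, 2] <- 0
    }
    x <- x + half * v
    f <- total_force(x)
    v <- v + half * f * inv_m
    if (step %% sample_every == 0) {
      si <- si + 1L
      e1 <- sqrt(sum((x[mo$i[tb1], ] - x[mo$j[tb1], ])^2)) - hb
      e2 <- sqrt(sum((x[mo$i[tb2], ] - x[mo$j[tb2], ])^2)) - hb
      out_t[si] <- step * sys$params$timestep
      out_b1[si] <- e1; out_b2[si] <- e2
      # separation of the pair = mean extension of its two bonds: the
      # analogue of the scan's summed pivot displacement, and insensitive
      # to rigid rotation of a whole strand about its bond-site column
      out_sep[si] <- (e1 + e2) / 2
      out_pe[si] <- duplex_energy(sys, x)
      out_ke[si] <- 0.5 * sum(mass * rowSums(v^2))
    }
  }
  if (!all(is.finite(x))) stop("integrate_duplex(): non-finite coordinates (integration blew up)")

  ratio <- (out_b2 - out_b1) / w
  theta <- ifelse(abs(ratio) <= 1, asin(pmax(-1, pmin(1, ratio))) * 180 / pi,
                  sign(ratio) * 90)
  frames <- tibble::tibble(
    time = out_t, B1_extension = out_b1, B2_extension = out_b2,
    theta = theta, separation = out_sep,
    potential_energy = out_pe, kinetic_energy = out_ke)
  structure(list(frames = frames, coords = x, velocities = v,
                 seed = seed, steering_force = steering_force,
                 target_pair = target_pair, params = sys$params),
            class = "duplex_trajectory")
}

#' Equilibrate a duplex in the NVT ensemble
#'
#' Langevin dynamics at the configured temperature with no steering force.
#' The returned state carries final coordinates and velocities; the
#' kinetic-temperature series over the sampled frames allows an
#' equipartition check.
#'
#' @param sys A [build_duplex()] system.
#' @param protocol A [steering_protocol()] (supplies the equilibration time
#'   and seed).
#' @return A `duplex_trajectory` (see [integrate_duplex()]).
#' @export
equilibrate <- function(sys, protocol = steering_protocol()) {
  traj <- integrate_duplex(
    sys, time_ps = protocol$equilibration_time,
    steering_force = 0, target_pair = protocol$target_pair,
    sample_every_ps = protocol$sampling_interval,
    seed = protocol$seed)
  if (!all(is.finite(traj$frames$potential_energy))) {
    stop("equilibrate(): non-finite energy during equilibration")
  }
  traj
}

#' Kinetic temperature of a trajectory
#'
#' Equipartition estimate `T = 2 <KE> / (n_dof kB)` over the last fraction
#' of the sampled frames; the planar model has 2 degrees of freedom per
#' bead.
#'
#' @param traj A `duplex_trajectory`.
#' @param n_sites Number of beads in the system.
#' @param last_fraction Fraction of the trajectory tail to average over.
#' @return Temperature, K.
#' @export
kinetic_temperature <- function(traj, n_sites, last_fraction = 0.5) {
  ke <- traj$frames$kinetic_energy
  tail_ke <- ke[seq.int(max(1, floor(length(ke) * (1 - last_fraction))), length(ke))]
  2 * mean(tail_ke) / (2 * n_sites * physical_constants$k_boltzmann)
}

#' Run a steered-separation replica ensemble
#'
#' For each replica: equilibrate without steering, then apply the constant
#' steering force to the terminal pair's backbone beads along their
#' center-of-mass separation vector and record per-frame observables.
#' Replica seeds are `protocol$seed + replica - 1`.
#'
#' @param sys A [build_duplex()] system.
#' @param protocol A [steering_protocol()].
#' @return Object of class `trajectory_ensemble`: tibble `frames` with a
#'   `replica` column, plus metadata.
#' @export
run_steered <- function(sys, protocol = steering_protocol()) {
  force_ev <- protocol$force_ev_a
  reps <- lapply(seq_len(protocol$n_replicas), function(r) {
    seed_r <- protocol$seed + r - 1L
    eq <- integrate_duplex(sys, time_ps = protocol$equilibration_time,
                           steering_force = 0,
                           target_pair = protocol$target_pair,
                           sample_every_ps = protocol$equilibration_time / 2,
                           seed = seed_r)
    prod <- integrate_duplex(sys, coords = eq$coords,
                             velocities = eq$velocities,
                             time_ps = protocol$production_time,
                             steering_force = force_ev,
                             target_pair = protocol$target_pair,
                             sample_every_ps = protocol$sampling_interval,
                             seed = seed_r + 100000L)
    dplyr::mutate(prod$frames, replica = r)
  })
  frames <- dplyr::bind_rows(reps)
  structure(list(frames = frames, protocol = protocol,
                 params = sys$params),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("<trajectory_ensemble>", max(x$frames$replica), "replicas,",
      nrow(x$frames), "frames; force", x$protocol$force,
      "kJ/mol/nm\n")
  invisible(x)
}

#' Classify which bond opens first in a replica
#'
#' @param frames Tibble with `B1_extension` and `B2_extension` series.
#' @param threshold Opening threshold on the bond extension, Angstrom.
#' @return "B1-first", "B2-first", or "none". A tie at the same sampled
#'   frame is resolved toward "B2-first" (the weaker bond).
#' @export
classify_opening_scenario <- function(frames, threshold = 0.5) {
  i1 <- match(TRUE, frames$B1_extension > threshold)
  i2 <- match(TRUE, frames$B2_extension > threshold)
  if (is.na(i1) && is.na(i2)) return("none")
  if (is.na(i2)) return("B1-first")
  if (is.na(i1)) return("B2-first")
  if (i1 < i2) "B1-first" else "B2-first"
}

#' Opening-angle histogram over a separation window
#'
#' Bins the opening angle of every frame whose separation lies inside the
#' window, partitioned by each replica's opening scenario. Positive angles
#' mean the pair opens from the B2 end.
#'
#' @param ensemble A [run_steered()] ensemble.
#' @param window Separation window (Angstrom), default 0 to 2.
#' @param breaks Bin edges, degrees.
#' @param threshold Scenario-classification threshold, Angstrom.
#' @return Object of class `angle_histogram`: tibble `counts` with columns
#'   `bin_mid`, `scenario`, `n`; plus `total_in_window`.
#' @export
angle_histogram <- function(ensemble, window = c(0, 2),
                            breaks = seq(-75, 75, by = 2.5),
                            threshold = 0.5) {
  fr <- ensemble$frames
  scen <- fr |>
    dplyr::group_by(replica) |>
    dplyr::group_modify(~ tibble::tibble(
      scenario = classify_opening_scenario(.x, threshold))) |>
    dplyr::ungroup()
  fr <- dplyr::left_join(fr, scen, by = "replica")
  inw <- dplyr::filter(fr, .data$separation >= window[1],
                       .data$separation <= window[2],
                       .data$theta >= min(breaks), .data$theta <= max(breaks))
  inw$bin <- cut(inw$theta, breaks = breaks, include.lowest = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- inw |>
    dplyr::count(.data$scenario, .data$bin, .drop = FALSE) |>
    dplyr::mutate(bin_mid = mids[as.integer(.data$bin)]) |>
    dplyr::select(bin_mid, scenario, n) |>
    dplyr::filter(!is.na(.data$bin_mid))
  structure(list(counts = counts, total_in_window = nrow(inw),
                 window = window, breaks = breaks),
            class = "angle_histogram")
}

#' @export
print.angle_histogram <- function(x, ...) {
  cat("<angle_histogram>", x$total_in_window, "frames in window [",
      x$window[1], ",", x$window[2], "] A\n")
  invisible(x)
}

#' Strand-separation speed estimate across a replica ensemble
#'
#' Per replica, the speed is the least-squares slope of separation versus
#' time between the first crossings of `d_start` and `d_end`. Replicas that
#' never cross both thresholds are excluded (and counted). The ensemble
#' mean is reported with its standard error (sample standard deviation over
#' the square root of the number of included replicas).
#'
#' @param ensemble A [run_steered()] ensemble.
#' @param d_start,d_end Separation thresholds, Angstrom.
#' @return Object of class `speed_estimate`: tibble `speeds` (per included
#'   replica), `mean`, `se`, `n_included`, `n_excluded`.
#' @export
separation_speed <- function(ensemble, d_start = 0.2, d_end = 2.0) {
  fr <- ensemble$frames
  per <- fr |>
    dplyr::group_by(replica) |>
    dplyr::group_modify(function(df, key) {
      i0 <- match(TRUE, df$separation >= d_start)
      i1 <- match(TRUE, df$separation >= d_end)
      if (is.na(i0) || is.na(i1) || i1 <= i0) {
        return(tibble::tibble(speed = NA_real_))
      }
      seg <- df[i0:i1, ]
      tibble::tibble(speed = unname(stats::coef(
        stats::lm(separation ~ time, data = seg))[2]))
    }) |>
    dplyr::ungroup()
  speeds <- per$speed[is.finite(per$speed)]
  if (!length(speeds)) {
    stop("separation_speed(): no replica crossed both thresholds")
  }
  structure(list(
    speeds = tibble::tibble(replica = per$replica[is.finite(per$speed)],
                            speed = speeds),
    mean = mean(speeds),
    se = stats::sd(speeds) / sqrt(length(speeds)),
    n_included = length(speeds),
    n_excluded = sum(!is.finite(per$speed))
  ), class = "speed_estimate")
}

#' @export
print.speed_estimate <- function(x, ...) {
  cat(sprintf("<speed_estimate> %.3f +/- %.3f A/ps (n = %d, excluded %d)\n",
              x$mean, x$se, x$n_included, x$n_excluded))
  invisible(x)
}
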