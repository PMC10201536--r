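test_that("steering-force unit conversion matches CODATA arithmetic", {
  expect_equal(force_kjmolnm_to_ev_a(25), 0.025911, tolerance = 1e-4)
  expect_equal(force_kjmolnm_to_ev_a(0), 0)
  # linearity across the ladder
  expect_equal(force_kjmolnm_to_ev_a(125), 5 * force_kjmolnm_to_ev_a(25))
})

test_that("the integrator conserves energy in the deterministic limit", {
  sys <- test_duplex(n_pairs = 3)
  set.seed(21)
  x0 <- sys$coords + 0.002 * matrix(stats::rnorm(length(sys$coords)), ncol = 3)
  x0[, 2] <- sys$coords[, 2]   # stay in the dynamical plane
  tr <- integrate_duplex(sys, coords = x0, time_ps = 10, temperature = 0,
                         friction = 0, seed = 1)
  e_tot <- tr$frames$potential_energy + tr$frames$kinetic_energy
  expect_lt(max(e_tot) - min(e_tot), 1e-4)
})

test_that("momentum is conserved without friction, noise, or steering", {
  sys <- test_duplex(n_pairs = 2)
  set.seed(22)
  x0 <- sys$coords + 0.05 * matrix(stats::rnorm(length(sys$coords)), ncol = 3)
  x0[, 2] <- sys$coords[, 2]
  v0 <- matrix(stats::rnorm(length(sys$coords), sd = 0.01), ncol = 3)
  v0[, 2] <- 0
  p0 <- colSums(sys$masses * v0)
  tr <- integrate_duplex(sys, coords = x0, velocities = v0, time_ps = 5,
                         temperature = 0, friction = 0, seed = 1)
  p1 <- colSums(sys$masses * tr$velocities)
  expect_equal(unname(p1), unname(p0), tolerance = 1e-10)
})

test_that("the steering pair force is internal: momentum stays conserved under steering", {
  sys <- test_duplex(n_pairs = 2)
  v0 <- matrix(0, nrow(sys$coords), 3)
  tr <- integrate_duplex(sys, velocities = v0, time_ps = 2, temperature = 0,
                         friction = 0, steering_force = 0.1, seed = 1)
  p1 <- colSums(sys$masses * tr$velocities)
  expect_equal(unname(p1), c(0, 0, 0), tolerance = 1e-10)
})

test_that("the thermostat holds the duplex near the target temperature", {
  sys <- test_duplex(n_pairs = 4)
  temps <- vapply(1:3, function(r) {
    eq <- integrate_duplex(sys, time_ps = 10, seed = 30 + r)
    kinetic_temperature(eq, nrow(sys$coords))
  }, numeric(1))
  expect_lt(abs(mean(temps) - 310) / 310, 0.1)
  # identical seeds give identical final states
  pr <- steering_protocol(equilibration_time = 1, seed = 5)
  a <- equilibrate(sys, pr)
  b <- equilibrate(sys, pr)
  expect_identical(a$coords, b$coords)
  expect_identical(a$frames, b$frames)
})

test_that("opening scenarios classify by first threshold crossing with B2 tie rule", {
  fr <- tibble::tibble(B1_extension = c(0, 0.6, 0.7, 0.7),
                       B2_extension = c(0, 0.1, 0.6, 0.8))
  expect_identical(classify_opening_scenario(fr), "B1-first")
  fr2 <- tibble::tibble(B1_extension = c(0, 0.1), B2_extension = c(0, 0.2))
  expect_identical(classify_opening_scenario(fr2), "none")
  fr3 <- tibble::tibble(B1_extension = c(0, 0.6), B2_extension = c(0, 0.6))
  expect_identical(classify_opening_scenario(fr3), "B2-first")
})

test_that("angle histogram conserves in-window counts and bins zero angles at zero", {
  fr <- tibble::tibble(
    time = rep(seq(0.01, 0.5, by = 0.01), 2),
    B1_extension = 0, B2_extension = 0, theta = 0, separation = 0.1,
    potential_energy = 0, kinetic_energy = 0,
    replica = rep(1:2, each = 50))
  ens <- structure(list(frames = fr,
                        protocol = steering_protocol(n_replicas = 2)),
                   class = "trajectory_ensemble")
  h <- angle_histogram(ens)
  expect_identical(h$total_in_window, 100L)
  expect_identical(sum(h$counts$n), 100L)
  nonzero <- h$counts[h$counts$n > 0, ]
  expect_true(all(abs(nonzero$bin_mid) <= 1.25))
})

test_that("separation speed recovers an exact synthetic slope and excludes flat replicas", {
  t <- seq(0.01, 2, by = 0.01)
  fr <- dplyr::bind_rows(
    tibble::tibble(time = t, separation = 1.25 * t, replica = 1),
    tibble::tibble(time = t, separation = 0.05, replica = 2))
  ens <- structure(list(frames = fr,
                        protocol = steering_protocol(n_replicas = 2)),
                   class = "trajectory_ensemble")
  sp <- separation_speed(ens, d_start = 0.2, d_end = 2.0)
  expect_equal(sp$mean, 1.25, tolerance = 1e-10)
  expect_identical(sp$n_included, 1L)
  expect_identical(sp$n_excluded, 1L)
  flat <- structure(list(frames = dplyr::filter(fr, replica == 2),
                         protocol = steering_protocol(n_replicas = 1)),
                    class = "trajectory_ensemble")
  expect_error(separation_speed(flat), "crossed")
})

test_that("a zero-force duplex does not spontaneously unzip", {
  sys <- test_duplex(n_pairs = 3)
  pr <- steering_protocol(force = 0, equilibration_time = 2,
                          production_time = 10, n_replicas = 3, seed = 40)
  en <- run_steered(sys, pr)
  # the terminal pair breathes but never unzips: its typical separation
  # stays far below the opening threshold in every replica
  st <- en$frames |>
    dplyr::group_by(replica) |>
    dplyr::summarise(med = stats::median(separation), avg = mean(separation))
  expect_true(all(st$med < 0.5))
  expect_true(all(st$avg < 0.5))
})
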