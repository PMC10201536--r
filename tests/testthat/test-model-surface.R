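test_that("canonical state is the energy reference at every separation", {
  p <- surface_params("AT")
  for (d in c(0, 0.222, 0.444, 1.0, 2.0)) {
    expect_equal(potential_energy(surface_state(0, 0, d), p), 0)
  }
})

test_that("zwitterion well sits at the single-transfer asymmetry above the canonical well", {
  m <- surface_model(surface_params("AT"), 0)
  # brute-force 2-D grid minimization of the two wells (independent oracle)
  g <- surface_grid_fast(m, step = 0.002)
  canonical <- min(g$E[, g$q < 0.5])
  zwitterion <- min(g$E[, g$q > 0.5])
  expect_equal(zwitterion - canonical, 0.55, tolerance = 1e-5)
  # the nominal zwitterion point evaluates near (but not exactly at) the well
  expect_equal(potential_energy(surface_state(0, 1, 0)), 0.55, tolerance = 0.01)
})

test_that("an isolated symmetric step has barrier h at the half-transferred point", {
  expect_equal(tilted_quartic(0.5, h = 0.37, delta = 0), 0.37)
  expect_equal(tilted_quartic_deriv(0.5, h = 0.37, delta = 0), 0)
})

test_that("out-of-bounds coordinates raise a domain error naming the coordinate", {
  expect_error(potential_energy(surface_state(1.5, 0, 0)), "q1")
  expect_error(potential_energy(surface_state(0, -0.6, 0)), "q2")
  expect_error(surface_gradient(surface_state(2, 2, 0)), "q1")
})

test_that("surface gradient matches central finite differences", {
  set.seed(42)
  p <- surface_params("AT")
  for (d in c(0, 0.444, 1.11)) {
    m <- surface_model(p, d)
    for (k in 1:34) {
      q <- stats::runif(2, -0.15, 1.15)
      expect_equal(m$gradient(q), fd_gradient(m$energy, q),
                   tolerance = 1e-6)
    }
  }
})

test_that("gradient vanishes at the relaxed stationary points", {
  m <- surface_model(surface_params("AT"), 0.888)
  for (w in c("canonical", "zwitterion", "tautomer")) {
    q <- relax_surface_state(m, w, tol = 1e-8)
    expect_lt(sqrt(sum(m$gradient(q)^2)), 1e-8)
  }
})

test_that("calibration reproduces requested barriers via true stationary analysis", {
  # symmetric well: barrier exactly h, no tilt
  cal <- calibrate_tilted_quartic(0.4, 0.4)
  expect_equal(cal$h, 0.4, tolerance = 1e-10)
  expect_equal(cal$delta, 0, tolerance = 1e-10)
  # asymmetric case checked against a dense 1-D grid oracle
  cal <- calibrate_tilted_quartic(0.5, 0.3)
  bars <- quartic_grid_barriers(cal$h, cal$delta)
  expect_equal(unname(bars["ef"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(bars["er"]), 0.3, tolerance = 1e-6)
  # degenerate wells are refused
  expect_error(calibrate_tilted_quartic(0.3, 0), "positive")
  expect_error(calibrate_tilted_quartic(-0.1, 0.3), "positive")
})

test_that("barrier targets follow the calibration laws and flag the unbound window", {
  p <- surface_params("AT")
  t0 <- barrier_targets(0, p)
  expect_equal(t0$Er1, 0.10)
  expect_false(t0$dpt_bound)
  expect_true(is.na(t0$Er2))
  # second increment: shallow negative would-be well, still unbound
  t2 <- barrier_targets(0.222, p)
  expect_false(t2$dpt_bound)
  # third increment: bound with Er2 = 0.5 * (0.444 - 0.30)
  t3 <- barrier_targets(0.444, p)
  expect_true(t3$dpt_bound)
  expect_equal(t3$Er2, 0.072)
  expect_equal(t3$Ef1, t3$A_spt + t3$Er1)
})

test_that("grid search finds two minima before onset and three after", {
  p <- surface_params("AT")
  for (d in c(0, 0.222)) {
    g <- surface_grid_fast(surface_model(p, d), step = 0.005)
    expect_identical(grid_minima_count(g$E), 2L + 0L)
  }
  for (d in c(0.444, 0.888)) {
    g <- surface_grid_fast(surface_model(p, d), step = 0.005)
    expect_identical(grid_minima_count(g$E), 3L + 0L)
  }
})

test_that("barrier orderings hold across the default grid", {
  p <- surface_params("AT")
  tg <- barrier_targets(0.222 * (0:12), p)
  expect_true(all(diff(tg$Er1) > 0))
  expect_true(all(tg$A_dpt > 0))
  bound <- tg$dpt_bound
  expect_true(all(tg$Ef2[bound] < tg$Ef1[bound]))
})

test_that("duplex construction counts and equilibrium are exact", {
  sys <- build_duplex(duplex_params())
  expect_identical(nrow(sys$morse), 28L)
  expect_identical(sys$params$n_pairs, 14L)
  sys2 <- build_duplex(duplex_params(n_pairs = 2))
  expect_identical(nrow(sys2$morse), 4L)
  expect_lt(max(abs(duplex_forces(sys2))), 1e-6)
  expect_error(duplex_params(morse_depth_B1 = 0.2, morse_depth_B2 = 0.22),
               "stronger")
  expect_error(duplex_params(n_pairs = 1), "n_pairs")
})

test_that("duplex energy is invariant under rigid motion", {
  sys <- test_duplex(n_pairs = 3)
  set.seed(7)
  x <- sys$coords + 0.1 * matrix(stats::rnorm(length(sys$coords)), ncol = 3)
  e0 <- duplex_energy(sys, x)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xr <- x %*% R + matrix(c(3, -2, 5), nrow(x), 3, byrow = TRUE)
  expect_equal(duplex_energy(sys, xr), e0, tolerance = 1e-9)
})

test_that("fixture structures realize the requested geometry exactly", {
  fr <- synth_fixture_structures(d = 0)
  expect_equal(hbond_length(fr, "B1"), 2.9)
  expect_equal(hbond_length(fr, "B2"), 2.9)
  expect_equal(opening_angle(bond_extension(fr, "B1"),
                             bond_extension(fr, "B2"), 4.5), 0)
  fr <- synth_fixture_structures(d = 0.444)
  expect_equal(separation_distance(fr), 0.444)
  # transferred B2 proton sits a covalent distance from its acceptor
  fr <- synth_fixture_structures(d = 0, q2 = 1)
  hb2 <- fr$hbonds$B2
  dist_ha <- sqrt(sum((fr$coords[hb2$hydrogen, ] - fr$coords[hb2$acceptor, ])^2))
  expect_equal(dist_ha, 1.0, tolerance = 1e-9)
})
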