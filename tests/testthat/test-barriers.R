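two_step_profile <- function() {
  # synthetic five-extremum profile with extrema (0, 0.9, 0.65, 0.67, 0.6):
  # piecewise-cosine steps make every anchor an exact stationary point
  ax <- c(0, 0.25, 0.5, 0.75, 1)
  ay <- c(0, 0.9, 0.65, 0.67, 0.6)
  x <- seq(0, 1, length.out = 201)
  seg <- findInterval(x, ax, rightmost.closed = TRUE)
  t <- (x - ax[seg]) / (ax[seg + 1] - ax[seg])
  y <- ay[seg] + (ay[seg + 1] - ay[seg]) * (1 - cos(pi * t)) / 2
  energy_profile(x, y)
}

test_that("stationary-point finder reads single- and two-hump profiles", {
  x <- seq(0, 1, length.out = 41)
  single <- energy_profile(x, sin(pi * x))
  st <- find_stationary_points(single, prominence = 0.005)
  expect_identical(sum(st$kind == "maximum"), 1L)
  expect_identical(sum(st$kind == "boundary"), 2L)
  st2 <- find_stationary_points(two_step_profile(), prominence = 0.005)
  expect_identical(sum(st2$kind == "maximum"), 2L)
  expect_identical(sum(st2$kind == "minimum"), 1L)
  mono <- energy_profile(x, x^2)
  st3 <- find_stationary_points(mono, prominence = 0.005)
  expect_identical(nrow(st3), 2L)   # only the two boundary candidates
})

test_that("barriers are read off the profile extrema by simple differences", {
  b <- extract_barriers(two_step_profile(), d = 1)
  expect_equal(b$Ef1, 0.9, tolerance = 0.02)
  expect_equal(b$Er1, 0.25, tolerance = 0.02)
  expect_equal(b$Ef2, 0.02, tolerance = 0.01)
  expect_equal(b$Er2, 0.07, tolerance = 0.01)
  expect_true(b$dpt_bound)
  x <- seq(0, 1, length.out = 41)
  single <- extract_barriers(energy_profile(x, sin(pi * x)), d = 0)
  expect_false(single$dpt_bound)
  expect_true(is.na(single$Ef2))
  expect_error(
    extract_barriers(energy_profile(x, x^2), d = 0),
    "stationary pattern")
})

test_that("reaction asymmetry is the signed product-reactant difference", {
  expect_equal(reaction_asymmetry(0.3, 0.3), 0)
  expect_gt(reaction_asymmetry(0, 0.55), 0)   # canonical more stable
  expect_equal(reaction_asymmetry(0, 0.55), 0.55)
})

test_that("stability classification applies the closed-boundary tie rule", {
  mk <- function(er2, bound = TRUE) {
    tibble::tibble(d = 1, Ef1 = 1, Er1 = 0.5, Ef2 = 0.1, Er2 = er2,
                   A_spt = 0.5, A_dpt = 0.5, dpt_bound = bound)
  }
  expect_identical(classify_stability(mk(NA, bound = FALSE)), "unbound")
  expect_identical(classify_stability(mk(0.005)), "unbound")  # boundary closed
  expect_identical(classify_stability(mk(0.03)), "metastable")
  expect_identical(classify_stability(mk(0.072)), "stable")
})

test_that("onset detection returns the first non-unbound separation", {
  tbl <- tibble::tibble(
    d = c(0, 0.222, 0.444, 0.666),
    classification = c("unbound", "unbound", "stable", "stable"))
  expect_equal(detect_onset(tbl), 0.444)
  all_bound <- tibble::tibble(d = c(0.1, 0.2),
                              classification = c("stable", "stable"))
  expect_equal(detect_onset(all_bound), 0.1)
  none <- tibble::tibble(d = c(0.1, 0.2),
                         classification = c("unbound", "unbound"))
  expect_error(detect_onset(none), "no scanned separation")
})

test_that("power-law fitting recovers exponents exactly on clean input", {
  d <- 0.222 * (1:12)
  fit <- fit_power_law(d, 2 * d^1.894)
  expect_equal(fit$exponent, 1.894, tolerance = 1e-10)
  expect_equal(fit$prefactor, 2, tolerance = 1e-8)
  flat <- fit_power_law(d, rep(3, 12))
  expect_equal(flat$exponent, 0, tolerance = 1e-12)
  expect_error(fit_power_law(d, -d), "positive")
  expect_error(fit_power_law(d[1:2], d[1:2]), "at least 3")
})

test_that("generator and fitter agree on the configured exponents for both presets", {
  expect_equal(reverse_barrier_power_law(surface_params("AT"))$exponent,
               1.894, tolerance = 1e-6)
  expect_equal(reverse_barrier_power_law(surface_params("GC"))$exponent,
               1.783, tolerance = 1e-6)
})

test_that("lifetime and temperature-bound arithmetic", {
  expect_equal(min_lifetime(2.0, 1.25), 1.6)
  expect_equal(min_lifetime(0, 3), 0)
  expect_equal(min_lifetime(1, 1), 1)
  expect_error(min_lifetime(2, 0), "positive")
  kb <- physical_constants$k_boltzmann
  expect_equal(barrier_temperature(kb), 1)
  expect_equal(barrier_temperature(0.02672), 310, tolerance = 0.01)
  expect_equal(barrier_temperature(3.016), 3.5e4, tolerance = 0.01)
  expect_error(barrier_temperature(-0.1), "non-negative")
})

test_that("state energies are path-independent across the calibration", {
  tg <- barrier_targets(0.222 * (2:12), surface_params("AT"))
  bound <- tg$dpt_bound
  lhs <- (tg$Ef1 - tg$Er1) + (tg$Ef2 - tg$Er2)
  expect_equal(lhs[bound], tg$A_dpt[bound], tolerance = 1e-9)
})
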