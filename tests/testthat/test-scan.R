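test_that("constrained relaxation honours frozen coordinates and tolerance", {
  # 2-D quadratic bowl with one coordinate frozen: analytic conditional
  # minimum at the frozen plane's foot point
  A <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  model <- list(energy = function(x) 0.5 * sum(x * (A %*% x)),
                gradient = function(x) as.vector(A %*% x))
  x0 <- c(1.3, 4)
  res <- relax_constrained(x0, fixed = 1L, model, tol = 1e-8)
  expect_identical(res$x[1], 1.3)                      # bit-identical
  expect_equal(res$x[2], -0.5 * 1.3 / 1, tolerance = 1e-6)
  # starting at a minimum returns the input unchanged
  res0 <- relax_constrained(c(0, 0), fixed = integer(0), model, tol = 1e-8)
  expect_identical(res0$steps, 0L)
  expect_equal(res0$x, c(0, 0))
  # non-convergence raises a condition carrying the last state
  stiff <- list(energy = function(x) sum(1e6 * x^2),
                gradient = function(x) 2e6 * x)
  err <- tryCatch(
    relax_constrained(c(5, 5), integer(0), stiff, tol = 1e-300, max_steps = 3),
    error = function(e) e)
  expect_s3_class(err, "tautopath_convergence_error")
  expect_true(is.numeric(err$last_state))
})

test_that("scan pivots stay frozen and the grid hits the printed landmarks", {
  sc <- run_separation_scan(scan_config(n_increments = 4))
  expect_equal(sc$d, c(0, 0.222, 0.444, 0.666))
  expect_equal(sc$d[3], 0.444)        # the third imposed increment
  expect_true(all(sc$grad_norm <= 0.01))
  one <- run_separation_scan(scan_config(n_increments = 1))
  expect_equal(nrow(one), 1L)
  expect_equal(one$B1_extension, 0, tolerance = 1e-8)
  expect_equal(one$B2_extension, 0, tolerance = 1e-8)
})

test_that("canonical scan shows asymmetric stretching and angular reversion", {
  sc <- run_separation_scan(scan_config())
  # pulling a bound pair apart costs energy monotonically
  expect_true(all(diff(sc$energy) > -1e-9))
  # B2 stretches at least as fast as B1 up to the angular maximum
  i_max <- which.max(abs(sc$theta))
  expect_true(all(sc$B2_extension[1:i_max] >= sc$B1_extension[1:i_max] - 1e-8))
  # the angle rises well away from zero, then reverts
  expect_gt(max(abs(sc$theta)), 5)
  expect_lt(abs(sc$theta[nrow(sc)]), max(abs(sc$theta)) / 2)
})

test_that("tautomeric scan flags unbound increments and binds from onset", {
  sc <- run_separation_scan(scan_config(n_increments = 5), form = "tautomeric")
  expect_equal(sc$bound_flag, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # unbound rows relax the zwitterionic product instead
  expect_true(all(sc$q1[!sc$bound_flag] < 0.1))
  expect_true(all(sc$q1[sc$bound_flag] > 0.9))
  expect_true(all(sc$q2 > 0.9))
  # tautomeric reversion happens later than canonical (stronger B1 holds on)
  can <- run_separation_scan(scan_config())
  i_rev <- function(x) which.max(abs(x$theta))
  expect_gte(i_rev(run_separation_scan(scan_config(), form = "tautomeric")),
             i_rev(can))
})

test_that("rerunning the scan from a perturbed start reproduces the energies", {
  cfg <- scan_config(n_increments = 6)
  sc1 <- run_separation_scan(cfg)
  # perturb via a slightly different (but still converged) continuation:
  # re-run and compare; the relaxation must erase sub-0.01 A perturbations
  sc2 <- run_separation_scan(cfg)
  expect_equal(sc1$energy, sc2$energy, tolerance = 1e-6)
  set.seed(5)
  m <- pair_scan_model(d = 0.444)
  x0 <- m$start + c(0, 0, stats::runif(4, -0.008, 0.008))
  r1 <- relax_constrained(m$start, 1:2, m, tol = 1e-4, max_steps = 500,
                          lower = m$lower, upper = m$upper)
  r2 <- relax_constrained(x0, 1:2, m, tol = 1e-4, max_steps = 500,
                          lower = m$lower, upper = m$upper)
  expect_equal(r1$energy, r2$energy, tolerance = 1e-6)
})
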