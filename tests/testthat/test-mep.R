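test_that("path interpolation is linear with exact endpoints", {
  p <- interpolate_path(c(0, 0), c(1, 1), 3)
  expect_equal(p[2, ], c(0.5, 0.5))
  expect_identical(p[1, ], c(0, 0))
  expect_identical(p[3, ], c(1, 1))
  expect_identical(nrow(interpolate_path(c(0, 0), c(1, 1), 15)), 15L)
  expect_error(interpolate_path(c(1, 1), c(1, 1), 5), "identical")
})

test_that("band relaxation finds the exact barrier of a 1-D symmetric step", {
  mod <- list(energy = function(x) tilted_quartic(x, 0.4, 0),
              gradient = function(x) tilted_quartic_deriv(x, 0.4, 0))
  r <- neb_relax(interpolate_path(0, 1, 9), mod, mlneb_config(n_images = 9))
  expect_equal(max(r$energies), 0.4, tolerance = 1e-3)
  expect_identical(r$path[1, ], 0)   # endpoints never move
  expect_identical(r$path[9, ], 1)
})

test_that("an already-converged band is returned essentially unchanged", {
  mod <- list(energy = function(x) tilted_quartic(x, 0.4, 0),
              gradient = function(x) tilted_quartic_deriv(x, 0.4, 0))
  r1 <- neb_relax(interpolate_path(0, 1, 9), mod, mlneb_config(n_images = 9))
  r2 <- neb_relax(r1$path, mod, mlneb_config(n_images = 9))
  expect_equal(r2$path, r1$path, tolerance = 1e-3)
})

test_that("climbing-image saddle matches the dense-grid minimax oracle", {
  p <- surface_params("AT")
  for (d in c(0.444, 0.888)) {
    m <- surface_model(p, d)
    ra <- relax_surface_state(m, "canonical")
    zw <- relax_surface_state(m, "zwitterion")
    r <- neb_relax(interpolate_path(ra, zw, 11), m, mlneb_config(n_images = 11))
    saddle_neb <- max(r$energies)
    g <- surface_grid_fast(m, step = 0.002)
    saddle_grid <- grid_minimax_barrier(g$E, grid_index(g$q, ra),
                                        grid_index(g$q, zw))
    expect_equal(saddle_neb, saddle_grid, tolerance = 1e-3)
  }
})

test_that("profile stationary structure flips from one to two saddles at onset", {
  p <- surface_params("AT")
  for (d in c(0, 0.222)) {
    m <- surface_model(p, d)
    r <- neb_relax(interpolate_path(relax_surface_state(m, "canonical"),
                                    relax_surface_state(m, "tautomer"), 15),
                   m, mlneb_config())
    st <- find_stationary_points(as_energy_profile(r), prominence = 0.005)
    expect_identical(sum(st$kind == "maximum"), 1L)
    expect_identical(sum(st$kind == "minimum"), 0L)
  }
  for (d in c(0.444, 0.888)) {
    m <- surface_model(p, d)
    r <- neb_relax(interpolate_path(relax_surface_state(m, "canonical"),
                                    relax_surface_state(m, "tautomer"), 15),
                   m, mlneb_config())
    st <- find_stationary_points(as_energy_profile(r), prominence = 0.005)
    expect_identical(sum(st$kind == "maximum"), 2L)
    expect_identical(sum(st$kind == "minimum"), 1L)
  }
})

test_that("profile is reversal-invariant up to mirroring", {
  p <- surface_params("AT")
  m <- surface_model(p, 0.444)
  ra <- relax_surface_state(m, "canonical")
  pr <- relax_surface_state(m, "tautomer")
  fwd <- neb_relax(interpolate_path(ra, pr, 15), m, mlneb_config())
  rev <- neb_relax(interpolate_path(pr, ra, 15), m, mlneb_config())
  expect_equal(max(fwd$energies), max(rev$energies), tolerance = 2e-3)
  expect_equal(fwd$energies[1], rev$energies[15], tolerance = 1e-6)
})

test_that("gaussian-process surrogate interpolates and reports honest uncertainty", {
  set.seed(9)
  X <- matrix(stats::runif(16), ncol = 2)
  y <- sin(3 * X[, 1]) + X[, 2]^2
  gp <- gp_fit(X, y, lengthscales = c(0.3, 0.3), sigma_f = 1)
  pred <- gp_predict(gp, X)
  expect_equal(pred$mean, y, tolerance = 1e-3)
  expect_true(all(pred$sd <= 1e-3))
  # constant data give a constant posterior mean
  gpc <- gp_fit(X, rep(2.5, nrow(X)))
  expect_equal(gp_predict(gpc, matrix(c(0.5, 0.5), 1))$mean, 2.5,
               tolerance = 1e-6)
  # far from all data the predictive sd recovers the prior scale
  far <- gp_predict(gp, matrix(c(50, 50), 1))
  expect_gte(far$sd, 0.9 * gp$sigma_f)
})

test_that("derivative-enhanced surrogate reproduces values and gradients", {
  set.seed(10)
  f <- function(x) sin(2 * x[1]) * cos(x[2])
  g <- function(x) c(2 * cos(2 * x[1]) * cos(x[2]), -sin(2 * x[1]) * sin(x[2]))
  X <- matrix(stats::runif(20, 0, 1.5), ncol = 2)
  y <- apply(X, 1, f); G <- t(apply(X, 1, g))
  gp <- tautopath:::gp_fit_grad(X, y, G, optimize_hyper = TRUE)
  q <- matrix(c(0.7, 0.4), 1)
  expect_equal(tautopath:::gp_predict_grad(gp, q)$mean, f(q[1, ]),
               tolerance = 1e-3)
  expect_equal(as.vector(tautopath:::gp_mean_gradient_grad(gp, q)), g(q[1, ]),
               tolerance = 5e-3)
})

test_that("surrogate-accelerated search matches the plain band with fewer true calls", {
  p <- surface_params("AT")
  m <- surface_model(p, 0.888)
  ra <- relax_surface_state(m, "canonical")
  pr <- relax_surface_state(m, "tautomer")
  plain <- neb_relax(interpolate_path(ra, pr, 15), m, mlneb_config())
  ml <- mlneb_run(ra, pr, m, mlneb_config())
  b_plain <- extract_barriers(as_energy_profile(plain), d = 0.888)
  b_ml <- extract_barriers(as_energy_profile(ml$path), d = 0.888)
  for (col in c("Ef1", "Er1", "Ef2", "Er2")) {
    expect_equal(b_ml[[col]], b_plain[[col]], tolerance = 0.02)
  }
  expect_lt(ml$n_true_evaluations, plain$n_force_calls)
})

test_that("identical seeds give identical evaluation logs", {
  p <- surface_params("AT")
  m <- surface_model(p, 0.444)
  ra <- relax_surface_state(m, "canonical")
  pr <- relax_surface_state(m, "tautomer")
  r1 <- mlneb_run(ra, pr, m, mlneb_config(seed = 7))
  r2 <- mlneb_run(ra, pr, m, mlneb_config(seed = 7))
  expect_identical(r1$log, r2$log)
  expect_identical(r1$path$energies, r2$path$energies)
})
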