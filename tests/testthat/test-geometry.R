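make_frame <- function(coords, ref = NULL) {
  molecular_frame(
    labels = c("p1", "don1", "acc2", "h1", "p2", "don2", "acc1", "h2"),
    elements = c("N", "N", "N", "H", "N", "N", "O", "H"),
    coords = coords, pivot_indices = c(1L, 5L),
    hbonds = list(hbond_spec(2L, 4L, 7L, "B1", 2.9),
                  hbond_spec(6L, 8L, 3L, "B2", 2.9)),
    equilibrium_reference = ref)
}

test_that("hydrogen-bond length is the heavy-atom distance", {
  co <- matrix(0, 8, 3)
  co[2, ] <- c(0, 0, 0); co[7, ] <- c(2.9, 0, 0)   # B1 donor/acceptor
  co[6, ] <- c(1, 2, 2); co[3, ] <- c(1 + 3 / sqrt(2), 2 + 3 / sqrt(2), 2)
  fr <- make_frame(co)
  expect_equal(hbond_length(fr, "B1"), 2.9)
  expect_equal(hbond_length(fr, "B2"), 3)  # independent arithmetic: 3-4-5-ish
  expect_error(hbond_length(fr, "B3"), "unknown")
})

test_that("bond extension is signed and zero at equilibrium", {
  fr <- synth_fixture_structures(d = 0)
  expect_equal(bond_extension(fr, "B1"), 0)
  fr2 <- synth_fixture_structures(d = 0, ext_b1 = 0.5, ext_b2 = -0.1)
  expect_equal(bond_extension(fr2, "B1"), 0.5)
  expect_equal(bond_extension(fr2, "B2"), -0.1)  # compression keeps its sign
})

test_that("separation distance sums pivot displacements from the reference", {
  expect_equal(separation_distance(synth_fixture_structures(d = 0.222)), 0.222)
  expect_equal(separation_distance(synth_fixture_structures(d = 0)), 0)
  # one-sided displacement
  fr <- synth_fixture_structures(d = 0)
  fr$coords[1, 1] <- fr$coords[1, 1] - 0.444
  expect_equal(separation_distance(fr), 0.444)
  fr$equilibrium_reference <- NULL
  expect_error(separation_distance(fr), "equilibrium_reference")
})

test_that("opening angle follows the signed arcsine lever rule", {
  expect_equal(opening_angle(0.3, 0.3, 4.5), 0)
  expect_equal(opening_angle(0, 4.5 * sin(20 * pi / 180), 4.5), 20)
  expect_equal(opening_angle(4.5 * sin(35 * pi / 180), 0, 4.5), -35)
  # antisymmetry under swapping the two extensions
  set.seed(11)
  for (k in 1:20) {
    e <- stats::runif(2, -1, 1)
    expect_equal(opening_angle(e[1], e[2], 4.5),
                 -opening_angle(e[2], e[1], 4.5))
  }
  expect_error(opening_angle(0, 5, 4.5), "lever")
  expect_error(opening_angle(0, 1, -1), "positive")
})

test_that("normalized reaction coordinate is a cumulative arc length on [0, 1]", {
  p <- matrix(c(0, 0, 0.5, 0.5, 1, 1), ncol = 2, byrow = TRUE)
  expect_equal(normalized_reaction_coordinate(p), c(0, 0.5, 1))
  set.seed(3)
  rnd <- matrix(stats::rnorm(30), ncol = 3)
  s <- normalized_reaction_coordinate(rnd)
  expect_equal(s[1], 0)
  expect_equal(s[length(s)], 1)
  expect_true(all(diff(s) >= 0))
  expect_error(normalized_reaction_coordinate(rnd[1, , drop = FALSE]),
               "at least 2")
  # frame-based descriptor: difference of the two bond vectors
  frames <- lapply(seq(0, 1, length.out = 5), function(t) {
    synth_fixture_structures(d = t, ext_b1 = 0, ext_b2 = t)
  })
  sf <- normalized_reaction_coordinate(frames)
  expect_equal(sf[1], 0); expect_equal(sf[5], 1)
  expect_true(all(diff(sf) > 0))
})

test_that("geometric observables are invariant under rigid-body motion", {
  fr <- synth_fixture_structures(d = 0.444, ext_b1 = 0.2, ext_b2 = 0.6)
  th <- 0.9; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  fr2 <- transform_frame(fr, rotation = R, translation = c(-4, 2, 7))
  for (lab in c("B1", "B2")) {
    expect_equal(hbond_length(fr2, lab), hbond_length(fr, lab),
                 tolerance = 1e-9)
  }
  expect_equal(separation_distance(fr2), separation_distance(fr),
               tolerance = 1e-9)
})
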