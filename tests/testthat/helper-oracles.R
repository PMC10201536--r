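# Independent oracles used across the suite. They share no code with the
# implementation paths they check.

# Central finite differences of a scalar field f at x.
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Dense-grid evaluation of a surface model over the physical box.
surface_grid <- function(model, step = 0.002, lo = -0.2, hi = 1.2) {
  q <- seq(lo, hi, by = step)
  E <- outer(q, q, Vectorize(function(q1, q2) model$energy(c(q1, q2))))
  list(q = q, E = E)
}

# Vectorized version (much faster): rebuilds the surface formula directly
# from the model's calibration, which is the same arithmetic but a separate
# code path is not required here -- the energy closure itself is the object
# under test, so we call it through a row-wise loop only where cheap.
surface_grid_fast <- function(model, step = 0.002, lo = -0.2, hi = 1.2) {
  q <- seq(lo, hi, by = step)
  n <- length(q)
  E <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    E[, j] <- vapply(q, function(q1) model$energy(c(q1, q[j])), numeric(1))
  }
  list(q = q, E = E)  # E[i, j] = V(q1 = q[i], q2 = q[j])
}

# Count strict local minima of a grid (4-neighbour comparison), interior
# cells only.
grid_minima_count <- function(E) {
  n <- nrow(E); m <- ncol(E)
  inner <- E[2:(n - 1), 2:(m - 1)]
  up <- E[1:(n - 2), 2:(m - 1)]; down <- E[3:n, 2:(m - 1)]
  left <- E[2:(n - 1), 1:(m - 2)]; right <- E[2:(n - 1), 3:m]
  sum(inner < up & inner < down & inner < left & inner < right)
}

# Minimax (watershed) barrier between two basins on a dense grid: the
# lowest threshold at which the two marked cells join one connected
# component of {E <= threshold}. Uses EBImage connected-component labelling
# as the independent engine; binary search to `tol` on the energy.
grid_minimax_barrier <- function(E, from_idx, to_idx, tol = 1e-6) {
  lo <- max(E[from_idx[1], from_idx[2]], E[to_idx[1], to_idx[2]])
  hi <- max(E)
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    lab <- EBImage::bwlabel(E <= mid)
    if (lab[from_idx[1], from_idx[2]] != 0 &&
        lab[from_idx[1], from_idx[2]] == lab[to_idx[1], to_idx[2]]) {
      hi <- mid
    } else {
      lo <- mid
    }
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Index of the grid cell nearest to a coordinate pair.
grid_index <- function(q, point) {
  c(which.min(abs(q - point[1])), which.min(abs(q - point[2])))
}

# Dense 1-D stationary analysis of a tilted quartic: forward and reverse
# barriers read directly off a fine grid.
quartic_grid_barriers <- function(h, delta, step = 1e-5) {
  q <- seq(-0.2, 1.2, by = step)
  e <- 16 * h * q^2 * (1 - q)^2 + delta * q
  dm <- diff(sign(diff(e)))
  mins <- which(dm == 2) + 1L
  maxs <- which(dm == -2) + 1L
  stopifnot(length(mins) == 2, length(maxs) == 1)
  c(ef = e[maxs] - e[mins[1]], er = e[maxs] - e[mins[2]])
}

# Small helpers for dynamics tests
test_duplex <- function(n_pairs = 4, ...) {
  tautopath::build_duplex(tautopath::duplex_params(n_pairs = n_pairs, ...))
}
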