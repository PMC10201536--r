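#' Tilted quartic step potential
#'
#' One proton-transfer step is modelled by the tilted double well
#' `S(q; h, delta) = 16 h q^2 (1-q)^2 + delta q`. For delta = 0 the wells
#' sit exactly at q = 0 and q = 1 and the barrier at q = 1/2 equals h; a
#' finite tilt shifts the stationary points, which is why calibration works
#' on the true stationary analysis rather than on (h, delta) directly.
#'
#' @param q Transfer-progress coordinate (dimensionless).
#' @param h Barrier scale, eV.
#' @param delta Tilt, eV.
#' @return Energy in eV (`tilted_quartic`) or its derivative in eV per unit
#'   coordinate (`tilted_quartic_deriv`).
#' @examples
#' tilted_quartic(0.5, h = 0.3, delta = 0)  # exactly 0.3
#' @export
tilted_quartic <- function(q, h, delta) {
  16 * h * q^2 * (1 - q)^2 + delta * q
}

#' @rdname tilted_quartic
#' @export
tilted_quartic_deriv <- function(q, h, delta) {
  32 * h * q * (1 - q) * (1 - 2 * q) + delta
}

# Stationary points of the tilted quartic: roots of the cubic
# 64 h q^3 - 96 h q^2 + 32 h q + delta = 0, ordered. Returns NULL when the
# double-well structure has degenerated (fewer than 3 real roots).
quartic_stationary <- function(h, delta) {
  r <- polyroot(c(delta, 32 * h, -96 * h, 64 * h))
  re <- Re(r)[abs(Im(r)) < 1e-8 * (1 + abs(Re(r)))]
  if (length(re) < 3) return(NULL)
  re <- sort(re)
  list(q_reactant = re[1], q_ts = re[2], q_product = re[3],
       e_reactant = tilted_quartic(re[1], h, delta),
       e_ts = tilted_quartic(re[2], h, delta),
       e_product = tilted_quartic(re[3], h, delta))
}

# Forward/reverse barriers realised by (h, delta), or NULL if degenerate.
quartic_barriers <- function(h, delta) {
  st <- quartic_stationary(h, delta)
  if (is.null(st)) return(NULL)
  c(ef = st$e_ts - st$e_reactant, er = st$e_ts - st$e_product)
}

#' Calibrate a tilted quartic to prescribed forward/reverse barriers
#'
#' Root-solves for (h, delta) such that the exact stationary analysis of the
#' tilted quartic realises forward barrier `ef` and reverse barrier `er`.
#' Because the tilt displaces the minima away from q = 0 and q = 1, the naive
#' assignment h = (ef + er)/2, delta = ef - er is only a first-order guess;
#' it seeds a Newton iteration on the true barrier map.
#'
#' @param ef Forward barrier, eV, > 0.
#' @param er Reverse barrier, eV, > 0.
#' @param tol Barrier residual tolerance, eV.
#' @return Named list with `h`, `delta`, and the realised `stationary`
#'   analysis.
#' @examples
#' calibrate_tilted_quartic(0.5, 0.3)
#' @export
calibrate_tilted_quartic <- function(ef, er, tol = 1e-10) {
  if (!is.finite(ef) || !is.finite(er) || ef <= 0 || er <= 0) {
    stop("calibrate_tilted_quartic(): degenerate well; both barriers must be ",
         "positive (got ef = ", format(ef), ", er = ", format(er), ")")
  }
  x <- c(h = (ef + er) / 2, delta = ef - er)
  target <- c(ef, er)
  for (iter in seq_len(60)) {
    b <- quartic_barriers(x[1], x[2])
    if (is.null(b)) stop("calibrate_tilted_quartic(): well structure degenerated during solve")
    res <- b - target
    if (max(abs(res)) < tol) {
      st <- quartic_stationary(x[1], x[2])
      return(list(h = unname(x[1]), delta = unname(x[2]), stationary = st))
    }
    # numerical Jacobian
    eps <- 1e-7 * pmax(abs(x), 1)
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + eps[j]
      bp <- quartic_barriers(xp[1], xp[2])
      if (is.null(bp)) stop("calibrate_tilted_quartic(): Jacobian step degenerated")
      J[, j] <- (bp - b) / eps[j]
    }
    step <- solve(J, res)
    # damped update keeping h positive
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      if (xn[1] > 0 && !is.null(quartic_barriers(xn[1], xn[2]))) break
      lambda <- lambda / 2
      if (lambda < 1e-6) stop("calibrate_tilted_quartic(): line search failed")
    }
    x <- xn
  }
  stop("calibrate_tilted_quartic(): no convergence in 60 iterations")
}
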