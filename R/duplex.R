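# internal geometry constants of the ladder model
.duplex_rise <- 3.4        # A, stacking distance between consecutive pairs
.duplex_base_depth <- 4.0  # A, backbone bead to bond-site line
.duplex_k_rigid <- 30      # eV/A^2, stiff triangle springs emulating a rigid base frame

morse_energy <- function(r, D, a, r0) D * (1 - exp(-a * (r - r0)))^2
morse_force_mag <- function(r, D, a, r0) {
  # -dV/dr
  e <- exp(-a * (r - r0))
  -2 * D * a * e * (1 - e)
}

#' Build the coarse-grained duplex mechanical system
#'
#' Constructs a double-stranded ladder of `n_pairs` base pairs. Each
#' nucleotide is three beads: a backbone bead and two hydrogen-bond sites
#' (B1 above, B2 below the pair axis, separated by the lever arm) held in a
#' stiff spring triangle that emulates a rigid base frame. Facing B1 and B2
#' sites across the strands are joined by breakable Morse bonds (B1 deeper
#' than B2); consecutive backbone beads along a strand are joined by
#' stacking springs. Restricting stacking to the backbone beads keeps the
#' opening dynamics of any one pair exactly symmetric under exchange of its
#' two bond sites, so an asymmetry of the opening-angle statistics can only
#' come from the bond depths themselves.
#'
#' The as-built configuration is the mechanical equilibrium: every spring is
#' at its rest length and every Morse bond at its minimum, so the residual
#' force vanishes identically.
#'
#' @param params A [duplex_params()] object.
#' @return An object of class `duplex_system`: coordinates, per-bead masses,
#'   site metadata tibble, spring and Morse bond tables, and the params.
#' @examples
#' sys <- build_duplex(duplex_params(n_pairs = 4))
#' nrow(sys$morse)  # 8 hydrogen-bond terms, 2 per pair
#' @export
build_duplex <- function(params = duplex_params()) {
  validate_duplex_params(params)
  n <- params$n_pairs
  hb <- params$hbond_eq_length
  w <- params$lever_arm
  xbb <- hb / 2 + .duplex_base_depth

  sites <- tidyr::expand_grid(pair = seq_len(n), strand = 1:2,
                              role = c("bb", "B1", "B2"))
  side <- ifelse(sites$strand == 1, -1, 1)
  x <- ifelse(sites$role == "bb", side * xbb, side * hb / 2)
  z <- (sites$pair - 1) * .duplex_rise +
    ifelse(sites$role == "B1", w / 2, ifelse(sites$role == "B2", -w / 2, 0))
  coords <- cbind(x = x, y = 0, z = z)
  sites$index <- seq_len(nrow(sites))

  idx <- function(pair, strand, role) {
    sites$index[sites$pair == pair & sites$strand == strand & sites$role == role]
  }
  dist_ij <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))

  springs <- list()
  for (p in seq_len(n)) {
    for (s in 1:2) {
      b <- idx(p, s, "bb"); s1 <- idx(p, s, "B1"); s2 <- idx(p, s, "B2")
      springs[[length(springs) + 1]] <- tibble::tibble(
        i = c(b, b, s1), j = c(s1, s2, s2), k = .duplex_k_rigid,
        r0 = c(dist_ij(b, s1), dist_ij(b, s2), dist_ij(s1, s2)),
        kind = "rigid")
      if (p < n) {
        b2 <- idx(p + 1, s, "bb")
        springs[[length(springs) + 1]] <- tibble::tibble(
          i = b, j = b2, k = params$stacking_k, r0 = dist_ij(b, b2),
          kind = "stacking")
      }
      if (p < n - 1) {
        # second-neighbour backbone springs give the strand bending
        # rigidity; confined to backbone beads they keep the pair-opening
        # dynamics symmetric in B1/B2
        b3 <- idx(p + 2, s, "bb")
        springs[[length(springs) + 1]] <- tibble::tibble(
          i = b, j = b3, k = params$stacking_k, r0 = dist_ij(b, b3),
          kind = "bending")
      }
    }
  }
  springs <- dplyr::bind_rows(springs)

  morse <- dplyr::bind_rows(lapply(seq_len(n), function(p) {
    tibble::tibble(
      i = c(idx(p, 1, "B1"), idx(p, 1, "B2")),
      j = c(idx(p, 2, "B1"), idx(p, 2, "B2")),
      D = c(params$morse_depth_B1, params$morse_depth_B2),
      a = params$morse_width, r0 = hb,
      label = c("B1", "B2"), pair = p)
  }))

  masses <- rep(params$bead_mass / 3, nrow(coords))

  # sparse incidence matrix (beads x bonds): scatter per-bond forces onto
  # beads with one multiply in the dynamics hot loop
  nb <- nrow(springs) + nrow(morse)
  ii <- c(springs$i, morse$i); jj <- c(springs$j, morse$j)
  incidence <- Matrix::sparseMatrix(
    i = c(ii, jj), j = rep(seq_len(nb), 2),
    x = rep(c(1, -1), each = nb), dims = c(nrow(coords), nb))

  structure(list(coords = coords, masses = masses, sites = sites,
                 springs = springs, morse = morse, incidence = incidence,
                 params = params),
            class = "duplex_system")
}

#' @export
print.duplex_system <- function(x, ...) {
  cat("<duplex_system>", x$params$n_pairs, "bp,", nrow(x$coords), "beads,",
      nrow(x$morse), "hydrogen-bond terms\n")
  invisible(x)
}

#' Potential energy and forces of a duplex configuration
#'
#' @param sys A [build_duplex()] system.
#' @param coords Optional n x 3 coordinate matrix (defaults to the stored
#'   configuration).
#' @return `duplex_energy()`: scalar energy, eV. `duplex_forces()`: n x 3
#'   force matrix, eV/A.
#' @export
duplex_energy <- function(sys, coords = sys$coords) {
  sp <- sys$springs; mo <- sys$morse
  dsp <- coords[sp$i, , drop = FALSE] - coords[sp$j, , drop = FALSE]
  rsp <- sqrt(rowSums(dsp^2))
  dmo <- coords[mo$i, , drop = FALSE] - coords[mo$j, , drop = FALSE]
  rmo <- sqrt(rowSums(dmo^2))
  sum(0.5 * sp$k * (rsp - sp$r0)^2) + sum(morse_energy(rmo, mo$D, mo$a, mo$r0))
}

#' @rdname duplex_energy
#' @export
duplex_forces <- function(sys, coords = sys$coords) {
  sp <- sys$springs; mo <- sys$morse
  dsp <- coords[sp$i, , drop = FALSE] - coords[sp$j, , drop = FALSE]
  rsp <- sqrt(rowSums(dsp^2))
  fmag <- -sp$k * (rsp - sp$r0) / rsp          # along dsp, on bead i
  dmo <- coords[mo$i, , drop = FALSE] - coords[mo$j, , drop = FALSE]
  rmo <- sqrt(rowSums(dmo^2))
  mmag <- morse_force_mag(rmo, mo$D, mo$a, mo$r0) / rmo
  ff <- rbind(dsp * fmag, dmo * mmag)
  as.matrix(sys$incidence %*% ff)
}
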