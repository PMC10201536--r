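#' Synthetic two-base fixture structure
#'
#' Builds a labeled 3-D A-T base-pair fixture whose geometry observables are
#' exact by construction: the separation is split equally between the two
#' pivot sites, and the bond extensions (hence the opening angle through the
#' lever formula) can be prescribed. The B2 bond donor is the thymine
#' nitrogen and the B1 donor the adenine nitrogen, matching the stepwise
#' transfer order (B2 proton first). Each shared hydrogen sits a covalent
#' distance from the donor when its transfer coordinate is 0 and from the
#' acceptor when it is 1.
#'
#' @param d Strand separation, Angstrom (summed pivot displacement).
#' @param q1,q2 Proton transfer-progress coordinates of bonds B1 and B2.
#' @param ext_b1,ext_b2 Bond extensions, Angstrom; default `d` (rigid
#'   attachment of the bond sites to their pivots: each pivot carries its
#'   half of the separation into both bonds).
#' @param eq_length Equilibrium hydrogen-bond length, Angstrom.
#' @param lever_arm Distance between B1 and B2 attachment sites, Angstrom.
#' @param base_depth Pivot to bond-site distance along the bond axis, Angstrom.
#' @return A [molecular_frame()] with an equilibrium reference attached.
#' @examples
#' fr <- synth_fixture_structures(d = 0.444)
#' separation_distance(fr)
#' @export
synth_fixture_structures <- function(d = 0, q1 = 0, q2 = 0,
                                     ext_b1 = d, ext_b2 = d,
                                     eq_length = 2.9, lever_arm = 4.5,
                                     base_depth = 4.0) {
  stopifnot(d >= 0)
  build <- function(d, e1, e2) {
    covalent <- 1.0
    hpos <- function(don, acc, q) {
      u <- (acc - don) / sqrt(sum((acc - don)^2))
      (1 - q) * (don + covalent * u) + q * (acc - covalent * u)
    }
    zb1 <- lever_arm / 2; zb2 <- -lever_arm / 2
    a_n6 <- c(-(eq_length + e1) / 2, 0, zb1)  # B1 donor (adenine side)
    t_o4 <- c(+(eq_length + e1) / 2, 0, zb1)  # B1 acceptor (thymine side)
    a_n1 <- c(-(eq_length + e2) / 2, 0, zb2)  # B2 acceptor (adenine side)
    t_n3 <- c(+(eq_length + e2) / 2, 0, zb2)  # B2 donor (thymine side)
    a_piv <- c(-(eq_length / 2 + base_depth + d / 2), 0, 0)  # adenine N9
    t_piv <- c(+(eq_length / 2 + base_depth + d / 2), 0, 0)  # thymine N1
    h_b1 <- hpos(a_n6, t_o4, q1)
    h_b2 <- hpos(t_n3, a_n1, q2)
    rbind(a_piv, a_n6, a_n1, h_b1, t_piv, t_n3, t_o4, h_b2)
  }
  coords <- build(d, ext_b1, ext_b2)
  ref <- build(0, 0, 0)
  molecular_frame(
    labels = c("A:N9", "A:N6", "A:N1", "B1:H", "T:N1", "T:N3", "T:O4", "B2:H"),
    elements = c("N", "N", "N", "H", "N", "N", "O", "H"),
    coords = coords,
    pivot_indices = c(1L, 5L),
    hbonds = list(
      hbond_spec(donor = 2L, hydrogen = 4L, acceptor = 7L, label = "B1",
                 eq_length = eq_length),
      hbond_spec(donor = 6L, hydrogen = 8L, acceptor = 3L, label = "B2",
                 eq_length = eq_length)
    ),
    equilibrium_reference = ref
  )
}
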