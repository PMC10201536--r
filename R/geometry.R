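#' Hydrogen-bond specification
#'
#' Declares one inter-base hydrogen bond by site indices into a
#' [molecular_frame()]. Bonds are declared, never inferred.
#'
#' @param donor Index of the donor heavy atom.
#' @param hydrogen Index of the shared hydrogen.
#' @param acceptor Index of the acceptor heavy atom.
#' @param label "B1" or "B2".
#' @param eq_length Equilibrium heavy-atom to heavy-atom length, Angstrom.
#' @return An object of class `hbond_spec`.
#' @export
hbond_spec <- function(donor, hydrogen, acceptor, label, eq_length = 2.9) {
  idx <- c(donor, hydrogen, acceptor)
  if (anyDuplicated(idx)) stop("hbond_spec: donor, hydrogen, acceptor indices must be distinct")
  if (!label %in% c("B1", "B2")) stop("hbond_spec: label must be 'B1' or 'B2'")
  if (eq_length <= 0) stop("hbond_spec: eq_length must be positive")
  structure(list(donor = as.integer(donor), hydrogen = as.integer(hydrogen),
                 acceptor = as.integer(acceptor), label = label,
                 eq_length = eq_length),
            class = "hbond_spec")
}

#' Labeled 3-D structure of a base pair
#'
#' Holds site labels, element symbols, Cartesian coordinates, the two pivot
#' sites that are fixed to the sugar-phosphate backbone, the two declared
#' hydrogen bonds B1/B2, and optionally the relaxed d = 0 reference
#' coordinates used to measure strand separation.
#'
#' @param labels Character vector of site labels.
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix, n x 3, Angstrom.
#' @param pivot_indices Integer vector of length 2 (one pivot per base).
#' @param hbonds List of exactly two [hbond_spec()]s with distinct labels.
#' @param equilibrium_reference Optional n x 3 matrix of reference coords.
#' @return An object of class `molecular_frame`.
#' @export
molecular_frame <- function(labels, elements, coords, pivot_indices, hbonds,
                            equilibrium_reference = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("molecular_frame: coords must be n x 3")
  n <- nrow(coords)
  if (length(labels) != n || length(elements) != n) {
    stop("molecular_frame: labels/elements must match coords rows")
  }
  if (length(pivot_indices) != 2 || anyDuplicated(pivot_indices)) {
    stop("molecular_frame: need two distinct pivot indices")
  }
  if (length(hbonds) != 2 || !all(vapply(hbonds, inherits, logical(1), "hbond_spec"))) {
    stop("molecular_frame: need exactly two hbond_spec entries")
  }
  labs <- vapply(hbonds, function(h) h$label, character(1))
  if (anyDuplicated(labs)) stop("molecular_frame: hbond labels must be distinct")
  names(hbonds) <- labs
  if (!is.null(equilibrium_reference)) {
    equilibrium_reference <- as.matrix(equilibrium_reference)
    if (!all(dim(equilibrium_reference) == dim(coords))) {
      stop("molecular_frame: equilibrium_reference must match coords dimensions")
    }
  }
  structure(list(labels = labels, elements = elements, coords = coords,
                 pivot_indices = as.integer(pivot_indices), hbonds = hbonds,
                 equilibrium_reference = equilibrium_reference),
            class = "molecular_frame")
}

#' @export
print.molecular_frame <- function(x, ...) {
  cat("<molecular_frame>", nrow(x$coords), "sites; pivots",
      paste(x$labels[x$pivot_indices], collapse = ", "), "\n")
  invisible(x)
}

get_hbond <- function(frame, label) {
  hb <- frame$hbonds[[label]]
  if (is.null(hb)) stop("unknown hydrogen-bond label '", label, "'")
  hb
}

#' Hydrogen-bond length
#'
#' Heavy-atom (donor to acceptor) Euclidean distance. Using the heavy atoms
#' rather than the H...acceptor distance makes the observable insensitive to
#' which well the proton occupies, so canonical and tautomeric forms are
#' measured on the same footing.
#'
#' @param frame A [molecular_frame()].
#' @param label "B1" or "B2".
#' @return Length in Angstrom.
#' @export
hbond_length <- function(frame, label) {
  hb <- get_hbond(frame, label)
  sqrt(sum((frame$coords[hb$donor, ] - frame$coords[hb$acceptor, ])^2))
}

#' Hydrogen-bond extension relative to equilibrium
#'
#' @inheritParams hbond_length
#' @return Extension (length minus `eq_length`), Angstrom; negative when the
#'   bond is compressed.
#' @export
bond_extension <- function(frame, label) {
  hb <- get_hbond(frame, label)
  hbond_length(frame, label) - hb$eq_length
}

#' Strand-separation distance of a frame
#'
#' Summed displacement of the two backbone pivot sites from their positions
#' in the equilibrium reference frame.
#'
#' @param frame A [molecular_frame()] carrying an `equilibrium_reference`.
#' @return Separation in Angstrom.
#' @export
separation_distance <- function(frame) {
  if (is.null(frame$equilibrium_reference)) {
    stop("separation_distance(): frame has no equilibrium_reference")
  }
  sum(vapply(frame$pivot_indices, function(i) {
    sqrt(sum((frame$coords[i, ] - frame$equilibrium_reference[i, ])^2))
  }, numeric(1)))
}

#' Signed base-pair opening angle
#'
#' Lever formula `theta = asin((ext_B2 - ext_B1) / lever_arm)`: the base
#' pair splays by the angle whose sine is the differential bond extension
#' over the distance between the two bond attachment sites. Positive angles
#' mean the pair opens from the B2 end, negative from the B1 end.
#'
#' @param ext_b1,ext_b2 Bond extensions, Angstrom.
#' @param lever_arm Distance between B1 and B2 attachment sites, Angstrom.
#' @return Angle in degrees.
#' @examples
#' opening_angle(0, 4.5 * sin(20 * pi / 180), 4.5)  # +20 degrees
#' @export
opening_angle <- function(ext_b1, ext_b2, lever_arm) {
  if (any(lever_arm <= 0)) stop("opening_angle(): lever_arm must be positive")
  r <- (ext_b2 - ext_b1) / lever_arm
  if (any(abs(r) > 1)) {
    stop("opening_angle(): |ext_B2 - ext_B1| exceeds the lever arm; ",
         "no real angle exists")
  }
  asin(r) * 180 / pi
}

#' Normalized reaction coordinate along a path
#'
#' Maps an ordered chain of images onto `[0, 1]` by cumulative arc length of
#' a per-image descriptor: for 3-D frames the descriptor is the difference
#' between the donor-to-acceptor vectors of bonds B1 and B2; for
#' reduced-coordinate paths (a numeric matrix, one image per row) the
#' descriptor is the coordinate vector itself. The first image maps to 0,
#' the last to 1, and the coordinate is non-decreasing.
#'
#' @param path A list of [molecular_frame()]s, or a numeric matrix with one
#'   image per row.
#' @return Numeric vector in `[0, 1]`, same length as the path.
#' @export
normalized_reaction_coordinate <- function(path) {
  if (is.matrix(path)) {
    n <- nrow(path)
    if (n < 2) stop("normalized_reaction_coordinate(): need at least 2 images")
    desc <- path
  } else if (is.list(path)) {
    n <- length(path)
    if (n < 2) stop("normalized_reaction_coordinate(): need at least 2 images")
    desc <- t(vapply(path, function(fr) {
      b1 <- get_hbond(fr, "B1"); b2 <- get_hbond(fr, "B2")
      v1 <- fr$coords[b1$acceptor, ] - fr$coords[b1$donor, ]
      v2 <- fr$coords[b2$acceptor, ] - fr$coords[b2$donor, ]
      v1 - v2
    }, numeric(3)))
  } else {
    stop("normalized_reaction_coordinate(): path must be a matrix or list of frames")
  }
  seg <- sqrt(rowSums((desc[-1, , drop = FALSE] - desc[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[n] == 0) return(seq(0, 1, length.out = n))
  s / s[n]
}

#' Apply a rigid-body transformation to a frame
#'
#' Rotates (about the origin) and translates all coordinates, including the
#' equilibrium reference if present. Used to verify that geometric
#' observables are frame-invariant.
#'
#' @param frame A [molecular_frame()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 numeric vector.
#' @return The transformed frame.
#' @export
transform_frame <- function(frame, rotation = diag(3), translation = c(0, 0, 0)) {
  tr <- function(m) sweep(m %*% t(rotation), 2, -translation)
  frame$coords <- tr(frame$coords)
  if (!is.null(frame$equilibrium_reference)) {
    frame$equilibrium_reference <- tr(frame$equilibrium_reference)
  }
  frame
}
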