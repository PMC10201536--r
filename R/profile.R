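#' Energy profile along a reaction path
#'
#' @param coord Strictly increasing normalized reaction coordinate in
#'   `[0, 1]`.
#' @param energy Energies, eV.
#' @param rule Interpolation rule id; "cubic" (natural spline) or "linear".
#' @return A tibble of class `energy_profile`.
#' @export
energy_profile <- function(coord, energy, rule = c("cubic", "linear")) {
  rule <- match.arg(rule)
  stopifnot(length(coord) == length(energy), length(coord) >= 2)
  if (any(diff(coord) <= 0)) stop("energy_profile: coord must be strictly increasing")
  if (!all(is.finite(energy))) stop("energy_profile: energies must be finite")
  out <- tibble::tibble(coord = coord, energy = energy)
  class(out) <- c("energy_profile", class(out))
  attr(out, "rule") <- rule
  out
}

#' Coerce a path-search result to an energy profile
#'
#' @param x Object to coerce (e.g. a `neb_path` from [neb_relax()]).
#' @param ... Unused.
#' @return An [energy_profile()].
#' @export
as_energy_profile <- function(x, ...) UseMethod("as_energy_profile")

#' @rdname as_energy_profile
#' @export
as_energy_profile.neb_path <- function(x, ...) energy_profile(x$coord, x$energies)

#' Locate stationary points of an interpolated energy profile
#'
#' Interpolates the profile (cubic spline by default), samples it densely,
#' and reports interior minima and maxima whose prominence (energy contrast
#' to the neighbouring extrema) reaches `prominence`. The two endpoints are
#' always reported as boundary minimum candidates.
#'
#' @param profile An [energy_profile()] (>= 5 points for interior extrema).
#' @param prominence Minimum extremum prominence, eV.
#' @param n_dense Number of dense samples used for localization.
#' @return A tibble with columns `kind` ("minimum"/"maximum"/"boundary"),
#'   `coord`, `energy`.
#' @export
find_stationary_points <- function(profile, prominence = 0.005, n_dense = 2001) {
  stopifnot(inherits(profile, "energy_profile"))
  x <- profile$coord; y <- profile$energy
  if (attr(profile, "rule") == "cubic" && length(x) >= 4) {
    f <- stats::splinefun(x, y, method = "natural")
  } else {
    f <- stats::approxfun(x, y)
  }
  xs <- seq(min(x), max(x), length.out = n_dense)
  ys <- f(xs)
  d <- diff(ys)
  sgn <- sign(d)
  turn <- which(sgn[-1] * sgn[-length(sgn)] < 0) + 1L
  ext <- tibble::tibble(
    kind = if (length(turn)) ifelse(d[turn] < 0, "maximum", "minimum") else character(0),
    coord = xs[turn], energy = ys[turn]
  )
  # prominence pruning by pair annihilation: repeatedly find the adjacent
  # pair of extrema (endpoints included) with the smallest energy contrast;
  # if it is below the prominence threshold, the pair is spurious structure
  # and its interior member(s) are removed.
  repeat {
    if (!nrow(ext)) break
    all_e <- c(ys[1], ext$energy, ys[n_dense])
    contrast <- abs(diff(all_e))
    i <- which.min(contrast)
    if (contrast[i] >= prominence) break
    # pair (i, i+1) in all_e maps to interior indices (i-1, i)
    drop <- intersect(c(i - 1L, i), seq_len(nrow(ext)))
    drop <- drop[drop >= 1L]
    ext <- ext[-drop, , drop = FALSE]
  }
  dplyr::bind_rows(
    tibble::tibble(kind = "boundary", coord = xs[1], energy = ys[1]),
    ext,
    tibble::tibble(kind = "boundary", coord = xs[n_dense], energy = ys[n_dense])
  )
}

#' Reaction asymmetry
#'
#' Product energy minus reactant energy along a transfer step; positive when
#' the product lies above the reactant (the canonical state is the most
#' stable, so both transfer asymmetries are positive on the model surface).
#'
#' @param e_reactant,e_product Energies, eV.
#' @return Asymmetry, eV.
#' @export
reaction_asymmetry <- function(e_reactant, e_product) e_product - e_reactant

#' Extract per-step barriers from a profile
#'
#' Classifies the stationary structure of a converged path profile and reads
#' off the forward/reverse barrier of each proton-transfer step. Two
#' patterns are admissible: min-max-min (single transfer only; the
#' double-transfer well is unbound) and min-max-min-max-min (both steps).
#'
#' @param profile An [energy_profile()].
#' @param d Strand separation the path was computed at, Angstrom.
#' @param stationary Optional precomputed [find_stationary_points()] table.
#' @param prominence Passed to [find_stationary_points()].
#' @return One-row tibble (a `BarrierSet`): `d`, `Ef1`, `Er1`, `Ef2`, `Er2`,
#'   `A_spt`, `A_dpt`, `dpt_bound`.
#' @export
extract_barriers <- function(profile, d = NA_real_, stationary = NULL,
                             prominence = 0.005) {
  if (is.null(stationary)) {
    stationary <- find_stationary_points(profile, prominence = prominence)
  }
  st <- stationary
  # boundary rows are the path endpoints, always minima candidates
  kinds <- st$kind
  interior <- st[kinds %in% c("minimum", "maximum"), ]
  e0 <- st$energy[kinds == "boundary"][1]
  e_end <- st$energy[kinds == "boundary"][length(which(kinds == "boundary"))]
  pat <- paste(substr(interior$kind, 1, 3), collapse = "-")
  if (pat == "max") {
    ts1 <- interior$energy[1]
    tibble::tibble(d = d, Ef1 = ts1 - e0, Er1 = ts1 - e_end,
                   Ef2 = NA_real_, Er2 = NA_real_,
                   A_spt = e_end - e0, A_dpt = NA_real_, dpt_bound = FALSE)
  } else if (pat == "max-min-max") {
    ts1 <- interior$energy[1]; mid <- interior$energy[2]; ts2 <- interior$energy[3]
    tibble::tibble(d = d, Ef1 = ts1 - e0, Er1 = ts1 - mid,
                   Ef2 = ts2 - mid, Er2 = ts2 - e_end,
                   A_spt = mid - e0, A_dpt = e_end - e0, dpt_bound = TRUE)
  } else {
    stop("extract_barriers(): unrecognized stationary pattern '", pat,
         "' (admissible: one or two maxima separated by minima)")
  }
}

#' Classify the stability of the double-transfer product
#'
#' @param barriers A one-row BarrierSet tibble from [extract_barriers()] or
#'   [barrier_targets()].
#' @param epsilon Unbound threshold, eV: no tautomer minimum, or a reverse
#'   barrier at or below this, is "unbound".
#' @param metastable_threshold eV; a reverse barrier at or below this (about
#'   2 kT at body temperature) is "metastable", deeper is "stable".
#' @return One of "unbound", "metastable", "stable".
#' @export
classify_stability <- function(barriers, epsilon = 0.005,
                               metastable_threshold = 0.05) {
  er2 <- barriers$Er2[1]
  if (!isTRUE(barriers$dpt_bound[1]) || is.na(er2) || er2 <= epsilon) {
    "unbound"
  } else if (er2 <= metastable_threshold) {
    "metastable"
  } else {
    "stable"
  }
}

#' Detect the onset separation of tautomer stability
#'
#' @param barrier_tbl A BarrierSet table ordered by `d` with a
#'   `classification` column (or `dpt_bound`/`Er2` columns from which the
#'   classification can be derived).
#' @param epsilon Unbound threshold passed to [classify_stability()].
#' @return The smallest scanned `d` whose classification is not "unbound",
#'   Angstrom.
#' @export
detect_onset <- function(barrier_tbl, epsilon = 0.005) {
  stopifnot(nrow(barrier_tbl) >= 2)
  if (!"classification" %in% names(barrier_tbl)) {
    barrier_tbl$classification <- vapply(
      seq_len(nrow(barrier_tbl)),
      function(i) classify_stability(barrier_tbl[i, ], epsilon = epsilon),
      character(1))
  }
  ok <- barrier_tbl$classification != "unbound"
  if (!any(ok)) {
    stop("detect_onset(): no scanned separation has a bound double-transfer minimum")
  }
  min(barrier_tbl$d[ok])
}

#' Least-squares power-law fit in log-log space
#'
#' Fits `y = A x^p` by ordinary least squares on `log y ~ log x`. On
#' noiseless power-law data the exponent is recovered exactly; degenerate
#' (constant-y) input returns p = 0.
#'
#' @param x Positive predictor values (e.g. separation distances, A).
#' @param y Positive response values (e.g. barrier increases, eV).
#' @return Object of class `power_law_fit`: list with `exponent`,
#'   `prefactor`, `r_squared`, `n`, and the underlying `lm` fit.
#' @examples
#' fit_power_law(c(1, 2, 3), 2 * c(1, 2, 3)^1.894)$exponent
#' @export
fit_power_law <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("fit_power_law(): need at least 3 finite pairs")
  if (any(x <= 0) || any(y <= 0)) {
    stop("fit_power_law(): x and y must be positive for a log-log fit")
  }
  fit <- stats::lm(log(y) ~ log(x))
  p <- unname(stats::coef(fit)[2])
  a <- exp(unname(stats::coef(fit)[1]))
  r2 <- suppressWarnings(summary(fit))$r.squared
  if (!is.finite(r2)) r2 <- 1  # constant response: zero residual, zero variance
  structure(list(exponent = p, prefactor = a, r_squared = r2,
                 n = length(x), fit = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * x^%.4f (R^2 = %.4f, n = %d)\n",
              x$prefactor, x$exponent, x$r_squared, x$n))
  invisible(x)
}
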