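#' Linear interpolation between two endpoint states
#'
#' Initial path guess for the elastic-band search: straight-line
#' interpolation in the reduced coordinates with endpoints preserved
#' exactly.
#'
#' @param reactant,product Numeric coordinate vectors of equal length; must
#'   differ.
#' @param n_images Total number of images including the endpoints (>= 3).
#' @return Numeric matrix, one image per row.
#' @examples
#' interpolate_path(c(0, 0), c(1, 1), 3)
#' @export
interpolate_path <- function(reactant, product, n_images = 15) {
  stopifnot(length(reactant) == length(product), n_images >= 3)
  if (all(reactant == product)) {
    stop("interpolate_path(): reactant and product are identical")
  }
  t <- seq(0, 1, length.out = n_images)
  out <- outer(1 - t, reactant) + outer(t, product)
  out[1, ] <- reactant; out[n_images, ] <- product
  out
}

# improved-tangent estimate (energy-weighted switch at extrema)
neb_tangents <- function(path, energies) {
  n <- nrow(path)
  tau <- matrix(0, n, ncol(path))
  for (i in 2:(n - 1)) {
    dp <- path[i + 1, ] - path[i, ]
    dm <- path[i, ] - path[i - 1, ]
    ep <- energies[i + 1]; e0 <- energies[i]; em <- energies[i - 1]
    if (ep > e0 && e0 > em) {
      t <- dp
    } else if (ep < e0 && e0 < em) {
      t <- dm
    } else {
      dmax <- max(abs(ep - e0), abs(em - e0))
      dmin <- min(abs(ep - e0), abs(em - e0))
      t <- if (ep > em) dp * dmax + dm * dmin else dp * dmin + dm * dmax
    }
    tau[i, ] <- t / sqrt(sum(t^2))
  }
  tau
}

# indices of interior images that are local energy maxima
path_maxima <- function(energies) {
  n <- length(energies)
  which(vapply(2:(n - 1), function(i) {
    energies[i] > energies[i - 1] && energies[i] > energies[i + 1]
  }, logical(1))) + 1L
}

# local maxima with topographic prominence >= prom: transient wiggles of a
# partially relaxed band must not become climbing images (a spurious
# climbing image on a monotone slope would ascend indefinitely)
prominent_maxima <- function(energies, prom = 1e-3) {
  idx <- path_maxima(energies)
  n <- length(energies)
  idx[vapply(idx, function(i) {
    left <- min(energies[1:i]); right <- min(energies[i:n])
    min(energies[i] - left, energies[i] - right) >= prom
  }, logical(1))]
}

#' Nudged-elastic-band relaxation of a path
#'
#' Standard NEB with the improved-tangent projection: each interior image
#' feels the true force perpendicular to the local tangent plus a spring
#' force along it; with `climbing_image` on, every interior image that is a
#' local maximum of the profile instead climbs along the tangent so it
#' converges onto the saddle point itself. The band is relaxed with a FIRE
#' (fast inertial relaxation engine) integrator. Endpoints never move.
#'
#' @param path Initial path matrix (one image per row), e.g. from
#'   [interpolate_path()].
#' @param model List with `energy(x)` and `gradient(x)`.
#' @param config An [mlneb_config()] (supplies `force_tolerance`,
#'   `spring_k`, `climbing_image`).
#' @param max_iter Iteration cap.
#' @param on_fail "error" (default) raises on non-convergence; "return"
#'   hands back the best partial band with `converged = FALSE` (used by the
#'   surrogate loop, which refines the model between relaxations).
#' @return List of class `neb_path`: `path` matrix, `energies`, `coord`
#'   (normalized reaction coordinate), `n_force_calls`, `converged`,
#'   `iterations`.
#' @export
neb_relax <- function(path, model, config = mlneb_config(), max_iter = 3000,
                      on_fail = c("error", "return")) {
  on_fail <- match.arg(on_fail)
  stopifnot(is.matrix(path), nrow(path) >= 3)
  n <- nrow(path); m <- ncol(path)
  interior <- 2:(n - 1)
  k <- config$spring_k
  ftol <- config$force_tolerance
  calls <- 0L
  evaluate <- function(p) {
    calls <<- calls + length(interior)
    if (!is.null(model$energy_batch)) {
      cbind(model$energy_batch(p[interior, , drop = FALSE]),
            model$gradient_batch(p[interior, , drop = FALSE]))
    } else {
      t(vapply(interior, function(i) {
        c(model$energy(p[i, ]), model$gradient(p[i, ]))
      }, numeric(1 + m)))
    }
  }
  e_ends <- c(model$energy(path[1, ]), model$energy(path[n, ]))

  # FIRE state
  v <- matrix(0, n, m)
  dt <- 0.05; dt_max <- 0.25; n_up <- 0L
  f_inc <- 1.1; f_dec <- 0.5; alpha0 <- 0.1; alpha <- alpha0

  # equal-arc-length redistribution of the interior images (string-method
  # reparametrization): prevents images from sliding along the band into
  # the wells, which leaves kinks and switchbacks in flat valleys
  redistribute <- function(p) {
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    if (s[n] == 0) return(p)
    targets <- seq(0, s[n], length.out = n)
    out <- p
    for (i in interior) {
      ti <- targets[i]
      j <- findInterval(ti, s, rightmost.closed = TRUE)
      j <- min(max(j, 1L), n - 1L)
      w <- if (seg[j] > 0) (ti - s[j]) / seg[j] else 0
      out[i, ] <- (1 - w) * p[j, ] + w * p[j + 1, ]
    }
    out
  }

  converged <- FALSE; it <- 0L
  energies <- NULL
  best <- NULL; best_res <- Inf  # lowest-residual band seen, for on_fail = "return"
  climb_active <- FALSE  # climbing switches on once the band is roughly relaxed
  climb_set <- integer(0)
  # designated once, when the band is already well relaxed: re-designating
  # every iteration lets a transient bump near an endpoint become a
  # "maximum" that then ascends a monotone slope indefinitely
  designate_climb <- function(energies) {
    idx <- prominent_maxima(energies, prom = 5e-3)
    if (!length(idx)) {
      gm <- which.max(energies)
      if (gm > 1 && gm < length(energies)) idx <- gm
    }
    idx
  }
  for (it in seq_len(max_iter)) {
    eg <- evaluate(path)
    if (!all(is.finite(eg))) {
      if (on_fail == "return" && !is.null(best)) {
        path <- best$path; energies <- best$energies; break
      }
      stop("neb_relax(): non-finite energy or gradient encountered")
    }
    energies <- c(e_ends[1], eg[, 1], e_ends[2])
    grads <- eg[, -1, drop = FALSE]
    tau <- neb_tangents(path, energies)
    climb <- if (config$climbing_image && climb_active) climb_set else integer(0)

    forces <- matrix(0, n, m)
    fmax_perp <- 0
    for (ii in seq_along(interior)) {
      i <- interior[ii]
      g <- grads[ii, ]; t_i <- tau[i, ]
      g_par <- sum(g * t_i) * t_i
      g_perp <- g - g_par
      if (i %in% climb) {
        forces[i, ] <- -g + 2 * g_par   # climb: invert the parallel component
        fmax_perp <- max(fmax_perp, sqrt(sum(g^2)))  # full force at the saddle
      } else if (climb_active) {
        dplus <- sqrt(sum((path[i + 1, ] - path[i, ])^2))
        dminus <- sqrt(sum((path[i, ] - path[i - 1, ])^2))
        f_spring <- k * (dplus - dminus) * t_i
        forces[i, ] <- -g_perp + f_spring
        fmax_perp <- max(fmax_perp, sqrt(sum(g_perp^2)))
      } else {
        # string phase: pure perpendicular descent; the tangential degrees
        # of freedom are handled by reparametrization
        forces[i, ] <- -g_perp
        fmax_perp <- max(fmax_perp, sqrt(sum(g_perp^2)))
      }
    }
    if (fmax_perp < best_res) {
      best <- list(path = path, energies = energies); best_res <- fmax_perp
    }
    if (fmax_perp <= ftol) {
      if (climb_active || !config$climbing_image) { converged <- TRUE; break }
      climb_active <- TRUE        # plain band converged; refine the saddles
      climb_set <- designate_climb(energies)
      v[] <- 0; dt <- 0.05
      next
    }
    if (!climb_active && config$climbing_image &&
        fmax_perp <= max(5 * ftol, 0.05)) {
      climb_active <- TRUE
      climb_set <- designate_climb(energies)
      v[] <- 0; dt <- 0.05
    }

    if (!climb_active) {
      # string phase: capped perpendicular-descent step, then redistribute
      step <- 0.02 * forces
      smax <- 0.03
      sn <- sqrt(rowSums(step^2))
      over <- sn > smax
      if (any(over)) step[over, ] <- step[over, ] * (smax / sn[over])
      path[interior, ] <- path[interior, ] + step[interior, , drop = FALSE]
      path <- redistribute(path)
    } else {
      # FIRE update on interior images
      p <- sum(forces * v)
      if (p > 0) {
        n_up <- n_up + 1L
        if (n_up > 5) { dt <- min(dt * f_inc, dt_max); alpha <- alpha * 0.99 }
        fn <- sqrt(sum(forces^2)); vn <- sqrt(sum(v^2))
        if (fn > 0) v <- (1 - alpha) * v + alpha * forces * (vn / fn)
      } else {
        v[] <- 0; dt <- dt * f_dec; alpha <- alpha0; n_up <- 0L
      }
      v <- v + dt * forces
      step <- dt * v
      smax <- 0.05  # cap the per-iteration displacement
      sn <- sqrt(rowSums(step^2))
      over <- sn > smax
      if (any(over)) step[over, ] <- step[over, ] * (smax / sn[over])
      path[interior, ] <- path[interior, ] + step[interior, , drop = FALSE]
    }
  }
  if (!converged) {
    if (on_fail == "return") {
      if (!is.null(best)) { path <- best$path; energies <- best$energies }
    } else {
      stop("neb_relax(): no convergence after ", max_iter,
           " iterations (residual force ", format(fmax_perp), " eV/coord)")
    }
  }
  structure(list(path = path, energies = energies,
                 coord = normalized_reaction_coordinate(path),
                 n_force_calls = calls, converged = converged,
                 iterations = it),
            class = "neb_path")
}

#' @export
print.neb_path <- function(x, ...) {
  cat("<neb_path>", nrow(x$path), "images; barrier",
      format(max(x$energies) - x$energies[1], digits = 4), "eV;",
      x$n_force_calls, "force calls\n")
  invisible(x)
}
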