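#' Surrogate-accelerated minimum-energy-path search
#'
#' Reconstructs the minimum energy path with far fewer true-model
#' evaluations than a plain elastic-band search. Each true-model call
#' returns an energy and its gradient, and both enter a
#' derivative-enhanced Gaussian-process surrogate of the landscape; the
#' band is relaxed on the surrogate, and the true model is queried only at
#' the image with the largest predictive uncertainty (ties broken toward
#' the higher predicted mean). Acquisition stops once the predictive
#' standard deviation along the whole surrogate path is below
#' `uncertainty_tolerance`; a short warm-started band relaxation on the
#' true model then certifies force convergence. The
#' `max_true_evaluations` budget governs the acquisition loop;
#' `n_true_evaluations` reports all true-model work including the final
#' certification.
#'
#' @param reactant,product Pre-relaxed endpoint coordinate vectors (minima
#'   of the true model).
#' @param model True model: list with `energy(x)` and `gradient(x)`.
#' @param config An [mlneb_config()].
#' @return List of class `mlneb_result`: `path` (converged `neb_path` with
#'   true energies), `surrogate`, `log` (tibble of true-model evaluations
#'   in order), `n_true_evaluations`.
#' @export
mlneb_run <- function(reactant, product, model, config = mlneb_config()) {
  ndim <- length(reactant)
  stopifnot(length(product) == ndim)
  path <- interpolate_path(reactant, product, config$n_images)
  interior <- 2:(config$n_images - 1)

  # seed the training set along the straight-line guess
  seed_idx <- unique(round(seq(1, config$n_images, length.out = 5)))
  X <- path[seed_idx, , drop = FALSE]
  y <- apply(X, 1, model$energy)
  G <- t(apply(X, 1, model$gradient))
  n_true <- nrow(X)
  log_tbl <- tibble::tibble(eval = seq_len(n_true), reason = "seed",
                            q1 = X[, 1],
                            q2 = if (ndim > 1) X[, 2] else NA_real_,
                            energy = y)

  # trust box: the surrogate is only informative near its data, so the
  # surrogate-band relaxation is confined to a box around the endpoints by
  # quadratic walls (the GP mean reverts to the flat prior far away and
  # would otherwise let the band wander)
  lo <- pmin(reactant, product) - 0.4
  hi <- pmax(reactant, product) + 0.4
  kw <- 10
  box_e <- function(x) kw * sum(pmin(x - lo, 0)^2 + pmax(x - hi, 0)^2)
  box_g <- function(x) 2 * kw * (pmin(x - lo, 0) + pmax(x - hi, 0))

  acq <- 0L
  gp <- gp_fit_grad(X, y, G, optimize_hyper = TRUE)
  repeat {
    gp_local <- gp
    smodel <- list(
      energy = function(x) gp_predict_grad(gp_local, x)$mean + box_e(x),
      gradient = function(x) {
        as.vector(gp_mean_gradient_grad(gp_local, x)) + box_g(x)
      },
      energy_batch = function(P) {
        gp_predict_grad(gp_local, P)$mean + apply(P, 1, box_e)
      },
      gradient_batch = function(P) {
        gp_mean_gradient_grad(gp_local, P) + t(apply(P, 1, box_g))
      }
    )
    relaxed <- neb_relax(path, smodel, config, max_iter = 500,
                         on_fail = "return")
    path <- relaxed$path

    pred <- gp_predict_grad(gp, path[interior, , drop = FALSE])
    # converged only when the band is relaxed on the surrogate AND the
    # surrogate is certain along it
    if (relaxed$converged && max(pred$sd) <= config$uncertainty_tolerance) break

    # acquisition at the most uncertain image (ties: higher predicted mean)
    ord <- order(-pred$sd, -pred$mean)
    xnew <- path[interior[ord[1]], ]
    if (min(sqrt(rowSums(sweep(X, 2, xnew)^2))) < 1e-8) {
      xnew <- path[interior[ord[2]], ]
      if (min(sqrt(rowSums(sweep(X, 2, xnew)^2))) < 1e-8) break
    }
    n_true <- n_true + 1L
    if (n_true > config$max_true_evaluations) {
      stop("mlneb_run(): true-evaluation budget (",
           config$max_true_evaluations, ") exhausted")
    }
    enew <- model$energy(xnew)
    gnew <- model$gradient(xnew)
    X <- rbind(X, xnew); y <- c(y, enew); G <- rbind(G, gnew)
    log_tbl <- dplyr::bind_rows(log_tbl, tibble::tibble(
      eval = nrow(log_tbl) + 1L, reason = "acquire",
      q1 = xnew[1], q2 = if (ndim > 1) xnew[2] else NA_real_, energy = enew))
    acq <- acq + 1L
    gp <- gp_fit_grad(X, y, G, lengthscales = gp$lengthscales,
                      sigma_f = gp$sigma_f, optimize_hyper = (acq %% 5 == 0))
  }

  # certification: short elastic-band relaxation on the true model from the
  # surrogate-converged band
  polish <- neb_relax(path, model, config, max_iter = 1500)
  n_true <- n_true + polish$n_force_calls

  structure(list(path = polish, surrogate = gp, log = log_tbl,
                 n_true_evaluations = n_true),
            class = "mlneb_result")
}

#' @export
print.mlneb_result <- function(x, ...) {
  cat("<mlneb_result>", x$n_true_evaluations, "true evaluations; barrier",
      format(max(x$path$energies) - x$path$energies[1], digits = 4), "eV\n")
  invisible(x)
}
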