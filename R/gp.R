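# Gaussian-process regression with a squared-exponential kernel.
# This is the surrogate engine of the accelerated path search: it
# interpolates the expensive model's energies and reports a predictive
# standard deviation that drives both the acquisition rule and the
# convergence criterion.

se_kernel <- function(X1, X2, lengthscales, sigma_f) {
  X1s <- sweep(X1, 2, lengthscales, "/")
  X2s <- sweep(X2, 2, lengthscales, "/")
  d2 <- outer(rowSums(X1s^2), rowSums(X2s^2), "+") - 2 * X1s %*% t(X2s)
  d2[d2 < 0] <- 0
  sigma_f^2 * exp(-0.5 * d2)
}

#' Fit a Gaussian-process surrogate to energy observations
#'
#' Squared-exponential kernel with per-dimension length scales, a constant
#' prior mean equal to the observation mean, a small noise floor, and
#' jitter-protected Cholesky factorization. With `optimize_hyper = TRUE`
#' the signal variance and length scales are refit by marginal-likelihood
#' maximization.
#'
#' @param X Numeric matrix of training coordinates (one point per row).
#' @param y Energies at the training points, eV.
#' @param lengthscales Initial per-dimension kernel length scales.
#' @param sigma_f Initial signal standard deviation, eV.
#' @param noise Observation noise standard deviation floor, eV.
#' @param optimize_hyper Refit hyperparameters by maximum marginal
#'   likelihood?
#' @return Object of class `gp_surrogate`.
#' @export
gp_fit <- function(X, y, lengthscales = NULL, sigma_f = NULL,
                   noise = 1e-6, optimize_hyper = FALSE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1)
  ndim <- ncol(X)
  if (is.null(lengthscales)) lengthscales <- rep(0.3, ndim)
  if (is.null(sigma_f)) sigma_f <- max(stats::sd(y), 0.1)
  mu <- mean(y)

  chol_K <- function(ls, sf) {
    K <- se_kernel(X, X, ls, sf) + diag(noise^2 + 1e-10, nrow(X))
    jitter <- 1e-10
    for (try in 1:8) {
      ch <- tryCatch(chol(K + diag(jitter, nrow(X))), error = function(e) NULL)
      if (!is.null(ch)) return(ch)
      jitter <- jitter * 100
    }
    stop("gp_fit(): kernel matrix not positive definite even with jitter")
  }

  if (optimize_hyper && nrow(X) >= 4) {
    nll <- function(theta) {
      ls <- exp(theta[seq_len(ndim)]); sf <- exp(theta[ndim + 1])
      ch <- tryCatch(chol_K(ls, sf), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      a <- backsolve(ch, forwardsolve(t(ch), y - mu))
      0.5 * sum((y - mu) * a) + sum(log(diag(ch)))
    }
    op <- stats::optim(log(c(lengthscales, sigma_f)), nll, method = "L-BFGS-B",
                       lower = log(c(rep(0.05, ndim), 1e-3)),
                       upper = log(c(rep(5, ndim), 100)),
                       control = list(maxit = 50))
    lengthscales <- exp(op$par[seq_len(ndim)])
    sigma_f <- exp(op$par[ndim + 1])
  }

  ch <- chol_K(lengthscales, sigma_f)
  alpha <- backsolve(ch, forwardsolve(t(ch), y - mu))
  structure(list(X = X, y = y, mu = mu, lengthscales = lengthscales,
                 sigma_f = sigma_f, noise = noise, chol = ch, alpha = alpha),
            class = "gp_surrogate")
}

#' Predict mean and uncertainty from a Gaussian-process surrogate
#'
#' @param gp A [gp_fit()] surrogate.
#' @param Xnew Matrix of query points (one per row) or a single vector.
#' @return Tibble with `mean` (eV) and `sd` (eV) per query point.
#' @export
gp_predict <- function(gp, Xnew) {
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  Ks <- se_kernel(Xnew, gp$X, gp$lengthscales, gp$sigma_f)
  mean <- gp$mu + as.vector(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$chol), t(Ks))
  var <- pmax(gp$sigma_f^2 - colSums(v^2), 0)
  tibble::tibble(mean = mean, sd = sqrt(var))
}

# analytic gradient of the posterior mean (needed by the surrogate path
# relaxation)
gp_mean_gradient <- function(gp, x) {
  x <- as.numeric(x)
  Ks <- se_kernel(matrix(x, 1), gp$X, gp$lengthscales, gp$sigma_f)  # 1 x n
  diffs <- sweep(gp$X, 2, x, "-")            # n x d, (X_i - x)
  w <- as.vector(Ks) * gp$alpha              # n
  # d/dx k(x, Xi) = k(x, Xi) * (Xi - x) / ls^2
  as.vector(colSums(diffs * w) / gp$lengthscales^2)
}

# ---- derivative-enhanced GP -------------------------------------------------
# Each true-model call yields the energy AND its gradient; including the
# gradient observations in the regression makes the surrogate locally
# first-order exact, which is what lets the uncertainty criterion certify
# the surrogate path. Joint covariance blocks of the SE kernel:
#   cov(f, f')      = k
#   cov(f, g'_b)    =  k * (x_b - x'_b) / l_b^2
#   cov(g_a, f')    = -k * (x_a - x'_a) / l_a^2
#   cov(g_a, g'_b)  =  k * (d_ab / l_a^2 - (x_a - x'_a)(x_b - x'_b) / (l_a^2 l_b^2))
# Observations are stacked values-first, then gradients grouped by dimension.

joint_K <- function(X1, X2, ls, sf) {
  n1 <- nrow(X1); n2 <- nrow(X2); d <- ncol(X1)
  Kff <- se_kernel(X1, X2, ls, sf)
  D <- lapply(seq_len(d), function(b) outer(X1[, b], X2[, b], "-"))
  K <- matrix(0, n1 * (1 + d), n2 * (1 + d))
  K[1:n1, 1:n2] <- Kff
  for (b in seq_len(d)) {
    cols <- n2 + (b - 1) * n2 + seq_len(n2)
    K[1:n1, cols] <- Kff * D[[b]] / ls[b]^2
  }
  for (a in seq_len(d)) {
    rows <- n1 + (a - 1) * n1 + seq_len(n1)
    K[rows, 1:n2] <- -Kff * D[[a]] / ls[a]^2
    for (b in seq_len(d)) {
      cols <- n2 + (b - 1) * n2 + seq_len(n2)
      delta <- if (a == b) 1 / ls[a]^2 else 0
      K[rows, cols] <- Kff * (delta - D[[a]] * D[[b]] / (ls[a]^2 * ls[b]^2))
    }
  }
  K
}

gp_fit_grad <- function(X, y, G, lengthscales = NULL, sigma_f = NULL,
                        noise_f = 1e-5, noise_g = 1e-4,
                        optimize_hyper = FALSE) {
  X <- as.matrix(X); G <- as.matrix(G)
  n <- nrow(X); d <- ncol(X)
  stopifnot(length(y) == n, nrow(G) == n, ncol(G) == d)
  if (is.null(lengthscales)) lengthscales <- rep(0.3, d)
  if (is.null(sigma_f)) sigma_f <- max(stats::sd(y), 0.1)
  mu <- mean(y)
  obs <- c(y - mu, as.vector(G))
  noise_diag <- c(rep(noise_f^2, n), rep(noise_g^2, n * d))

  chol_K <- function(ls, sf) {
    K <- joint_K(X, X, ls, sf) + diag(noise_diag + 1e-10)
    jitter <- 1e-10
    for (try in 1:8) {
      ch <- tryCatch(chol(K + diag(jitter, nrow(K))), error = function(e) NULL)
      if (!is.null(ch)) return(ch)
      jitter <- jitter * 100
    }
    stop("gp_fit_grad(): kernel matrix not positive definite even with jitter")
  }

  if (optimize_hyper && n >= 3) {
    nll <- function(theta) {
      ls <- exp(theta[seq_len(d)]); sf <- exp(theta[d + 1])
      ch <- tryCatch(chol_K(ls, sf), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      a <- backsolve(ch, forwardsolve(t(ch), obs))
      val <- 0.5 * sum(obs * a) + sum(log(diag(ch)))
      if (!is.finite(val)) 1e10 else val
    }
    op <- stats::optim(log(c(lengthscales, sigma_f)), nll, method = "L-BFGS-B",
                       lower = log(c(rep(0.05, d), 1e-3)),
                       upper = log(c(rep(5, d), 100)),
                       control = list(maxit = 40))
    lengthscales <- exp(op$par[seq_len(d)])
    sigma_f <- exp(op$par[d + 1])
  }

  ch <- chol_K(lengthscales, sigma_f)
  alpha <- backsolve(ch, forwardsolve(t(ch), obs))
  structure(list(X = X, y = y, G = G, mu = mu, lengthscales = lengthscales,
                 sigma_f = sigma_f, chol = ch, alpha = alpha),
            class = "gp_surrogate_grad")
}

# cross-covariance rows between f(Q) and the joint training observations
joint_ks <- function(gp, Q) {
  n <- nrow(gp$X); d <- ncol(gp$X)
  Kff <- se_kernel(Q, gp$X, gp$lengthscales, gp$sigma_f)
  out <- matrix(0, nrow(Q), n * (1 + d))
  out[, 1:n] <- Kff
  for (b in seq_len(d)) {
    Dq <- outer(Q[, b], gp$X[, b], "-")
    out[, n + (b - 1) * n + seq_len(n)] <- Kff * Dq / gp$lengthscales[b]^2
  }
  out
}

gp_predict_grad <- function(gp, Q) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  Ks <- joint_ks(gp, Q)
  mean <- gp$mu + as.vector(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$chol), t(Ks))
  var <- pmax(gp$sigma_f^2 - colSums(v^2), 0)
  tibble::tibble(mean = mean, sd = sqrt(var))
}

# gradient of the posterior mean at each row of Q
gp_mean_gradient_grad <- function(gp, Q) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  n <- nrow(gp$X); d <- ncol(gp$X)
  ls <- gp$lengthscales
  out <- matrix(0, nrow(Q), d)
  Kff <- se_kernel(Q, gp$X, ls, gp$sigma_f)
  Dq <- lapply(seq_len(d), function(b) outer(Q[, b], gp$X[, b], "-"))
  for (a in seq_len(d)) {
    # rows cov(g_a(q), obs): against values then against each gradient dim
    blocks <- matrix(0, nrow(Q), n * (1 + d))
    blocks[, 1:n] <- -Kff * Dq[[a]] / ls[a]^2
    for (b in seq_len(d)) {
      delta <- if (a == b) 1 / ls[a]^2 else 0
      blocks[, n + (b - 1) * n + seq_len(n)] <-
        Kff * (delta - Dq[[a]] * Dq[[b]] / (ls[a]^2 * ls[b]^2))
    }
    out[, a] <- blocks %*% gp$alpha
  }
  out
}

#' @export
print.gp_surrogate_grad <- function(x, ...) {
  cat("<gp_surrogate_grad>", nrow(x$X), "energy+force observations;",
      "lengthscales", paste(signif(x$lengthscales, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.gp_surrogate <- function(x, ...) {
  cat("<gp_surrogate>", nrow(x$X), "observations; lengthscales",
      paste(signif(x$lengthscales, 3), collapse = ", "),
      "; sigma_f", signif(x$sigma_f, 3), "\n")
  invisible(x)
}
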