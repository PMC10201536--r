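#' Quasi-Newton relaxation with frozen coordinates
#'
#' Minimizes a differentiable energy model over the unconstrained
#' coordinates while holding a fixed set bit-identical to its input values
#' (the scan protocol freezes the backbone pivot positions this way).
#' Uses L-BFGS-B restarts until the gradient norm over the free coordinates
#' drops below `tol`.
#'
#' @param x0 Numeric start vector.
#' @param fixed Integer indices of coordinates to freeze (may be empty for
#'   free relaxation).
#' @param model List with `energy(x)` and `gradient(x)` functions.
#' @param tol Convergence tolerance on the free-gradient norm, eV/coordinate.
#' @param max_steps Iteration budget.
#' @param lower,upper Optional box bounds (recycled over coordinates). Used
#'   to keep a relaxation inside one basin of a multi-well landscape, where
#'   an unguarded line search could hop a low barrier into a deeper well.
#' @return List with `x` (relaxed vector), `energy`, `grad_norm`, `steps`.
#' @export
relax_constrained <- function(x0, fixed = integer(0), model,
                              tol = 0.01, max_steps = 500,
                              lower = -Inf, upper = Inf) {
  stopifnot(is.numeric(x0), is.function(model$energy), is.function(model$gradient))
  fixed <- as.integer(fixed)
  free <- setdiff(seq_along(x0), fixed)
  if (!length(free)) stop("relax_constrained(): no free coordinates")
  lower <- rep_len(lower, length(x0)); upper <- rep_len(upper, length(x0))
  x <- x0
  splice <- function(xf) { x[free] <- xf; x }
  gn <- function(xx) {
    g <- model$gradient(xx)
    # projected gradient: drop components blocked by an active box bound
    g[xx <= lower & g > 0] <- 0
    g[xx >= upper & g < 0] <- 0
    sqrt(sum(g[free]^2))
  }
  steps <- 0L
  if (gn(x) <= tol) {
    return(list(x = x, energy = model$energy(x), grad_norm = gn(x), steps = 0L))
  }
  while (steps < max_steps) {
    budget <- min(100L, max_steps - steps)
    op <- stats::optim(
      par = x[free],
      fn = function(xf) model$energy(splice(xf)),
      gr = function(xf) model$gradient(splice(xf))[free],
      method = "L-BFGS-B", lower = lower[free], upper = upper[free],
      control = list(maxit = budget, factr = 10, pgtol = tol / 100))
    steps <- steps + budget
    x[free] <- op$par
    if (gn(x) <= tol) {
      return(list(x = x, energy = model$energy(x), grad_norm = gn(x),
                  steps = steps))
    }
  }
  cond <- structure(
    class = c("tautopath_convergence_error", "error", "condition"),
    list(message = paste0("relax_constrained(): gradient norm ",
                          format(gn(x)), " > tol ", tol, " after ",
                          steps, " steps"),
         call = sys.call(-1), last_state = x))
  stop(cond)
}
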