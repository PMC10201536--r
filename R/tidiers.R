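#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a power-law fit
#'
#' One row per coefficient of the underlying log-log regression, mapped
#' back to the power-law parameterization `y = A x^p`.
#'
#' @param x A [fit_power_law()] object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.power_law_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("prefactor", "exponent"),
    estimate = c(x$prefactor, x$exponent),
    std.error = c(x$prefactor * s[1, 2], s[2, 2])
  )
}

#' @rdname tidy.power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n)
}

#' Tidy a speed estimate
#'
#' @param x A [separation_speed()] object.
#' @param ... Unused.
#' @return Per-replica speeds (`tidy`) or the ensemble summary (`glance`).
#' @export
tidy.speed_estimate <- function(x, ...) x$speeds

#' @rdname tidy.speed_estimate
#' @export
glance.speed_estimate <- function(x, ...) {
  tibble::tibble(mean = x$mean, std.error = x$se,
                 n_included = x$n_included, n_excluded = x$n_excluded)
}

#' Tidy a landscape report
#'
#' @param x A [landscape_report()] object.
#' @param ... Unused.
#' @return The per-separation barrier table (`tidy`) or the headline
#'   summary (`glance`).
#' @export
tidy.landscape_report <- function(x, ...) x$barriers

#' @rdname tidy.landscape_report
#' @export
glance.landscape_report <- function(x, ...) {
  tibble::tibble(
    preset = x$params$preset_label,
    onset = x$onset,
    exponent = x$power_law$exponent,
    r.squared = x$power_law$r_squared,
    min_lifetime_ps = x$min_lifetime,
    barrier_temperature_K = x$barrier_temperature
  )
}
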