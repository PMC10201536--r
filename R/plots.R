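#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a separation scan
#'
#' Bond extensions and opening angle as functions of the imposed strand
#' separation.
#'
#' @param object A [run_separation_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.separation_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[c("d", "B1_extension", "B2_extension", "theta")],
    cols = -"d", names_to = "observable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$d, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ .data$observable, scales = "free_y") +
    ggplot2::labs(x = "strand separation (A)", y = NULL,
                  title = paste(unique(object$form), "separation scan"))
}

#' Plot an energy profile
#'
#' @param object An [energy_profile()] or `neb_path`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.energy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$coord, y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "normalized reaction coordinate", y = "energy (eV)")
}

#' @rdname autoplot.energy_profile
#' @export
autoplot.neb_path <- function(object, ...) {
  autoplot.energy_profile(as_energy_profile(object), ...)
}

#' Plot a barrier table
#'
#' Forward/reverse barriers of both transfer steps against separation.
#'
#' @param object A [barrier_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.barrier_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[c("d", "Ef1", "Er1", "Ef2", "Er2")],
    cols = -"d", names_to = "barrier", values_to = "energy")
  ggplot2::ggplot(stats::na.omit(long),
                  ggplot2::aes(x = .data$d, y = .data$energy,
                               colour = .data$barrier)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "strand separation (A)", y = "barrier (eV)",
                  colour = NULL)
}

#' Plot an opening-angle histogram
#'
#' Occurrence counts per angle bin, coloured by opening scenario; positive
#' angles open from the B2 end.
#'
#' @param object An [angle_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.angle_histogram <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = .data$bin_mid, y = .data$n,
                               fill = .data$scenario)) +
    ggplot2::geom_col(position = "stack", width = diff(object$breaks)[1]) +
    ggplot2::labs(x = "opening angle (degrees)", y = "occurrences",
                  fill = "scenario")
}

#' Plot a speed estimate against its ensemble
#'
#' @param object A [separation_speed()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.speed_estimate <- function(object, ...) {
  ggplot2::ggplot(object$speeds,
                  ggplot2::aes(x = .data$replica, y = .data$speed)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "replica", y = "separation speed (A/ps)")
}
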