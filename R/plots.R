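#' Plot membrane-potential traces
#'
#' One line per recorded node, offset-free overlay of the propagating
#' action potential.
#'
#' @param object An `axon_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.axon_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$v,
                                       colour = factor(.data$node))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)",
                  colour = "node") +
    ggplot2::theme_minimal()
}

#' Plot a conduction-velocity sweep
#'
#' @param object An `axon_sweep` from [sweep_internode_length()] or
#'   [sweep_affected_inrs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.axon_sweep <- function(object, ...) {
  xvar <- attr(object, "sweep_param")
  xlab <- switch(xvar, internode_length = "internode length (um)",
                 n_affected = "dysmyelinated internodes", xvar)
  ggplot2::ggplot(object, ggplot2::aes(.data[[xvar]], .data$velocity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = "conduction velocity (m/s)",
                  title = attr(object, "condition")) +
    ggplot2::theme_minimal()
}

#' Plot firing-rate curves
#'
#' @param object An [fi_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fi_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$amplitude, .data$frequency_hz,
                                       colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "injected current (nA)", y = "firing frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot nodal leak currents across conditions
#'
#' @param object A [nodal_leak_trace()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.leak_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$i_leak,
                                       colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "nodal leak current (nA)") +
    ggplot2::theme_minimal()
}

#' @export
plot.axon_trace <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.axon_sweep <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.fi_curve <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.leak_trace <- function(x, ...) print(autoplot(x, ...))
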