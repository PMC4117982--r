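#' Tidy a conduction-velocity result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-node first-spike table: `node`, `time`, `peak_v`.
#' @export
tidy.cv_result <- function(x, ...) x$spikes

#' One-row summary of a conduction-velocity result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble with `condition`, `velocity`, `blocked`, `valid`,
#'   `delay_ms`, `distance_um`, `amplitude_nA`.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(condition = x$condition, velocity = x$velocity,
                 blocked = x$blocked, valid = x$valid, delay_ms = x$delay_ms,
                 distance_um = x$distance_um, amplitude_nA = x$amplitude_nA)
}

#' Tidy a block-threshold search
#'
#' @param x A `block_threshold`.
#' @param ... Unused.
#' @return The search history: `fraction`, `conducts`, `velocity`.
#' @export
tidy.block_threshold <- function(x, ...) x$history

#' One-row summary of a block-threshold search
#'
#' @param x A `block_threshold`.
#' @param ... Unused.
#' @return A tibble with `threshold`, `threshold_percent` and the bracket.
#' @export
glance.block_threshold <- function(x, ...) {
  tibble::tibble(threshold = x$threshold,
                 threshold_percent = x$threshold_percent,
                 bracket_fails = x$bracket[["fails"]],
                 bracket_conducts = x$bracket[["conducts"]])
}
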