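#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Fit-quality overview: R² against half-life
#'
#' Reproduces the assay's characteristic quality profile — regressions are
#' accurate for half-lives inside the sampling window and degrade for
#' reactions far slower than the last timepoint.
#'
#' @param object A `qit_kinfit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qit_kinfit
#' @export
autoplot.qit_kinfit <- function(object, ...) {
  d <- dplyr::filter(object$fits, !is.na(.data$k_h))
  ggplot2::ggplot(d, ggplot2::aes(.data$half_life_h, .data$r_squared,
                                  colour = .data$quality)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = c(1, 200, 500), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "half-life (h)", y = expression(R^2),
                  title = "Exponential-fit accuracy by half-life") +
    ggplot2::theme_minimal()
}

#' REF distribution with hit thresholds
#'
#' @param object A `qit_ref_calls` table from [call_hits()].
#' @param ... Unused.
#' @return A ggplot histogram of log10 REF with the accelerated/retarded
#'   cutoffs marked.
#' @method autoplot qit_ref_calls
#' @export
autoplot.qit_ref_calls <- function(object, ...) {
  p <- attr(object, "policy")
  ggplot2::ggplot(object, ggplot2::aes(.data$ref, fill = .data$hit_class)) +
    ggplot2::geom_histogram(bins = 40, colour = "white") +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = c(p$lower, p$upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "rate enhancement factor (REF)", y = "fragments",
                  title = sprintf("REF distribution (cutoffs %g / %g)",
                                  p$lower, p$upper)) +
    ggplot2::theme_minimal()
}

#' Time-resolved Z' factors
#'
#' @param object A `qit_zprime` table from [zprime_timecourse()].
#' @param ... Unused.
#' @return A ggplot of Z' versus time with the sufficient/good/excellent
#'   grade lines.
#' @method autoplot qit_zprime
#' @export
autoplot.qit_zprime <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_h, .data$z_prime)) +
    ggplot2::geom_hline(yintercept = c(0.5, 0.6, 0.7), linetype = "dotted",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$grade), size = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (h)", y = "Z'",
                  title = "Assay robustness over the time course") +
    ggplot2::theme_minimal()
}

#' Plot normalized reaction progress for selected pairs
#'
#' @param normalized Output of [normalize_screen()].
#' @param fragments Optional character vector of fragment ids to show.
#' @return A ggplot of fraction remaining versus time, panelled by target.
#' @export
plot_timecourses <- function(normalized, fragments = NULL) {
  d <- normalized
  if (!is.null(fragments))
    d <- dplyr::filter(d, .data$fragment_id %in% fragments)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$fraction_remaining,
                                  colour = .data$fragment_id,
                                  group = interaction(.data$fragment_id,
                                                      .data$replicate))) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$target_id)) +
    ggplot2::labs(x = "time (h)", y = "fraction thiol remaining") +
    ggplot2::theme_minimal()
}
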