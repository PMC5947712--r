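#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-pair fit table of a kinetics fit
#'
#' @param x A `qit_kinfit` from [fit_kinetics()].
#' @param ... Unused.
#' @return Tibble with one row per fragment x target fit.
#' @method tidy qit_kinfit
#' @export
tidy.qit_kinfit <- function(x, ...) x$fits

#' One-row summary of a kinetics fit
#'
#' @param x A `qit_kinfit`.
#' @param ... Unused.
#' @return Tibble with fit counts, quality breakdown and mean R² among
#'   fits in the reliable 1--500 h half-life window.
#' @method glance qit_kinfit
#' @export
glance.qit_kinfit <- function(x, ...) {
  f <- x$fits
  ok <- f$quality %in% c("optimal", "acceptable")
  tibble::tibble(
    n_fits = nrow(f),
    n_optimal = sum(f$quality == "optimal"),
    n_acceptable = sum(f$quality == "acceptable"),
    n_out_of_range = sum(f$quality == "out_of_range"),
    n_failed = sum(f$quality == "failed"),
    mean_r_squared_reliable = if (any(ok)) mean(f$r_squared[ok], na.rm = TRUE)
                              else NA_real_,
    median_half_life_h = stats::median(f$half_life_h, na.rm = TRUE))
}

#' Tidy REF calls
#' @param x A `qit_ref_calls` table from [call_hits()].
#' @param ... Unused.
#' @return The calls as a plain tibble with `ref_2sf` display column added.
#' @method tidy qit_ref_calls
#' @export
tidy.qit_ref_calls <- function(x, ...) {
  tibble::as_tibble(dplyr::mutate(x, ref_2sf = format_ref(.data$ref)))
}

#' Summary of a hit-calling run
#' @param x A `qit_ref_calls` table.
#' @param ... Unused.
#' @return One-row tibble with call counts and the thresholds applied.
#' @method glance qit_ref_calls
#' @export
glance.qit_ref_calls <- function(x, ...) {
  p <- attr(x, "policy")
  tibble::tibble(
    n_pairs = nrow(x),
    n_accelerated = sum(x$hit_class == "accelerated"),
    n_retarded = sum(x$hit_class == "retarded"),
    n_neutral = sum(x$hit_class == "neutral"),
    upper = p$upper, lower = p$lower, mode = p$mode)
}
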