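#' Rate enhancement factor
#'
#' REF = k_protein / k_GSH: the fold acceleration of a fragment's reaction
#' with a protein thiol relative to its intrinsic glutathione reactivity.
#' Values above 1 indicate protein-templated acceleration (specific
#' binding); values below 1, retardation. Full precision is returned;
#' outputs are conventionally displayed at two significant figures (see
#' [format_ref()]).
#'
#' @param k_target Protein rate constant(s), 1/h; > 0.
#' @param k_gsh Glutathione rate constant(s), 1/h; > 0.
#' @return Numeric REF value(s).
#' @examples
#' compute_ref(0.233, 0.089)  # ~2.6
#' compute_ref(0.185, 0.033)  # ~5.6
#' @export
compute_ref <- function(k_target, k_gsh) {
  if (!is.numeric(k_target) || !is.numeric(k_gsh) ||
      anyNA(k_target) || anyNA(k_gsh) ||
      any(k_target <= 0) || any(k_gsh <= 0))
    stop("compute_ref() requires strictly positive rate constants",
         call. = FALSE)
  k_target / k_gsh
}

#' Display a REF value at two significant figures
#' @param ref Numeric REF value(s).
#' @return `signif(ref, 2)`.
#' @export
format_ref <- function(ref) signif(ref, 2)

#' Hit-calling threshold policy
#'
#' Fixed thresholds default to the headline rule: fragments with REF > 3
#' are called rate-accelerated and REF < 0.3 rate-retarded (strict
#' inequalities; a REF exactly at a cutoff is neutral), a symmetric
#' fold-change rule chosen to keep the screen's false-discovery rate under
#' `target_fdr`.
#'
#' @param upper Upper REF cutoff (accelerated above it).
#' @param lower Lower REF cutoff (retarded below it).
#' @param target_fdr Intended false-discovery bound for derived mode.
#' @param mode `"fixed"` or `"derived"`.
#' @return A list of class `qit_policy`.
#' @export
ref_policy <- function(upper = 3, lower = 0.3, target_fdr = 0.025,
                       mode = c("fixed", "derived")) {
  mode <- match.arg(mode)
  if (!is.numeric(lower) || !is.numeric(upper) ||
      !(0 < lower && lower < 1 && 1 < upper))
    stop("threshold policy requires 0 < lower < 1 < upper", call. = FALSE)
  if (target_fdr <= 0 || target_fdr >= 1)
    stop("target_fdr must lie in (0, 1)", call. = FALSE)
  structure(list(upper = upper, lower = lower, target_fdr = target_fdr,
                 mode = mode), class = "qit_policy")
}

#' @export
print.qit_policy <- function(x, ...) {
  cat(sprintf("<qit_policy> %s: accelerated REF > %g, retarded REF < %g (target FDR %g)\n",
              x$mode, x$upper, x$lower, x$target_fdr))
  invisible(x)
}

usable_fits <- function(fits) {
  dplyr::filter(fits, !is.na(.data$k_h), .data$quality != "failed")
}

as_fits_table <- function(x) {
  if (inherits(x, "qit_kinfit")) x$fits else x
}

#' Call accelerated and retarded hits from a reactivity matrix
#'
#' Joins each protein-target fit to the fragment's glutathione fit, forms
#' REF = k_target / k_GSH, and classifies each pair: `accelerated` when
#' REF strictly exceeds `policy$upper`, `retarded` when strictly below
#' `policy$lower`, otherwise `neutral`. Pairs whose protein or GSH fit is
#' missing or `failed` are skipped (a fragment without a usable GSH fit
#' yields no REF values at all). A REF is also only reported when at least
#' one of its two rate constants lies inside the assay's validated
#' half-life window: when both fits are `out_of_range` the ratio is a
#' quotient of two unmeasurable rates and carries no kinetic information,
#' so the pair is skipped.
#'
#' @param fits A `qit_kinfit` object or its fits tibble; targets must
#'   include the glutathione column `"GSH"`.
#' @param policy A [ref_policy()].
#' @return Tibble of class `qit_ref_calls`: `fragment_id`, `target_id`,
#'   `ref` (full precision), `hit_class`.
#' @examples
#' fits <- tibble::tibble(
#'   fragment_id = c("F1", "F1"), target_id = c("GSH", "P1"),
#'   k_h = c(0.089, 0.233), quality = "optimal")
#' call_hits(fits)
#' @export
call_hits <- function(fits, policy = ref_policy()) {
  fits <- as_fits_table(fits)
  stopifnot(inherits(policy, "qit_policy"))
  if (!"GSH" %in% fits$target_id)
    stop("reactivity matrix has no glutathione column (target_id 'GSH')",
         call. = FALSE)
  ok <- usable_fits(fits)
  gsh <- ok |>
    dplyr::filter(.data$target_id == "GSH") |>
    dplyr::select("fragment_id", k_gsh = "k_h", gsh_quality = "quality")
  out <- ok |>
    dplyr::filter(.data$target_id != "GSH") |>
    dplyr::inner_join(gsh, by = "fragment_id") |>
    dplyr::filter(!(.data$quality == "out_of_range" &
                      .data$gsh_quality == "out_of_range")) |>
    dplyr::mutate(ref = compute_ref(.data$k_h, .data$k_gsh),
                  hit_class = dplyr::case_when(
                    .data$ref > policy$upper ~ "accelerated",
                    .data$ref < policy$lower ~ "retarded",
                    TRUE ~ "neutral")) |>
    dplyr::select("fragment_id", "target_id", "ref", "hit_class") |>
    dplyr::arrange(.data$target_id, .data$fragment_id)
  class(out) <- c("qit_ref_calls", class(out))
  attr(out, "policy") <- policy
  out
}

#' Derive REF cutoffs that bound the estimated false-discovery rate
#'
#' Fits a robust Gaussian null to the observed log10 REF distribution
#' (location = median, scale = 1.4826 x MAD) and, taking the conservative
#' null proportion pi0 = 1, returns the smallest symmetric cutoffs
#' `10^(m +/- c s)` whose estimated FDR is at or below `target_fdr` on the
#' accelerated (upper) side; the retarded cutoff is the mirror image in
#' log space. The estimated null exceedance count is the larger of the
#' Gaussian tail prediction `N P(null > cutoff)` and the empirical mirror
#' count `#{REF below the cutoff reflected through the median}`, so the
#' bound stays conservative when fit errors give the null REF distribution
#' heavier-than-Gaussian tails. If the fixed defaults (3, 0.3) already
#' satisfy the bound they are returned unchanged.
#'
#' @param ref_values Numeric vector of at least 30 REF values.
#' @param target_fdr Desired false-discovery bound (default 0.025).
#' @return A [ref_policy()] with `mode = "derived"`.
#' @examples
#' set.seed(1)
#' derive_thresholds(10^rnorm(500, 0, 0.2434))
#' @export
derive_thresholds <- function(ref_values, target_fdr = 0.025) {
  if (!is.numeric(ref_values) || length(ref_values) < 30)
    stop("derive_thresholds() needs at least 30 REF values; ",
         "use the fixed policy for smaller screens", call. = FALSE)
  if (anyNA(ref_values) || any(ref_values <= 0))
    stop("REF values must be positive and non-missing", call. = FALSE)
  x <- log10(ref_values)
  m <- stats::median(x)
  s <- stats::mad(x)  # 1.4826 * median absolute deviation
  n <- length(x)
  eps <- 1e-9

  if (s < eps) {
    # zero-scale null: cutoffs collapse to just beyond the common value
    return(ref_policy(upper = 10^(m + eps), lower = 10^(m - eps),
                      target_fdr = target_fdr, mode = "derived"))
  }
  est_fdr <- function(cut_hi) {
    lcut <- log10(cut_hi)
    gauss <- n * stats::pnorm((lcut - m) / s, lower.tail = FALSE)
    mirror <- sum(x < 2 * m - lcut)
    max(gauss, mirror) / max(1, sum(ref_values > cut_hi))
  }
  # fixed defaults win when they already control the estimated FDR
  if (est_fdr(3) <= target_fdr) {
    return(ref_policy(upper = 3, lower = 0.3, target_fdr = target_fdr,
                      mode = "derived"))
  }
  cs <- seq(0, 12, by = 1e-3)
  ok <- vapply(cs, function(c) est_fdr(10^(m + c * s)) <= target_fdr,
               logical(1))
  if (!any(ok))
    stop("no symmetric cutoff achieves the requested FDR bound", call. = FALSE)
  c_min <- cs[which(ok)[1]]
  c_min <- max(c_min, eps / s)  # keep upper > 1 when m = 0, s tiny
  ref_policy(upper = 10^(m + c_min * s), lower = 10^(m - c_min * s),
             target_fdr = target_fdr, mode = "derived")
}

#' Average reactivity along fragments or targets
#'
#' Geometric mean of the usable rate constants (failed fits and missing
#' cells excluded) per fragment or per target. Rate constants across a
#' library are log-normally spread, so the geometric mean is the natural
#' location summary; `per_fragment` averages over protein targets only,
#' yielding the mean protein reactivity that REF analysis compares with
#' k_GSH.
#'
#' @param fits A `qit_kinfit` or fits tibble.
#' @param axis `"per_fragment"` or `"per_target"`.
#' @return Tibble with the id column, `k_geomean_h`, and `n_cells` (count
#'   of contributing fits).
#' @export
average_reactivity <- function(fits, axis = c("per_fragment", "per_target")) {
  axis <- match.arg(axis)
  fits <- usable_fits(as_fits_table(fits))
  if (nrow(fits) == 0) stop("no usable fits to average", call. = FALSE)
  if (axis == "per_fragment") {
    fits |>
      dplyr::filter(.data$target_id != "GSH") |>
      dplyr::group_by(.data$fragment_id) |>
      dplyr::summarise(k_geomean_h = exp(mean(log(.data$k_h))),
                       n_cells = dplyr::n(), .groups = "drop")
  } else {
    fits |>
      dplyr::group_by(.data$target_id) |>
      dplyr::summarise(k_geomean_h = exp(mean(log(.data$k_h))),
                       n_cells = dplyr::n(), .groups = "drop")
  }
}

#' Correlate glutathione and mean protein reactivity
#'
#' Compares each fragment's k_GSH with its mean reactivity across the
#' protein panel on the log10 scale: Pearson and Spearman correlation plus
#' the least-squares line of log10 mean-protein-k on log10 k_GSH. A strong
#' correlation indicates glutathione works as a control for intrinsic
#' electrophilicity, motivating REF as a binding-specific ranking.
#'
#' @param fits A `qit_kinfit` or fits tibble with a `"GSH"` target column
#'   and at least 3 fragments carrying both sides.
#' @return One-row tibble: `pearson_r`, `spearman_rho`, `slope`,
#'   `intercept`, `n`.
#' @export
correlate_reactivity <- function(fits) {
  fits <- as_fits_table(fits)
  gsh <- usable_fits(fits) |>
    dplyr::filter(.data$target_id == "GSH") |>
    dplyr::select("fragment_id", k_gsh = "k_h")
  prot <- average_reactivity(fits, "per_fragment")
  d <- dplyr::inner_join(gsh, prot, by = "fragment_id")
  if (nrow(d) < 3)
    stop("correlate_reactivity() needs >= 3 fragments with both k_GSH and ",
         "mean protein reactivity", call. = FALSE)
  lx <- log10(d$k_gsh)
  ly <- log10(d$k_geomean_h)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  tibble::tibble(
    pearson_r = stats::cor(lx, ly),
    spearman_rho = stats::cor(lx, ly, method = "spearman"),
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    n = nrow(d))
}
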