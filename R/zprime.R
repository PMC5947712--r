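#' Z' screening-window factor for one pair of control groups
#'
#' Z' = 1 - 3 (sigma_pos + sigma_neg) / |mu_pos - mu_neg|, computed with
#' sample (n - 1) standard deviations. Grades follow the usual HTS
#' convention: > 0.7 excellent, (0.6, 0.7] good, (0.5, 0.6] sufficient,
#' otherwise insufficient.
#'
#' @param pos,neg Fluorescence readings of the positive and negative
#'   control groups (>= 2 values each).
#' @param tol Degenerate-separation tolerance: an error is raised when the
#'   group means differ by less than `tol` times the larger group SD (no
#'   usable screening window).
#' @return One-row tibble: `z_prime`, `mu_pos`, `sigma_pos`, `mu_neg`,
#'   `sigma_neg`, `n_pos`, `n_neg`, `grade`.
#' @examples
#' zprime(rnorm(72, 100, 5), rnorm(72, 10, 5))
#' @export
zprime <- function(pos, neg, tol = 0.5) {
  if (!is.numeric(pos) || !is.numeric(neg) || anyNA(pos) || anyNA(neg))
    stop("control groups must be numeric without missing values", call. = FALSE)
  if (length(pos) < 2 || length(neg) < 2)
    stop("each control group needs at least 2 values", call. = FALSE)
  mu_p <- mean(pos); mu_n <- mean(neg)
  sd_p <- stats::sd(pos); sd_n <- stats::sd(neg)
  delta <- abs(mu_p - mu_n)
  if (delta == 0 || delta < tol * max(sd_p, sd_n))
    stop("degenerate separation: control means are not distinguishable",
         call. = FALSE)
  z <- 1 - 3 * (sd_p + sd_n) / delta
  grade <- if (z > 0.7) "excellent" else if (z > 0.6) "good"
           else if (z > 0.5) "sufficient" else "insufficient"
  tibble::tibble(z_prime = z, mu_pos = mu_p, sigma_pos = sd_p,
                 mu_neg = mu_n, sigma_neg = sd_n,
                 n_pos = length(pos), n_neg = length(neg), grade = grade)
}

#' Time-resolved Z' factors over a control plate
#'
#' A kinetic assay's screening window opens as the reaction proceeds, so Z'
#' is evaluated at every scheduled timepoint from the positive- and
#' negative-control wells. Timepoints where the groups are not separable
#' (e.g. t = 0, before any reaction) are skipped with a message.
#'
#' @param timecourses Long-format readings containing wells with roles
#'   `positive_control` and `negative_control` sharing a time grid.
#' @inheritParams zprime
#' @return Tibble of class `qit_zprime`: one [zprime()] row per retained
#'   timepoint, prefixed with `time_h`; the `verdict` attribute carries the
#'   minimum grade and the min/max Z' across timepoints.
#' @examples
#' qc <- simulate_qc_plate(qit_config(seed = 9, n_qc_wells = 24))
#' zprime_timecourse(qc)
#' @export
zprime_timecourse <- function(timecourses, tol = 0.5) {
  stopifnot(all(c("role", "time_h", "fluorescence_au") %in% names(timecourses)))
  res <- timecourses |>
    dplyr::filter(.data$role %in% c("positive_control", "negative_control")) |>
    dplyr::group_by(.data$time_h) |>
    dplyr::group_map(function(d, key) {
      pos <- d$fluorescence_au[d$role == "positive_control"]
      neg <- d$fluorescence_au[d$role == "negative_control"]
      if (length(pos) < 2 || length(neg) < 2) {
        message(sprintf("t = %g h skipped: missing a control group", key$time_h))
        return(NULL)
      }
      tryCatch(
        dplyr::mutate(zprime(pos, neg, tol), time_h = key$time_h, .before = 1),
        error = function(e) {
          message(sprintf("t = %g h skipped: %s", key$time_h, conditionMessage(e)))
          NULL
        })
    }) |>
    dplyr::bind_rows()
  if (nrow(res) == 0)
    stop("no timepoint yielded a valid Z' factor", call. = FALSE)
  class(res) <- c("qit_zprime", class(res))
  grades <- c("insufficient", "sufficient", "good", "excellent")
  attr(res, "verdict") <- list(
    min_grade = grades[min(match(res$grade, grades))],
    z_min = min(res$z_prime), z_max = max(res$z_prime))
  res
}

#' @export
print.qit_zprime <- function(x, ...) {
  v <- attr(x, "verdict")
  NextMethod()
  cat(sprintf("screen verdict: %s (Z' range %.2f to %.2f)\n",
              v$min_grade, v$z_min, v$z_max))
  invisible(x)
}
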