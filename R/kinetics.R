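#' Half-life of a first-order reaction
#'
#' @param k_h Rate constant(s) in 1/h; must be strictly positive.
#' @return Half-life `ln(2) / k_h` in hours.
#' @examples
#' half_life(log(2))   # 1 h
#' half_life(0.089)    # ~7.79 h
#' @export
half_life <- function(k_h) {
  if (!is.numeric(k_h) || anyNA(k_h) || any(k_h <= 0))
    stop("half_life() requires strictly positive rate constants", call. = FALSE)
  log(2) / k_h
}

#' Classify a kinetic fit by its half-life window
#'
#' The qIT assay models reactions reliably for half-lives between 1 and
#' 500 h, with optimum accuracy between 1 and 200 h. Boundaries are closed
#' on the stated endpoints: optimal is `[1, 200]`, acceptable `(200, 500]`,
#' anything faster than 1 h or slower than 500 h is out of range.
#'
#' @param half_life_h Half-life (or vector of half-lives) in hours; > 0.
#' @return Character vector in `optimal` / `acceptable` / `out_of_range`.
#' @examples
#' classify_fit_quality(c(132, 500, 0.5))
#' @export
classify_fit_quality <- function(half_life_h) {
  if (!is.numeric(half_life_h) || anyNA(half_life_h) || any(half_life_h <= 0))
    stop("classify_fit_quality() requires positive half-lives", call. = FALSE)
  dplyr::case_when(
    half_life_h >= 1 & half_life_h <= 200 ~ "optimal",
    half_life_h > 200 & half_life_h <= 500 ~ "acceptable",
    TRUE ~ "out_of_range"
  )
}

#' Normalize sample fluorescence against a matched DMSO control
#'
#' Converts raw fluorescence into the residual thiol fraction:
#' `(F_sample - background) / (F_control - background)`, where the control
#' trajectory is the per-timepoint mean over DMSO-control replicates for the
#' same target. Because oxidation affects samples and vehicle controls with
#' the same first-order factor, the division cancels it exactly.
#'
#' @param sample Long-format tibble of sample readings (columns
#'   `fragment_id`, `target_id`, `replicate`, `time_h`, `fluorescence_au`).
#' @param control Long-format tibble of DMSO-control readings for the same
#'   target and time grid (`role` must be `dmso_control` if present).
#' @param background_au Instrument background fluorescence to subtract.
#' @param tol Relative tolerance: a control signal within
#'   `tol * max(|background|, 1)` of background is degenerate.
#' @return Tibble with `fragment_id`, `target_id`, `replicate`, `time_h`,
#'   `fraction_remaining`.
#' @examples
#' cfg <- qit_config(seed = 2, n_fragments = 2, n_protein_targets = 1,
#'                   noise_cv = 0)
#' tc <- simulate_timecourses(simulate_truth(cfg), cfg)
#' s <- dplyr::filter(tc, role == "sample", target_id == "GSH")
#' ctl <- dplyr::filter(tc, role == "dmso_control", target_id == "GSH")
#' normalize_to_control(s, ctl, background_au = cfg$background_au)
#' @export
normalize_to_control <- function(sample, control, background_au, tol = 1e-6) {
  req <- c("target_id", "time_h", "fluorescence_au")
  stopifnot(all(req %in% names(sample)), all(req %in% names(control)))
  if ("role" %in% names(control) && !all(control$role == "dmso_control"))
    stop("control wells must all have role 'dmso_control'", call. = FALSE)
  if (!all(unique(sample$target_id) %in% unique(control$target_id)))
    stop("control is missing targets present in the sample table", call. = FALSE)

  ctl <- control |>
    dplyr::group_by(.data$target_id, .data$time_h) |>
    dplyr::summarise(control_au = mean(.data$fluorescence_au), .groups = "drop")
  denom <- ctl$control_au - background_au
  if (any(abs(denom) <= tol * max(abs(background_au), 1)))
    stop("degenerate control: signal within tolerance of background", call. = FALSE)

  out <- dplyr::left_join(sample, ctl, by = c("target_id", "time_h"))
  if (anyNA(out$control_au))
    stop("time-grid mismatch: sample timepoints missing from the DMSO control",
         call. = FALSE)
  out |>
    dplyr::mutate(fraction_remaining =
                    (.data$fluorescence_au - background_au) /
                    (.data$control_au - background_au)) |>
    dplyr::select(dplyr::any_of(c("fragment_id", "target_id", "replicate")),
                  "time_h", "fraction_remaining")
}

#' Normalize a whole screen table
#'
#' Applies [normalize_to_control()] per target across a long-format screen
#' table that contains both `sample` and `dmso_control` wells.
#'
#' @param timecourses Long-format readings as produced by
#'   [simulate_timecourses()] or [read_timecourses()].
#' @inheritParams normalize_to_control
#' @return Normalized tibble (`fragment_id`, `target_id`, `replicate`,
#'   `time_h`, `fraction_remaining`).
#' @export
normalize_screen <- function(timecourses, background_au, tol = 1e-6) {
  stopifnot("role" %in% names(timecourses))
  smp <- dplyr::filter(timecourses, .data$role == "sample")
  ctl <- dplyr::filter(timecourses, .data$role == "dmso_control")
  if (nrow(ctl) == 0) stop("no DMSO-control wells found", call. = FALSE)
  if (nrow(smp) == 0) stop("no sample wells found", call. = FALSE)
  normalize_to_control(smp, ctl, background_au, tol)
}

# One-parameter exponential least squares on the linear scale.
# SSE(k) is minimized over log(k) in [log(lo), log(hi)] by a coarse
# log-spaced grid (plus the log-linear initial guess) followed by Brent
# refinement inside the bracketing interval; deterministic and bounded.
fit_k_core <- function(t, f, k_lower = 1e-5, k_upper = 1e2, n_grid = 240L) {
  sse <- function(lk) {
    r <- f - exp(-exp(lk) * t)
    sum(r * r)
  }
  grid <- seq(log(k_lower), log(k_upper), length.out = n_grid)
  # log-linear regression on positive fractions as an extra candidate
  pos <- f > 0
  if (sum(pos) >= 2 && stats::var(t[pos]) > 0) {
    sl <- stats::cov(t[pos], log(f[pos])) / stats::var(t[pos])
    if (is.finite(sl) && sl < 0)
      grid <- sort(c(grid, min(max(log(-sl), log(k_lower)), log(k_upper))))
  }
  vals <- colSums((f - exp(-t %o% exp(grid)))^2)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) {
    lk <- grid[i]
  } else {
    opt <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
    lk <- if (opt$objective <= vals[i]) opt$minimum else grid[i]
  }
  k <- exp(lk)
  pinned <- k <= k_lower * (1 + 1e-8) || k >= k_upper * (1 - 1e-8)
  list(k = k, sse = sse(lk), pinned = pinned)
}

# standard error from the local curvature of the SSE surface
fit_k_se <- function(t, f, k, sse_val) {
  n <- length(f)
  if (n <= 1 || k <= 0) return(NA_real_)
  h <- 1e-4 * k
  s <- function(kk) { r <- f - exp(-kk * t); sum(r * r) }
  hess <- (s(k + h) - 2 * sse_val + s(k - h)) / h^2
  sigma2 <- sse_val / (n - 1)
  if (!is.finite(hess) || hess <= 0) return(NA_real_)
  sqrt(2 * sigma2 / hess)
}

#' Fit a pseudo-first-order rate constant to one normalized series
#'
#' Least-squares fit of the one-parameter exponential `f(t) = exp(-k t)` on
#' the linear (untransformed) scale, with `k` bounded in
#' `[1e-5, 1e2]` per hour. The amplitude is fixed at 1 because DMSO
#' normalization already maps the no-reaction trajectory to 1. Negative or
#' greater-than-one fractions are retained (not clipped) but counted as
#' outliers when outside `[-0.2, 1.5]`; a series with more than 20% outlier
#' points is flagged `failed`.
#'
#' @param times_h Timepoints in hours (>= 4 readings for a fittable series).
#' @param fraction_remaining Normalized thiol fractions, same length.
#' @param k_lower,k_upper Search bounds for `k` (1/h).
#' @return One-row tibble: `k_h`, `k_se_h`, `r_squared`, `half_life_h`,
#'   `n_points`, `n_outliers`, `quality` (`optimal` / `acceptable` /
#'   `out_of_range` / `failed`).
#' @examples
#' t <- c(0, 2, 6, 18, 30, 54, 78, 126)
fit_series <- function(times_h, fraction_remaining, k_lower, k_upper) {
  t <- as.numeric(times_h)
  f <- as.numeric(fraction_remaining)
  keep <- is.finite(t) & is.finite(f)
  t <- t[keep]; f <- f[keep]
  n <- length(f)
  n_out <- sum(f > 1.5 | f < -0.2)
  failed <- list(k_h = NA_real_, k_se_h = NA_real_, r_squared = NA_real_,
                 half_life_h = NA_real_, n_points = n, n_outliers = n_out,
                 quality = "failed")
  if (n < 4) return(failed)
  ft <- tryCatch(fit_k_core(t, f, k_lower, k_upper), error = function(e) NULL)
  if (is.null(ft)) return(failed)
  sst <- sum((f - mean(f))^2)
  r2 <- if (sst > 0) 1 - ft$sse / sst else if (ft$sse < 1e-20) 1 else NA_real_
  t_half <- log(2) / ft$k
  quality <- if (n_out / n > 0.2) "failed"
             else if (ft$pinned) "out_of_range"
             else classify_fit_quality(t_half)
  list(k_h = ft$k, k_se_h = fit_k_se(t, f, ft$k, ft$sse), r_squared = r2,
       half_life_h = t_half, n_points = n, n_outliers = n_out,
       quality = quality)
}

#' Fit a pseudo-first-order rate constant to one normalized series
#'
#' Least-squares fit of the one-parameter exponential `f(t) = exp(-k t)` on
#' the linear (untransformed) scale, with `k` bounded in
#' `[1e-5, 1e2]` per hour. The amplitude is fixed at 1 because DMSO
#' normalization already maps the no-reaction trajectory to 1. Negative or
#' greater-than-one fractions are retained (not clipped) but counted as
#' outliers when outside `[-0.2, 1.5]`; a series with more than 20% outlier
#' points is flagged `failed`.
#'
#' @param times_h Timepoints in hours (>= 4 readings for a fittable series).
#' @param fraction_remaining Normalized thiol fractions, same length.
#' @param k_lower,k_upper Search bounds for `k` (1/h).
#' @return One-row tibble: `k_h`, `k_se_h`, `r_squared`, `half_life_h`,
#'   `n_points`, `n_outliers`, `quality` (`optimal` / `acceptable` /
#'   `out_of_range` / `failed`).
#' @examples
#' t <- c(0, 2, 6, 18, 30, 54, 78, 126)
#' fit_first_order(t, exp(-0.1 * t))
#' @export
fit_first_order <- function(times_h, fraction_remaining,
                            k_lower = 1e-5, k_upper = 1e2) {
  tibble::as_tibble(fit_series(times_h, fraction_remaining,
                               k_lower, k_upper))
}

#' Fit rate constants for every fragment x target pair in a screen
#'
#' Pools replicate wells of the same pair into a single regression (rather
#' than averaging per-replicate fits) and applies [fit_first_order()] to
#' each pair.
#'
#' @param normalized Normalized table from [normalize_screen()].
#' @inheritParams fit_first_order
#' @return Object of class `qit_kinfit`; its `$fits` tibble has one row per
#'   pair with columns `fragment_id`, `target_id`, `k_h`, `k_se_h`,
#'   `r_squared`, `half_life_h`, `n_points`, `n_outliers`, `quality`. Use
#'   [tidy()][generics::tidy] / [glance()][generics::glance] /
#'   [autoplot()][ggplot2::autoplot] on it.
#' @examples
#' cfg <- qit_config(seed = 4, n_fragments = 3, n_protein_targets = 1)
#' sim <- simulate_screen(cfg)
#' fits <- normalize_screen(sim$timecourses, cfg$background_au) |>
#'   fit_kinetics()
#' tidy(fits)
#' @export
fit_kinetics <- function(normalized, k_lower = 1e-5, k_upper = 1e2) {
  req <- c("fragment_id", "target_id", "time_h", "fraction_remaining")
  stopifnot(all(req %in% names(normalized)))
  normalized <- dplyr::arrange(normalized, .data$target_id, .data$fragment_id,
                               .data$time_h)
  key <- paste(normalized$target_id, normalized$fragment_id, sep = "\r")
  pieces <- split(seq_len(nrow(normalized)), factor(key, levels = unique(key)))
  rows <- purrr::map(pieces, function(idx) {
    fit_series(normalized$time_h[idx], normalized$fraction_remaining[idx],
               k_lower, k_upper)
  })
  first <- vapply(pieces, `[`, integer(1), 1L)
  fits <- tibble::tibble(
    fragment_id = normalized$fragment_id[first],
    target_id = normalized$target_id[first],
    k_h = vapply(rows, `[[`, numeric(1), "k_h"),
    k_se_h = vapply(rows, `[[`, numeric(1), "k_se_h"),
    r_squared = vapply(rows, `[[`, numeric(1), "r_squared"),
    half_life_h = vapply(rows, `[[`, numeric(1), "half_life_h"),
    n_points = vapply(rows, `[[`, integer(1), "n_points"),
    n_outliers = vapply(rows, `[[`, integer(1), "n_outliers"),
    quality = vapply(rows, `[[`, character(1), "quality"))
  structure(list(fits = fits, k_bounds = c(k_lower, k_upper)),
            class = "qit_kinfit")
}

#' @export
print.qit_kinfit <- function(x, ...) {
  cat(sprintf("<qit_kinfit> %d fragment x target fits\n", nrow(x$fits)))
  print(dplyr::count(x$fits, .data$quality))
  invisible(x)
}
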