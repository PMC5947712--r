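make_tc <- function(target, role, fluor, times = c(0, 2, 4, 8),
                    fragment = "FX", replicate = 1) {
  tibble::tibble(fragment_id = if (role == "dmso_control") "" else fragment,
                 target_id = target, role = role, replicate = replicate,
                 time_h = times, fluorescence_au = fluor)
}

test_that("normalization maps control-identical samples to fraction 1", {
  ctl <- make_tc("GSH", "dmso_control", c(1100, 1050, 1000, 900))
  smp <- make_tc("GSH", "sample", c(1100, 1050, 1000, 900))
  norm <- normalize_to_control(smp, ctl, background_au = 100)
  expect_equal(norm$fraction_remaining, rep(1, 4))
})

test_that("normalization subtracts background before dividing", {
  ctl <- make_tc("GSH", "dmso_control", rep(1100, 4))
  smp <- make_tc("GSH", "sample", c(1100, 600, 350, 225))
  norm <- normalize_to_control(smp, ctl, background_au = 100)
  expect_equal(norm$fraction_remaining, c(1, 0.5, 0.25, 0.125))
})

test_that("control replicates are averaged per timepoint before division", {
  ctl <- dplyr::bind_rows(
    make_tc("GSH", "dmso_control", rep(1000, 4), replicate = 1),
    make_tc("GSH", "dmso_control", rep(1200, 4), replicate = 2))
  smp <- make_tc("GSH", "sample", rep(600, 4))
  norm <- normalize_to_control(smp, ctl, background_au = 100)
  expect_equal(norm$fraction_remaining, rep(500 / 1000, 4))
})

test_that("DMSO normalization cancels the oxidation channel exactly", {
  cfg <- qit_config(seed = 5, n_fragments = 3, n_protein_targets = 1,
                    noise_cv = 0, oxidation_rate_h = 0.1)
  tc <- simulate_timecourses(simulate_truth(cfg), cfg)
  # a non-reacting sample: duplicate the control trajectory as a sample well
  ctl <- dplyr::filter(tc, role == "dmso_control", target_id == "GSH")
  fake <- dplyr::mutate(ctl, role = "sample", fragment_id = "NOREACT")
  norm <- normalize_to_control(fake, ctl, cfg$background_au)
  expect_equal(norm$fraction_remaining, rep(1, nrow(norm)), tolerance = 1e-12)
  # and a reacting one still fits to its own k after the shared channel cancels
  smp <- dplyr::filter(tc, role == "sample", fragment_id == "F0001",
                       target_id == "GSH")
  norm2 <- normalize_to_control(smp, ctl, cfg$background_au)
  truth <- dplyr::filter(simulate_truth(cfg), fragment_id == "F0001",
                         target_id == "GSH")
  fit <- fit_first_order(norm2$time_h[norm2$replicate == 1],
                         norm2$fraction_remaining[norm2$replicate == 1])
  expect_lt(abs(fit$k_h - truth$true_k_h) / truth$true_k_h, 1e-6)
})

test_that("degenerate controls and mismatched grids are rejected", {
  ctl <- make_tc("GSH", "dmso_control", rep(100, 4))
  smp <- make_tc("GSH", "sample", rep(600, 4))
  expect_error(normalize_to_control(smp, ctl, background_au = 100),
               "degenerate control")
  ctl2 <- make_tc("GSH", "dmso_control", rep(1100, 4),
                  times = c(0, 3, 6, 9))
  expect_error(normalize_to_control(smp, ctl2, background_au = 100),
               "mismatch")
})

test_that("noiseless exponential series are recovered exactly", {
  for (k in c(0.005, 0.05, 0.7)) {
    fit <- fit_first_order(default_times, exp(-k * default_times))
    expect_lt(abs(fit$k_h - k) / k, 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_equal(fit$half_life_h * fit$k_h, log(2), tolerance = 1e-12)
  }
})

test_that("a flat series pins k at the lower bound and is out of range", {
  fit <- fit_first_order(default_times, rep(1, 8))
  expect_equal(fit$k_h, 1e-5, tolerance = 1e-6)
  expect_equal(fit$quality, "out_of_range")
})

test_that("short and outlier-ridden series are flagged failed", {
  expect_equal(fit_first_order(c(0, 2, 6), exp(-0.1 * c(0, 2, 6)))$quality,
               "failed")
  f <- exp(-0.05 * default_times)
  f[1:3] <- 5 # 3/8 readings far outside the plausible fraction band
  expect_equal(fit_first_order(default_times, f)$quality, "failed")
})

test_that("median fit error stays below 5% at 5% noise in the optimal window", {
  set.seed(301)
  ks <- log(2) / 10^stats::runif(200, 0, log10(200)) # t1/2 in [1, 200] h
  rel <- vapply(ks, function(k) {
    f <- c(noisy_series(k, 0.05), noisy_series(k, 0.05))
    fit <- fit_first_order(rep(default_times, 2), f)
    abs(fit$k_h - k) / k
  }, numeric(1))
  expect_lt(stats::median(rel), 0.05)
})

test_that("the fit matches a brute-force grid-search oracle", {
  set.seed(77)
  for (i in 1:10) {
    k <- log(2) / 10^stats::runif(1, 0, log10(300))
    f <- noisy_series(k, 0.05)
    fit <- fit_first_order(default_times, f)
    oracle <- oracle_grid_fit(default_times, f, n_grid = 1e5)
    expect_lte(abs(log(fit$k_h) - log(oracle$k)), oracle$log_step * 1.01)
  }
})

test_that("half_life inverts rate constants and rejects the nonpositive", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.089), log(2) / 0.089) # ~7.79 h
  expect_error(half_life(0), "positive")
  expect_error(half_life(-1), "positive")
})

test_that("fit quality windows are closed on their stated endpoints", {
  expect_equal(classify_fit_quality(c(1, 132, 200)), rep("optimal", 3))
  expect_equal(classify_fit_quality(c(200.1, 500)), rep("acceptable", 2))
  expect_equal(classify_fit_quality(c(0.5, 501)), rep("out_of_range", 2))
  expect_error(classify_fit_quality(0), "positive")
})

test_that("pooled-replicate fits equal single-series fits on identical data", {
  f <- exp(-0.08 * default_times)
  single <- fit_first_order(default_times, f)
  pooled <- fit_first_order(rep(default_times, 2), rep(f, 2))
  expect_equal(pooled$k_h, single$k_h, tolerance = 1e-9)
  expect_equal(pooled$r_squared, single$r_squared, tolerance = 1e-9)
})

test_that("fits are invariant to affine rescaling of raw fluorescence", {
  set.seed(11)
  f_true <- noisy_series(0.06, 0.03)
  raw <- tibble::tibble(fragment_id = "F1", target_id = "GSH", role = "sample",
                        replicate = 1, time_h = default_times,
                        fluorescence_au = 100 + 900 * f_true)
  ctl <- dplyr::mutate(raw, role = "dmso_control", fragment_id = "",
                       fluorescence_au = 1000)
  norm1 <- normalize_to_control(raw, ctl, 100)
  a <- 3.7; b <- 250
  raw2 <- dplyr::mutate(raw, fluorescence_au = a * fluorescence_au + b)
  ctl2 <- dplyr::mutate(ctl, fluorescence_au = a * fluorescence_au + b)
  norm2 <- normalize_to_control(raw2, ctl2, a * 100 + b)
  expect_equal(norm2$fraction_remaining, norm1$fraction_remaining,
               tolerance = 1e-12)
  expect_equal(fit_first_order(default_times, norm2$fraction_remaining)$k_h,
               fit_first_order(default_times, norm1$fraction_remaining)$k_h,
               tolerance = 1e-12)
})

test_that("fit_kinetics pools replicates and recovers simulator truth", {
  cfg <- qit_config(seed = 6, n_fragments = 8, n_protein_targets = 2,
                    noise_cv = 0)
  truth <- simulate_truth(cfg)
  fits <- simulate_timecourses(truth, cfg) |>
    normalize_screen(cfg$background_au) |>
    fit_kinetics()
  m <- dplyr::inner_join(tidy(fits), truth,
                         by = c("fragment_id", "target_id"))
  expect_equal(nrow(m), 8 * 3)
  expect_true(all(abs(m$k_h - m$true_k_h) / m$true_k_h < 1e-6))
  expect_true(all(m$n_points == 2 * length(default_times)))
  g <- glance(fits)
  expect_equal(g$n_fits, 24)
  expect_equal(g$n_failed, 0)
})
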