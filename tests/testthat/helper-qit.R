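default_times <- c(0, 2, 6, 18, 30, 54, 78, 126)

# noisy normalized decay series with the package's multiplicative noise model
noisy_series <- function(k, cv, times = default_times) {
  exp(-k * times) * (1 + stats::rnorm(length(times), 0, cv))
}

# brute-force SSE oracle: best k over an n_grid-point log-spaced grid,
# independent of the package's fitting path
oracle_grid_fit <- function(t, f, k_lower = 1e-5, k_upper = 1e2,
                            n_grid = 1e6) {
  grid <- exp(seq(log(k_lower), log(k_upper), length.out = n_grid))
  best_k <- NA_real_
  best_sse <- Inf
  chunk <- 2e5
  for (i in seq(1, n_grid, by = chunk)) {
    ks <- grid[i:min(i + chunk - 1, n_grid)]
    sse <- colSums((f - exp(-t %o% ks))^2)
    j <- which.min(sse)
    if (sse[j] < best_sse) {
      best_sse <- sse[j]
      best_k <- ks[j]
    }
  }
  list(k = best_k, sse = best_sse,
       log_step = (log(k_upper) - log(k_lower)) / (n_grid - 1))
}

# one synthetic screen for false-discovery experiments: n_null neutral
# fragments plus n_hit planted binders at a single true REF, one protein
# target, duplicate wells
fdr_screen_config <- function(seed, n_null = 200, n_hit = 20, true_ref = 5,
                              noise_cv = 0.05) {
  n <- n_null + n_hit
  qit_config(seed = seed, n_fragments = n, n_protein_targets = 1,
             hit_fraction = n_hit / n, hit_ref_range = c(true_ref,
                                                         true_ref + 1e-9),
             retarded_fraction = 0, noise_cv = noise_cv)
}

run_fdr_screen <- function(seed, ...) {
  cfg <- fdr_screen_config(seed, ...)
  truth <- simulate_truth(cfg)
  tc <- simulate_timecourses(truth, cfg)
  fits <- fit_kinetics(normalize_screen(tc, cfg$background_au))
  calls <- call_hits(fits)
  m <- dplyr::inner_join(calls,
                         dplyr::filter(truth, target_id != "GSH"),
                         by = c("fragment_id", "target_id"))
  called <- m$hit_class == "accelerated"
  is_hit <- m$label == "accelerated"
  list(fdr = if (sum(called) > 0) sum(called & !is_hit) / sum(called) else 0,
       power = sum(called & is_hit) / sum(is_hit),
       calls = calls, truth = truth, fits = fits)
}
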