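#' Simulation configuration for a synthetic qIT screen
#'
#' Builds and validates the parameter set that defines a simulated
#' quantitative irreversible tethering (qIT) screen: library size, target
#' panel, sampling schedule, the log-normal spread of intrinsic glutathione
#' reactivity, planted binder structure, and the fluorescence noise model.
#'
#' Defaults describe a screen of 138 electrophilic fragments read at eight
#' timepoints over 126 h in duplicate, with glutathione rate constants drawn
#' so the library's median half-life is 132 h and roughly 90% of half-lives
#' fall in the 1--500 h window the assay models reliably.
#'
#' @param seed Integer seed controlling all randomness downstream.
#' @param n_fragments Number of electrophilic fragments in the library.
#' @param n_protein_targets Number of protein thiol targets (glutathione is
#'   always present in addition, as target `"GSH"`).
#' @param timepoints_h Sampling times in hours; nonnegative, strictly
#'   increasing, may start at 0.
#' @param n_replicates Wells per fragment x target condition.
#' @param log10_kgsh_mean,log10_kgsh_sd Mean and SD of log10 k_GSH (k in
#'   1/h); fragments draw i.i.d. from this log-normal reactivity spread.
#' @param hit_fraction,retarded_fraction Fractions of fragments planted, per
#'   protein target, as rate-accelerated binders (true REF > 1) or
#'   rate-retarded fragments (true REF < 1). Must sum to at most 1.
#' @param hit_ref_range,retarded_ref_range Length-2 numeric ranges the true
#'   REF of planted pairs is drawn from (uniform). Hit range must lie above
#'   1, retarded range inside (0, 1).
#' @param noise_cv Fractional coefficient of variation of the multiplicative
#'   Gaussian fluorescence noise applied to the signal span of each reading.
#' @param background_au,span_au Fluorescence background and dynamic span in
#'   arbitrary units; span must be positive.
#' @param oxidation_rate_h First-order aerobic thiol-oxidation rate (1/h)
#'   affecting every well, samples and DMSO controls alike; 0 models
#'   TCEP-agarose protection.
#' @param n_qc_wells Wells per control group on the QC plate.
#' @param qc_k_pos First-order signal-decay rate (1/h) of positive-control
#'   QC wells; negative-control wells do not react.
#'
#' @return A validated list of class `qit_config`.
#' @examples
#' cfg <- qit_config(seed = 1, n_fragments = 20, n_protein_targets = 1)
#' cfg$timepoints_h
#' @export
qit_config <- function(seed = 1L,
                       n_fragments = 138L,
                       n_protein_targets = 7L,
                       timepoints_h = c(0, 2, 6, 18, 30, 54, 78, 126),
                       n_replicates = 2L,
                       log10_kgsh_mean = log10(log(2) / 132),
                       log10_kgsh_sd = 0.5,
                       hit_fraction = 0.05,
                       hit_ref_range = c(3, 10),
                       retarded_fraction = 0.05,
                       retarded_ref_range = c(0.03, 0.3),
                       noise_cv = 0.05,
                       background_au = 50,
                       span_au = 1000,
                       oxidation_rate_h = 0,
                       n_qc_wells = 72L,
                       qc_k_pos = 0.7) {
  cfg <- list(
    seed = seed, n_fragments = n_fragments,
    n_protein_targets = n_protein_targets, timepoints_h = timepoints_h,
    n_replicates = n_replicates, log10_kgsh_mean = log10_kgsh_mean,
    log10_kgsh_sd = log10_kgsh_sd, hit_fraction = hit_fraction,
    hit_ref_range = hit_ref_range, retarded_fraction = retarded_fraction,
    retarded_ref_range = retarded_ref_range, noise_cv = noise_cv,
    background_au = background_au, span_au = span_au,
    oxidation_rate_h = oxidation_rate_h, n_qc_wells = n_qc_wells,
    qc_k_pos = qc_k_pos
  )
  validate_qit_config(cfg)
  structure(cfg, class = "qit_config")
}

# one scalar check -> config error naming the offending field
cfg_stop <- function(field, why) {
  stop(sprintf("invalid simulation config: field '%s' %s", field, why),
       call. = FALSE)
}

validate_qit_config <- function(cfg) {
  num1 <- function(field, x) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      cfg_stop(field, "must be a single finite number")
    x
  }
  s <- num1("seed", cfg$seed)
  if (s != round(s) || abs(s) >= 2^30) cfg_stop("seed", "must be an integer below 2^30 in magnitude")
  if (num1("n_fragments", cfg$n_fragments) < 1) cfg_stop("n_fragments", "must be >= 1")
  if (num1("n_protein_targets", cfg$n_protein_targets) < 1)
    cfg_stop("n_protein_targets", "must be >= 1")
  tp <- cfg$timepoints_h
  if (!is.numeric(tp) || length(tp) < 2L || anyNA(tp))
    cfg_stop("timepoints_h", "must be a numeric vector of >= 2 times")
  if (any(tp < 0)) cfg_stop("timepoints_h", "must be nonnegative")
  if (any(diff(tp) <= 0)) cfg_stop("timepoints_h", "must be strictly increasing")
  if (num1("n_replicates", cfg$n_replicates) < 1) cfg_stop("n_replicates", "must be >= 1")
  num1("log10_kgsh_mean", cfg$log10_kgsh_mean)
  if (num1("log10_kgsh_sd", cfg$log10_kgsh_sd) < 0) cfg_stop("log10_kgsh_sd", "must be >= 0")
  hf <- num1("hit_fraction", cfg$hit_fraction)
  rf <- num1("retarded_fraction", cfg$retarded_fraction)
  if (hf < 0 || hf > 1) cfg_stop("hit_fraction", "must lie in [0, 1]")
  if (rf < 0 || rf > 1) cfg_stop("retarded_fraction", "must lie in [0, 1]")
  if (hf + rf > 1) cfg_stop("hit_fraction", "plus retarded_fraction must be <= 1")
  rng2 <- function(field, r) {
    if (!is.numeric(r) || length(r) != 2L || anyNA(r) || r[1] > r[2])
      cfg_stop(field, "must be an increasing numeric range of length 2")
    r
  }
  if (any(rng2("hit_ref_range", cfg$hit_ref_range) <= 1))
    cfg_stop("hit_ref_range", "must lie strictly above 1 (rate-accelerated binders)")
  rr <- rng2("retarded_ref_range", cfg$retarded_ref_range)
  if (any(rr <= 0) || any(rr >= 1))
    cfg_stop("retarded_ref_range", "must lie strictly inside (0, 1)")
  if (num1("noise_cv", cfg$noise_cv) < 0) cfg_stop("noise_cv", "must be >= 0")
  num1("background_au", cfg$background_au)
  if (num1("span_au", cfg$span_au) <= 0) cfg_stop("span_au", "must be > 0")
  if (num1("oxidation_rate_h", cfg$oxidation_rate_h) < 0)
    cfg_stop("oxidation_rate_h", "must be >= 0")
  if (num1("n_qc_wells", cfg$n_qc_wells) < 2) cfg_stop("n_qc_wells", "must be >= 2")
  if (num1("qc_k_pos", cfg$qc_k_pos) <= 0) cfg_stop("qc_k_pos", "must be > 0")
  invisible(cfg)
}

#' @export
print.qit_config <- function(x, ...) {
  cat("<qit_config>\n")
  cat(sprintf("  %d fragments x %d protein targets (+ GSH), %d replicate(s)\n",
              x$n_fragments, x$n_protein_targets, x$n_replicates))
  cat(sprintf("  %d timepoints over %g h; noise CV %.3g; seed %d\n",
              length(x$timepoints_h), max(x$timepoints_h), x$noise_cv,
              as.integer(x$seed)))
  cat(sprintf("  log10 k_GSH ~ N(%.4g, %.3g); hits %.1f%% REF [%g, %g]; retarded %.1f%% REF [%g, %g]\n",
              x$log10_kgsh_mean, x$log10_kgsh_sd, 100 * x$hit_fraction,
              x$hit_ref_range[1], x$hit_ref_range[2], 100 * x$retarded_fraction,
              x$retarded_ref_range[1], x$retarded_ref_range[2]))
  invisible(x)
}
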