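#' Draw the ground-truth kinetics of a synthetic qIT screen
#'
#' Samples each fragment's intrinsic glutathione rate constant from the
#' library's log-normal reactivity spread and plants, per protein target, a
#' set of rate-accelerated (true REF > 1) and rate-retarded (true REF < 1)
#' fragment--target pairs; all remaining pairs are neutral with true REF
#' exactly 1. The implied protein rate constant is `true_ref * k_GSH`.
#'
#' @param config A [qit_config()].
#' @return A tibble of class `qit_truth` with one row per fragment x target
#'   (targets are `"GSH"` plus `P1 ... Pn`): `fragment_id`, `target_id`,
#'   `true_k_h` (1/h), `true_ref` (NA for the GSH column -- REF is defined
#'   against it) and `label` in `accelerated` / `neutral` / `retarded`.
#' @examples
#' truth <- simulate_truth(qit_config(seed = 7, n_fragments = 10,
#'                                    n_protein_targets = 2))
#' dplyr::count(truth, label)
#' @export
simulate_truth <- function(config) {
  validate_qit_config(config)
  set.seed(as.integer(config$seed))
  n <- as.integer(config$n_fragments)
  frag_ids <- sprintf("F%04d", seq_len(n))
  k_gsh <- 10^stats::rnorm(n, config$log10_kgsh_mean, config$log10_kgsh_sd)
  names(k_gsh) <- frag_ids

  n_hit <- round(config$hit_fraction * n)
  n_ret <- round(config$retarded_fraction * n)
  targets <- sprintf("P%d", seq_len(config$n_protein_targets))

  per_target <- lapply(targets, function(tg) {
    ref <- rep(1, n)
    label <- rep("neutral", n)
    planted <- sample.int(n, n_hit + n_ret, replace = FALSE)
    if (n_hit > 0) {
      hit_idx <- planted[seq_len(n_hit)]
      ref[hit_idx] <- stats::runif(n_hit, config$hit_ref_range[1],
                                   config$hit_ref_range[2])
      label[hit_idx] <- "accelerated"
    }
    if (n_ret > 0) {
      ret_idx <- planted[n_hit + seq_len(n_ret)]
      ref[ret_idx] <- stats::runif(n_ret, config$retarded_ref_range[1],
                                   config$retarded_ref_range[2])
      label[ret_idx] <- "retarded"
    }
    tibble::tibble(fragment_id = frag_ids, target_id = tg,
                   true_k_h = unname(k_gsh) * ref, true_ref = ref,
                   label = label)
  })

  gsh <- tibble::tibble(fragment_id = frag_ids, target_id = "GSH",
                        true_k_h = unname(k_gsh), true_ref = NA_real_,
                        label = "neutral")
  out <- dplyr::bind_rows(gsh, per_target) |>
    dplyr::arrange(.data$target_id != "GSH", .data$target_id, .data$fragment_id)
  class(out) <- c("qit_truth", class(out))
  out
}

# decaying fluorescence reading: F = bg + span * exp(-(k + k_ox) t) * (1 + eps)
sim_fluor <- function(times, k, config) {
  f <- exp(-(k + config$oxidation_rate_h) * times)
  eps <- if (config$noise_cv > 0) {
    stats::rnorm(length(times), 0, config$noise_cv)
  } else 0
  config$background_au + config$span_au * f * (1 + eps)
}

# expand a well table (one row per well, column `k`) into the long reading
# table; noise is drawn in well-major order so results match a per-well loop
sim_readings <- function(wells, times, config) {
  nw <- nrow(wells)
  ntp <- length(times)
  k_vec <- rep(wells$k, each = ntp)
  t_vec <- rep(times, times = nw)
  out <- wells[rep(seq_len(nw), each = ntp),
               setdiff(names(wells), "k"), drop = FALSE]
  out$time_h <- t_vec
  out$fluorescence_au <- sim_fluor(t_vec, k_vec, config)
  dplyr::select(out, "plate", "well", "fragment_id", "target_id", "role",
                "replicate", "time_h", "fluorescence_au")
}

#' Simulate raw fluorescence time courses for a screen
#'
#' Generates the long-format plate-reader table for every fragment x target
#' well (with replicates) plus per-target DMSO-control wells. The residual
#' thiol fraction decays as `exp(-(k_pair + k_ox) t)`; fluorescence is
#' `background + span * fraction * (1 + eps)` with i.i.d. multiplicative
#' Gaussian noise `eps ~ N(0, noise_cv)` per reading. DMSO controls carry
#' `k_pair = 0` but are still subject to the oxidation channel, which is why
#' downstream DMSO normalization cancels oxidation exactly.
#'
#' @param truth A `qit_truth` table from [simulate_truth()], generated with
#'   the same config.
#' @param config The [qit_config()] used for `truth`.
#' @return A tibble with columns `plate`, `well`, `fragment_id` (empty
#'   string for DMSO controls), `target_id`, `role`, `replicate`, `time_h`,
#'   `fluorescence_au`; one row per reading.
#' @examples
#' cfg <- qit_config(seed = 3, n_fragments = 4, n_protein_targets = 1)
#' tc <- simulate_timecourses(simulate_truth(cfg), cfg)
#' head(tc)
#' @export
simulate_timecourses <- function(truth, config) {
  validate_qit_config(config)
  stopifnot(is.data.frame(truth),
            all(c("fragment_id", "target_id", "true_k_h") %in% names(truth)))
  set.seed(as.integer(config$seed) + 1L)
  times <- config$timepoints_h
  n_rep <- as.integer(config$n_replicates)

  wells <- truth |>
    dplyr::select("fragment_id", "target_id", "true_k_h") |>
    tidyr::crossing(replicate = seq_len(n_rep)) |>
    dplyr::mutate(role = "sample")
  dmso <- tidyr::crossing(
    target_id = unique(truth$target_id), replicate = seq_len(n_rep)
  ) |>
    dplyr::mutate(fragment_id = "", true_k_h = 0, role = "dmso_control")
  wells <- dplyr::bind_rows(wells, dmso) |>
    dplyr::arrange(.data$target_id != "GSH", .data$target_id,
                   .data$role != "dmso_control", .data$fragment_id,
                   .data$replicate) |>
    dplyr::mutate(plate = "SIM1", well = sprintf("W%05d", dplyr::row_number()))

  sim_readings(dplyr::rename(wells, k = "true_k_h"), times, config)
}

#' Simulate a Z'-factor control plate
#'
#' Generates matched positive- and negative-control wells for assay QC.
#' Positive wells contain a reacting thiol whose signal decays first-order
#' at rate `qc_k_pos`; negative wells contain no reactive thiol, so their
#' signal stays at `background + span` (up to noise). The two groups
#' coincide at t = 0 and separate as the reaction proceeds, mirroring a
#' kinetic assay whose screening window opens with time.
#'
#' @inheritParams simulate_timecourses
#' @return Long-format tibble in the same schema as
#'   [simulate_timecourses()], with roles `positive_control` and
#'   `negative_control` and `n_qc_wells` wells per group.
#' @examples
#' qc <- simulate_qc_plate(qit_config(seed = 5, n_qc_wells = 8))
#' dplyr::count(qc, role)
#' @export
simulate_qc_plate <- function(config) {
  validate_qit_config(config)
  set.seed(as.integer(config$seed) + 2L)
  times <- config$timepoints_h
  n <- as.integer(config$n_qc_wells)
  wells <- tibble::tibble(
    role = rep(c("positive_control", "negative_control"), each = n),
    replicate = rep(seq_len(n), 2L),
    k = rep(c(config$qc_k_pos, 0), each = n)
  ) |>
    dplyr::mutate(plate = "QC1", well = sprintf("Q%04d", dplyr::row_number()),
                  fragment_id = "", target_id = "QC")
  sim_readings(wells, times, config)
}

#' Simulate a complete synthetic screen
#'
#' Convenience wrapper bundling [simulate_truth()], [simulate_timecourses()]
#' and [simulate_qc_plate()] for one seeded screen.
#'
#' @param config A [qit_config()].
#' @return A list of class `qit_screen_sim` with elements `truth`,
#'   `timecourses`, `qc_plate` and `config`.
#' @export
simulate_screen <- function(config) {
  truth <- simulate_truth(config)
  list(truth = truth,
       timecourses = simulate_timecourses(truth, config),
       qc_plate = simulate_qc_plate(config),
       config = config) |>
    structure(class = "qit_screen_sim")
}

#' @export
print.qit_screen_sim <- function(x, ...) {
  cat("<qit_screen_sim>\n")
  print(x$config)
  cat(sprintf("  %d time-course readings, %d QC readings\n",
              nrow(x$timecourses), nrow(x$qc_plate)))
  invisible(x)
}
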