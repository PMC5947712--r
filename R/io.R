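tc_columns <- c("plate", "well", "fragment_id", "target_id", "role",
                "replicate", "time_h", "fluorescence_au")
tc_roles <- c("sample", "dmso_control", "positive_control", "negative_control")

qit_log <- function(fmt, ..., level = "INFO") {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Read a long-format plate-reader time-course table
#'
#' Expects a delimited text file with one row per well per timepoint and
#' the columns `plate, well, fragment_id, target_id, role, replicate,
#' time_h, fluorescence_au` (time in hours only). Each well's rows must
#' appear in strictly increasing time order; duplicate (well, time) pairs
#' are rejected. Missing fluorescence values are dropped per reading with
#' a warning.
#'
#' @param path Path to the file.
#' @param delim Field delimiter (default comma).
#' @return Tibble ordered by (target, fragment, replicate, time).
#' @export
read_timecourses <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(tc_columns, names(raw))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_role <- setdiff(unique(raw$role), tc_roles)
  if (length(bad_role) > 0)
    stop("schema error: unknown role(s) ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  raw$fragment_id <- dplyr::coalesce(as.character(raw$fragment_id), "")
  raw$replicate <- as.integer(raw$replicate)
  if (anyNA(raw$fluorescence_au)) {
    warning(sum(is.na(raw$fluorescence_au)),
            " missing fluorescence reading(s) dropped", call. = FALSE)
    raw <- dplyr::filter(raw, !is.na(.data$fluorescence_au))
  }
  raw$.row <- seq_len(nrow(raw))
  dup <- raw$.row[duplicated(raw[c("plate", "well", "time_h")])]
  if (length(dup) > 0)
    stop(sprintf("data error: duplicate (well, time) readings at row(s) %s",
                 paste(utils::head(dup, 10), collapse = ", ")),
         call. = FALSE)
  bad <- raw |>
    dplyr::group_by(.data$plate, .data$well) |>
    dplyr::filter(c(FALSE, diff(.data$time_h) <= 0)) |>
    dplyr::ungroup()
  if (nrow(bad) > 0)
    stop(sprintf("data error: non-monotone times within a well series at row(s) %s",
                 paste(utils::head(bad$.row, 10), collapse = ", ")),
         call. = FALSE)
  raw |>
    dplyr::select(dplyr::all_of(tc_columns)) |>
    dplyr::arrange(.data$target_id, .data$fragment_id, .data$replicate,
                   .data$time_h)
}

#' Write a time-course table (round-trippable with [read_timecourses()])
#' @param timecourses Long-format tibble with the standard columns.
#' @param path Destination file.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(timecourses, path, delim = ",") {
  stopifnot(all(tc_columns %in% names(timecourses)))
  readr::write_delim(timecourses[tc_columns], path, delim = delim)
  invisible(path)
}

default_screen_config <- function() {
  list(
    seed = 1L,
    input = NULL,
    qc_input = NULL,
    output_dir = "qit_results",
    background_au = 50,
    thresholds = list(mode = "fixed", upper = 3, lower = 0.3,
                      target_fdr = 0.025),
    fit = list(k_lower = 1e-5, k_upper = 1e2),
    simulator = unclass(qit_config()),
    log_level = "info"
  )
}

#' Read and validate a screen configuration file
#'
#' YAML file with top-level keys `seed`, `input` (path to a time-course
#' table; omit to simulate), `qc_input`, `output_dir`, `background_au`,
#' `thresholds` (`mode`, `upper`, `lower`, `target_fdr`), `fit`
#' (`k_lower`, `k_upper`) and `simulator` (any [qit_config()] field).
#' Unknown keys are rejected with a message naming them; omitted keys take
#' the package defaults.
#'
#' @param path YAML config path; `NULL` returns the defaults.
#' @return Validated nested config list of class `qit_screen_config`.
#' @export
read_screen_config <- function(path = NULL) {
  cfg <- default_screen_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (blk in c("thresholds", "fit", "simulator")) {
      if (!is.null(user[[blk]])) {
        bad <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
        if (length(bad) > 0)
          stop(sprintf("unknown config key(s) in '%s': %s", blk,
                       paste(bad, collapse = ", ")), call. = FALSE)
        cfg[[blk]] <- utils::modifyList(cfg[[blk]], user[[blk]])
        user[[blk]] <- NULL
      }
    }
    cfg <- utils::modifyList(cfg, user[!vapply(user, is.null, logical(1))])
  }
  cfg$simulator$seed <- cfg$seed
  validate_qit_config(cfg$simulator)
  ref_policy(upper = cfg$thresholds$upper, lower = cfg$thresholds$lower,
             target_fdr = cfg$thresholds$target_fdr)
  if (!cfg$thresholds$mode %in% c("fixed", "derived"))
    stop("thresholds$mode must be 'fixed' or 'derived'", call. = FALSE)
  if (!is.numeric(cfg$background_au) || length(cfg$background_au) != 1)
    stop("background_au must be a single number", call. = FALSE)
  if (cfg$fit$k_lower <= 0 || cfg$fit$k_upper <= cfg$fit$k_lower)
    stop("fit bounds must satisfy 0 < k_lower < k_upper", call. = FALSE)
  structure(cfg, class = "qit_screen_config")
}

#' Run the full qIT analysis pipeline
#'
#' Executes simulate/ingest -> DMSO normalization -> exponential fitting ->
#' REF and hit calls -> matrix summaries -> reactivity correlation -> Z'
#' QC, and writes the result tables plus a run manifest to
#' `config$output_dir`. Reruns with the same config and seed are
#' byte-identical.
#'
#' @param config A `qit_screen_config` from [read_screen_config()], or
#'   `NULL` for the defaults (simulated screen).
#' @param seed Optional integer overriding `config$seed`.
#' @param output_dir Optional override of `config$output_dir`.
#' @return Invisibly, a list of class `qit_results` with elements
#'   `timecourses`, `truth` (simulated runs only), `fits`, `ref_calls`,
#'   `summaries`, `correlation`, `qc`, `manifest`.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, output_dir = NULL) {
  if (is.null(config)) config <- read_screen_config(NULL)
  stopifnot(inherits(config, "qit_screen_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$simulator$seed <- as.integer(seed)
  }
  if (!is.null(output_dir)) config$output_dir <- output_dir
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_cfg <- do.call(qit_config, config$simulator)

  truth <- NULL
  if (is.null(config$input)) {
    qit_log("simulating screen (seed %d)", config$seed)
    truth <- simulate_truth(sim_cfg)
    tc <- simulate_timecourses(truth, sim_cfg)
    qc_tc <- simulate_qc_plate(sim_cfg)
  } else {
    qit_log("reading time courses from %s", config$input)
    tc <- read_timecourses(config$input)
    qc_tc <- if (!is.null(config$qc_input)) read_timecourses(config$qc_input)
             else dplyr::filter(tc, .data$role %in%
                                  c("positive_control", "negative_control"))
  }

  qit_log("normalizing against DMSO controls")
  norm <- normalize_screen(tc, config$background_au)
  qit_log("fitting %d series", dplyr::n_distinct(paste(norm$fragment_id,
                                                       norm$target_id)))
  fits <- fit_kinetics(norm, config$fit$k_lower, config$fit$k_upper)

  policy <- if (config$thresholds$mode == "derived") {
    prelim <- call_hits(fits, ref_policy(target_fdr =
                                           config$thresholds$target_fdr))
    derive_thresholds(prelim$ref, config$thresholds$target_fdr)
  } else {
    ref_policy(config$thresholds$upper, config$thresholds$lower,
               config$thresholds$target_fdr)
  }
  calls <- call_hits(fits, policy)
  summaries <- dplyr::bind_rows(
    dplyr::mutate(average_reactivity(fits, "per_fragment"),
                  axis = "per_fragment", id = .data$fragment_id),
    dplyr::mutate(average_reactivity(fits, "per_target"),
                  axis = "per_target", id = .data$target_id)) |>
    dplyr::select("axis", "id", "k_geomean_h", "n_cells")
  correlation <- tryCatch(correlate_reactivity(fits), error = function(e) {
    qit_log("correlation skipped: %s", conditionMessage(e), level = "WARN")
    NULL
  })
  qc <- if (nrow(qc_tc) > 0) {
    tryCatch(zprime_timecourse(qc_tc), error = function(e) {
      qit_log("QC skipped: %s", conditionMessage(e), level = "WARN")
      NULL
    })
  }

  readr::write_csv(fits$fits, file.path(out_dir, "fits.csv"))
  readr::write_csv(dplyr::mutate(calls, ref_2sf = format_ref(.data$ref)),
                   file.path(out_dir, "ref_calls.csv"))
  readr::write_csv(summaries, file.path(out_dir, "matrix_summary.csv"))
  if (!is.null(correlation))
    readr::write_csv(correlation, file.path(out_dir, "correlation.csv"))
  if (!is.null(qc)) {
    v <- attr(qc, "verdict")
    readr::write_csv(qc, file.path(out_dir, "qc_report.csv"))
    writeLines(sprintf("screen verdict: %s (Z' %.4f to %.4f)",
                       v$min_grade, v$z_min, v$z_max),
               file.path(out_dir, "qc_verdict.txt"))
  }
  if (!is.null(truth)) {
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
    write_timecourses(tc, file.path(out_dir, "timecourses.csv"))
  }
  manifest <- list(
    package = "qitscreen",
    version = as.character(utils::packageVersion("qitscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(config$seed),
    config_hash = rlang::hash(unclass(config)),
    policy = unclass(policy),
    outputs = list.files(out_dir, pattern = "[.](csv|txt)$"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  qit_log("wrote %d files to %s", length(manifest$outputs) + 1L, out_dir)
  invisible(structure(
    list(timecourses = tc, truth = truth, fits = fits, ref_calls = calls,
         summaries = summaries, correlation = correlation, qc = qc,
         manifest = manifest),
    class = "qit_results"))
}

#' @export
print.qit_results <- function(x, ...) {
  cat("<qit_results>\n")
  print(x$fits)
  cat(sprintf("  %d REF calls (%d accelerated, %d retarded)\n",
              nrow(x$ref_calls), sum(x$ref_calls$hit_class == "accelerated"),
              sum(x$ref_calls$hit_class == "retarded")))
  if (!is.null(x$qc)) {
    v <- attr(x$qc, "verdict")
    cat(sprintf("  QC: %s (Z' %.2f-%.2f)\n", v$min_grade, v$z_min, v$z_max))
  }
  invisible(x)
}
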