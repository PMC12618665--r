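#' Read and write simulator configurations as JSON
#'
#' The CLI exchanges configurations as JSON mirroring
#' [simulation_config()]; the bin scheme travels as parallel `lo`/`hi`
#' arrays. Unspecified fields fall back to [default_config()].
#'
#' @param path JSON file path.
#' @return `read_config_json()` returns a `simulation_config`.
#' @export
read_config_json <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  scheme <- if (!is.null(raw$bin_scheme)) {
    bin_scheme(raw$bin_scheme$lo, raw$bin_scheme$hi)
  } else {
    default_bin_scheme()
  }
  simulation_config(
    n_participants = raw$n_participants %||% 10L,
    n_images = raw$n_images %||% 65L,
    ga_range_weeks = raw$ga_range_weeks %||% c(13, 42),
    bin_scheme = scheme,
    model_error = as.list(raw$model_error %||% list()),
    population = as.list(raw$population %||% list()),
    helped_fraction = raw$helped_fraction %||% 0.5,
    confidence = as.list(raw$confidence %||% list()),
    likert = as.list(raw$likert %||% list()),
    timing = as.list(raw$timing %||% list()),
    seed = raw$seed %||% 1L
  )
}

#' @rdname read_config_json
#' @param config A `simulation_config`.
#' @export
write_config_json <- function(config, path) {
  validate_simulation_config(config)
  out <- unclass(config)
  out$bin_scheme <- list(lo = config$bin_scheme$lo, hi = config$bin_scheme$hi)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

config_digest <- function(config) {
  out <- unclass(config)
  out$bin_scheme <- list(lo = config$bin_scheme$lo, hi = config$bin_scheme$hi)
  fnv1a32(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA))
}

write_manifest <- function(out_dir, command, config_digest, seed, inputs, outputs) {
  manifest <- list(
    command = command,
    config_digest = config_digest,
    seed = seed,
    inputs = inputs,
    outputs = outputs,
    tool_version = as.character(utils::packageVersion("woar")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Pipeline commands: simulate, analyze, report
#'
#' The end-to-end pipeline is three file-driven commands with no hidden
#' state. `cmd_simulate()` generates a synthetic study and writes the three
#' study CSVs; `cmd_analyze()` reads a study directory and writes
#' `metrics.csv`, `reliance_summary.csv` and `results_report.{json,md}`;
#' `cmd_report()` condenses the analysis outputs into a single Markdown
#' summary (`report.md`). Each command drops a manifest recording the
#' command, config digest, seed, paths and tool version. The data outputs
#' are byte-reproducible for a fixed seed; manifests carry a timestamp and
#' are the one exception.
#'
#' @param config_path Path to a JSON config, or NULL for the default.
#' @param seed Integer seed (overrides the config's).
#' @param out_dir Output directory.
#' @return The written file paths, invisibly.
#' @export
cmd_simulate <- function(config_path = NULL, seed = NULL, out_dir) {
  config <- if (is.null(config_path)) default_config() else read_config_json(config_path)
  seed <- as.integer(seed %||% config$seed)
  tbl <- generate_study(config, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_study_csv(tbl, out_dir)
  write_manifest(out_dir, "simulate", config_digest(config), seed,
                 inputs = config_path %||% "default_config", outputs = unname(paths))
  message(sprintf("simulate: wrote %d estimates, %d predictions, %d likert rows to %s",
                  nrow(tbl$estimates), nrow(tbl$predictions), nrow(tbl$likert), out_dir))
  invisible(paths)
}

#' @rdname cmd_simulate
#' @param study_dir Directory holding `estimates.csv`, `predictions.csv`,
#'   `likert.csv`.
#' @export
cmd_analyze <- function(study_dir, out_dir) {
  tbl <- read_study_csv(
    file.path(study_dir, "estimates.csv"),
    file.path(study_dir, "predictions.csv"),
    file.path(study_dir, "likert.csv")
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- stage_metrics(tbl)
  rel <- reliance_summary(tbl)
  battery <- run_full_battery(tbl)
  metrics_path <- file.path(out_dir, "metrics.csv")
  rel_path <- file.path(out_dir, "reliance_summary.csv")
  readr::write_csv(metrics, metrics_path, progress = FALSE)
  readr::write_csv(rel, rel_path, progress = FALSE)
  report_paths <- write_results_report(battery, out_dir)
  skipped <- battery[battery$note != "", ]
  for (i in seq_len(nrow(skipped))) {
    message(sprintf("analyze: %s [%s] %s", skipped$comparison[i],
                    skipped$variant[i], skipped$note[i]))
  }
  message(sprintf("analyze: %d comparisons computed, %d skipped",
                  sum(battery$note == ""), nrow(skipped)))
  paths <- c(metrics = metrics_path, reliance = rel_path, report_paths)
  write_manifest(out_dir, "analyze", "", NA_integer_,
                 inputs = study_dir, outputs = unname(paths))
  invisible(paths)
}

#' @rdname cmd_simulate
#' @param results_dir Directory holding `cmd_analyze()` outputs.
#' @param out_path Path for the condensed Markdown report.
#' @export
cmd_report <- function(results_dir, out_path = file.path(results_dir, "report.md")) {
  metrics_path <- file.path(results_dir, "metrics.csv")
  rel_path <- file.path(results_dir, "reliance_summary.csv")
  bat_path <- file.path(results_dir, "results_report.md")
  for (p in c(metrics_path, rel_path, bat_path)) {
    if (!file.exists(p)) stopf("missing analysis output: %s", p)
  }
  metrics <- readr::read_csv(metrics_path, show_col_types = FALSE, progress = FALSE)
  rel <- readr::read_csv(rel_path, show_col_types = FALSE, progress = FALSE)

  stage_tbl <- metrics |>
    dplyr::group_by(stage) |>
    dplyr::summarise(
      mae_days_mean = mean(mae_days), mae_days_sd = stats::sd(mae_days),
      confidence_mean = mean(confidence_mean),
      time_mean_sec = mean(time_mean_sec), .groups = "drop"
    )
  rel_tbl <- rel |>
    dplyr::group_by(stage) |>
    dplyr::summarise(
      agreement_mean = mean(agreement), agreement_sd = stats::sd(agreement),
      woa_mean = mean(mean_woa, na.rm = TRUE),
      p_appropriate = mean(p_appropriate), p_under = mean(p_under),
      p_over = mean(p_over), .groups = "drop"
    )

  lines <- c(
    "# Reader-study report",
    "",
    "## Performance and confidence by stage",
    "",
    "| stage | MAE (days) | SD | mean confidence | mean time (s) |",
    "|---|---|---|---|---|",
    sprintf("| %d | %.1f | %.1f | %.2f | %.1f |",
            stage_tbl$stage, stage_tbl$mae_days_mean, stage_tbl$mae_days_sd,
            stage_tbl$confidence_mean, stage_tbl$time_mean_sec),
    "",
    "Stage 1 times are not comparable with stages 2-3 (extra annotation work).",
    "",
    "## Reliance on the model (advised stages)",
    "",
    "| stage | agreement | SD | mean WoA | appropriate | under | over |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %d | %.2f | %.2f | %.2f | %.2f | %.2f | %.2f |",
            rel_tbl$stage, rel_tbl$agreement_mean, rel_tbl$agreement_sd,
            rel_tbl$woa_mean, rel_tbl$p_appropriate, rel_tbl$p_under,
            rel_tbl$p_over),
    "",
    readLines(bat_path)
  )
  writeLines(lines, out_path)
  message(sprintf("report: wrote %s", out_path))
  invisible(out_path)
}
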