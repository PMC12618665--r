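#' Mean absolute error of one participant at one stage, in days
#'
#' Errors are computed in weeks (`|estimate - truth|`) and reported in days
#' (x7), the unit GA accuracy is conventionally quoted in.
#'
#' @param table A [study_table()].
#' @param participant_id Participant.
#' @param stage Stage 1, 2 or 3.
#' @return MAE in days.
#' @export
mae_days <- function(table, participant_id, stage) {
  est <- table$estimates
  sub <- est[est$participant_id == participant_id & est$stage == stage, ]
  if (!nrow(sub)) stopf("no stage-%d records for participant %s", stage, participant_id)
  mean(abs(sub$estimate_weeks - sub$true_ga_weeks)) * 7
}

#' Change in MAE between two stages, in days
#'
#' `delta_mae(..., stage_a = 2, stage_b = 3)` is MAE(stage 3) - MAE(stage 2):
#' negative means the participant improved in the later stage.
#'
#' @inheritParams mae_days
#' @param stage_a,stage_b Stages to compare.
#' @return Signed difference in days (MAE_b - MAE_a).
#' @export
delta_mae <- function(table, participant_id, stage_a, stage_b) {
  mae_days(table, participant_id, stage_b) - mae_days(table, participant_id, stage_a)
}

#' Confidence histogram at a stage
#'
#' Counts of each ordinal confidence level 1-5, optionally restricted to a
#' subset of participants (used for the helpful / not-helpful split).
#'
#' @inheritParams mae_days
#' @param participant_subset Participant ids to include (default all).
#' @return Named integer vector of counts for levels "1".."5".
#' @export
confidence_distribution <- function(table, stage,
                                    participant_subset = participants(table)) {
  est <- table$estimates
  sub <- est[est$stage == stage & est$participant_id %in% participant_subset, ]
  counts <- tabulate(sub$confidence, nbins = 5L)
  stats::setNames(as.integer(counts), as.character(1:5))
}

#' Feature usage in the unaided stage
#'
#' In stage 1 participants record which image features informed each
#' estimate. This summarises the mean number of features cited per image
#' and each participant's repertoire (number of distinct features they used
#' at least once).
#'
#' @param table A [study_table()].
#' @return List with `mean_per_image`, `sd_per_image`, and a tibble
#'   `repertoire` (`participant_id`, `n_features`).
#' @export
feature_usage_summary <- function(table) {
  est <- table$estimates
  s1 <- est[est$stage == 1, ]
  feats <- strsplit(ifelse(is.na(s1$features), "", s1$features), ";", fixed = TRUE)
  feats <- lapply(feats, function(f) f[nzchar(f)])
  n_per_image <- vapply(feats, length, integer(1))
  rep_tbl <- tibble::tibble(participant_id = s1$participant_id,
                            features = feats)
  repertoire <- rep_tbl |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(n_features = length(unique(unlist(features))),
                     .groups = "drop")
  list(
    mean_per_image = if (length(n_per_image)) mean(n_per_image) else 0,
    sd_per_image = if (length(n_per_image) > 1) stats::sd(n_per_image) else 0,
    repertoire = repertoire
  )
}

#' Response-time summary at a stage
#'
#' Mean and SD of seconds per estimate across all records at the stage.
#' Stage 1 asked participants for extra annotation work, so its times are
#' flagged as not comparable with the advised stages.
#'
#' @inheritParams mae_days
#' @return Tibble with `stage`, `mean_sec`, `sd_sec`, `n`, `comparable`.
#' @export
timing_summary <- function(table, stage) {
  est <- table$estimates
  sub <- est[est$stage == stage, ]
  if (!nrow(sub)) stopf("no stage-%d records", stage)
  tibble::tibble(
    stage = as.integer(stage),
    mean_sec = mean(sub$time_sec),
    sd_sec = if (nrow(sub) > 1) stats::sd(sub$time_sec) else 0,
    n = nrow(sub),
    comparable = stage != 1L
  )
}

#' Per-participant, per-stage metric table
#'
#' One row per participant x stage with MAE (days), mean confidence, mean
#' time and image count; the shape of the `metrics.csv` artifact. Aggregate
#' study MAE is the unweighted mean of the per-participant MAEs in this
#' table (participant-level aggregation), and its SD is across
#' participants.
#'
#' @param table A [study_table()].
#' @return Tibble with `participant_id`, `stage`, `mae_days`,
#'   `confidence_mean`, `time_mean_sec`, `n`.
#' @export
stage_metrics <- function(table) {
  est <- table$estimates
  est |>
    dplyr::group_by(participant_id, stage) |>
    dplyr::summarise(
      mae_days = mean(abs(estimate_weeks - true_ga_weeks)) * 7,
      confidence_mean = mean(confidence),
      time_mean_sec = mean(time_sec),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(participant_id, stage)
}
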