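#' Assemble and validate a three-stage reader-study table
#'
#' A `study_table` bundles everything one reader study produces:
#'
#' * `estimates`: one row per participant x image x stage, with the ground
#'   truth GA, the participant's estimate (weeks), ordinal confidence (1-5),
#'   the time taken (seconds), and -- in stage 1 only -- the image features
#'   the participant reported using (semicolon-joined tags).
#' * `predictions`: one row per image with the model's GA bin and its scalar
#'   point value (weeks).
#' * `likert`: questionnaire responses (participant, timepoint, item, 1-5).
#' * `bin_scheme`: the GA discretisation the model used.
#'
#' Stages mean: 1 = unaided, 2 = model prediction shown, 3 = prediction plus
#' explanation shown. Validation enforces the structural invariants the
#' analysis relies on (uniqueness of participant x image x stage, one
#' prediction per image, all three stages on the same image set per
#' participant, estimates within 10-45 weeks, confidence in 1..5, features
#' only in stage 1).
#'
#' @param estimates Data frame of estimate records (see Details).
#' @param predictions Data frame with `image_id`, `bin_lo_weeks`,
#'   `bin_hi_weeks`, `point_weeks`.
#' @param likert Data frame with `participant_id`, `timepoint`, `item_id`,
#'   `value`; may be empty.
#' @param bin_scheme A [bin_scheme()].
#' @return A validated `study_table` object.
#' @export
study_table <- function(estimates, predictions, likert = empty_likert(),
                        bin_scheme = default_bin_scheme()) {
  tbl <- structure(
    list(
      estimates = tibble::as_tibble(estimates),
      predictions = tibble::as_tibble(predictions),
      likert = tibble::as_tibble(likert),
      bin_scheme = bin_scheme
    ),
    class = "study_table"
  )
  validate_study_table(tbl)
  tbl
}

empty_likert <- function() {
  tibble::tibble(
    participant_id = character(), timepoint = character(),
    item_id = character(), value = integer()
  )
}

#' @rdname study_table
#' @param table A `study_table`.
#' @export
validate_study_table <- function(table) {
  est <- table$estimates
  pred <- table$predictions
  lik <- table$likert

  need <- c("participant_id", "image_id", "stage", "true_ga_weeks",
            "estimate_weeks", "confidence", "time_sec", "features")
  miss <- setdiff(need, names(est))
  if (length(miss)) stopf("estimates is missing columns: %s", paste(miss, collapse = ", "))
  need_p <- c("image_id", "bin_lo_weeks", "bin_hi_weeks", "point_weeks")
  miss <- setdiff(need_p, names(pred))
  if (length(miss)) stopf("predictions is missing columns: %s", paste(miss, collapse = ", "))
  need_l <- c("participant_id", "timepoint", "item_id", "value")
  miss <- setdiff(need_l, names(lik))
  if (length(miss)) stopf("likert is missing columns: %s", paste(miss, collapse = ", "))

  validate_bin_scheme(table$bin_scheme)

  bad <- which(!(est$stage %in% 1:3))
  if (length(bad)) stopf("estimates row %d: stage must be 1, 2 or 3", bad[1])
  bad <- which(!(est$confidence %in% 1:5))
  if (length(bad)) stopf("estimates row %d: confidence must be an integer in 1..5", bad[1])
  bad <- which(est$estimate_weeks < 10 | est$estimate_weeks > 45)
  if (length(bad)) stopf("estimates row %d: estimate_weeks must lie in [10, 45]", bad[1])
  bad <- which(!is.finite(est$true_ga_weeks))
  if (length(bad)) stopf("estimates row %d: true_ga_weeks must be finite", bad[1])
  bad <- which(est$time_sec < 0)
  if (length(bad)) stopf("estimates row %d: time_sec must be non-negative", bad[1])
  feats <- est$features
  feats[is.na(feats)] <- ""
  bad <- which(est$stage != 1 & nzchar(feats))
  if (length(bad)) stopf("estimates row %d: features are only recorded in stage 1", bad[1])

  key <- paste(est$participant_id, est$image_id, est$stage, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stopf("estimates row %d: duplicate (participant_id, image_id, stage)", dup[1])
  }

  if (anyDuplicated(pred$image_id)) stopf("predictions: duplicate image_id")
  bad <- which(!(pred$point_weeks >= pred$bin_lo_weeks - 1e-9 &
                 pred$point_weeks <= pred$bin_hi_weeks + 1e-9))
  if (length(bad)) stopf("predictions row %d: point_weeks must lie inside its bin", bad[1])

  unmatched <- setdiff(unique(est$image_id), pred$image_id)
  if (length(unmatched)) {
    stopf("every image in estimates needs a model prediction; missing: %s",
          unmatched[1])
  }

  # each participant sees the same image set at all three stages
  split_imgs <- split(est, est$participant_id)
  for (pid in names(split_imgs)) {
    sub <- split_imgs[[pid]]
    per_stage <- lapply(1:3, function(s) sort(unique(sub$image_id[sub$stage == s])))
    if (!identical(per_stage[[1]], per_stage[[2]]) ||
        !identical(per_stage[[2]], per_stage[[3]])) {
      stopf("participant %s: the three stages must cover the same image set", pid)
    }
  }

  if (nrow(lik)) {
    bad <- which(!(lik$value %in% 1:5))
    if (length(bad)) stopf("likert row %d: value must be an integer in 1..5", bad[1])
    ok_tp <- c("pre_study", "post_stage2", "post_stage3", "post_study")
    bad <- which(!(lik$timepoint %in% ok_tp))
    if (length(bad)) stopf("likert row %d: unknown timepoint", bad[1])
  }

  invisible(table)
}

#' @export
print.study_table <- function(x, ...) {
  est <- x$estimates
  cat("<study_table>\n")
  cat(sprintf("  participants: %d\n", length(unique(est$participant_id))))
  cat(sprintf("  images:       %d\n", length(unique(est$image_id))))
  cat(sprintf("  estimates:    %d rows over stages {%s}\n",
              nrow(est), paste(sort(unique(est$stage)), collapse = ",")))
  cat(sprintf("  predictions:  %d\n", nrow(x$predictions)))
  cat(sprintf("  likert:       %d responses\n", nrow(x$likert)))
  invisible(x)
}

#' Participant identifiers of a study table
#'
#' @param table A `study_table`.
#' @return Sorted vector of unique participant ids.
#' @export
participants <- function(table) sort(unique(table$estimates$participant_id))

# Wide per-image frame for one participant: truth, stage-1..3 estimates and
# the model point / bin. Used by most metrics.
participant_wide <- function(table, participant_id) {
  est <- table$estimates
  sub <- est[est$participant_id == participant_id, , drop = FALSE]
  if (!nrow(sub)) stopf("no records for participant %s", participant_id)
  wide <- tidyr::pivot_wider(
    sub[, c("image_id", "stage", "true_ga_weeks", "estimate_weeks")],
    names_from = "stage", values_from = "estimate_weeks", names_prefix = "est_"
  )
  dplyr::left_join(wide, table$predictions, by = "image_id")
}
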