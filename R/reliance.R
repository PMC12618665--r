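#' Weight of Advice
#'
#' The Weight of Advice (WoA) from the judge-advisor literature measures how
#' far a judge moved toward an advisor:
#' \deqn{WoA = (prior - posterior) / (prior - model)}
#' where `prior` is the estimate before seeing the advice, `posterior` the
#' revised estimate, and `model` the advisor's value (all in weeks here).
#' A value of 0 means the estimate did not change, 0.5 that the judge
#' averaged the two, 1 that the judge adopted the advice, negative that they
#' moved away, and above 1 that they overshot.
#'
#' When the prior already sits within `exclude_lt` weeks of the advice the
#' ratio is meaningless (the model's two-week interval makes prior and model
#' effectively agree, and the denominator can vanish), so such points are
#' flagged excluded rather than given a value.
#'
#' @param prior,posterior,model Numeric GA estimates in weeks (vectorised).
#' @param exclude_lt Exclusion threshold in weeks: points with
#'   `|prior - model| < exclude_lt` are excluded. Default 1.
#' @return A tibble with columns `prior_weeks`, `posterior_weeks`,
#'   `model_weeks`, `excluded` (logical) and `value` (NA when excluded).
#' @export
#' @examples
#' weight_of_advice(20, 25, 30)  # moved half way: 0.5
#' weight_of_advice(20, 30, 30)  # adopted the advice: 1
#' weight_of_advice(29.5, 30, 30)  # prior within a week of advice: excluded
weight_of_advice <- function(prior, posterior, model, exclude_lt = 1) {
  n <- max(length(prior), length(posterior), length(model))
  prior <- rep_len(as.numeric(prior), n)
  posterior <- rep_len(as.numeric(posterior), n)
  model <- rep_len(as.numeric(model), n)
  if (!all(is.finite(prior), is.finite(posterior), is.finite(model))) {
    stopf("weight_of_advice requires finite inputs")
  }
  excluded <- abs(prior - model) < exclude_lt
  value <- ifelse(excluded, NA_real_, (prior - posterior) / (prior - model))
  value <- value + 0  # normalise IEEE negative zero from an unchanged estimate
  tibble::tibble(
    prior_weeks = prior, posterior_weeks = posterior, model_weeks = model,
    excluded = excluded, value = value
  )
}

#' Mean Weight of Advice for one participant and stage
#'
#' Computes WoA image-by-image for a participant at an advised stage (2 or
#' 3) and averages the non-excluded values. The prior defaults to the
#' stage-1 (unaided) estimate for both stages, since that is the estimate
#' made before any information from the model; set `prior_stage = 2` to use
#' the stage-2 estimate as the prior for stage-3 WoA instead.
#'
#' @param table A [study_table()].
#' @param participant_id Participant to summarise.
#' @param stage Advised stage, 2 or 3.
#' @param prior_stage Stage providing the prior estimate (default 1).
#' @param exclude_lt Exclusion threshold in weeks (see [weight_of_advice()]).
#' @return A one-row tibble with `participant_id`, `stage`, `mean_woa`
#'   (NA if every image was excluded), `n_used`, `n_excluded`.
#' @export
mean_woa <- function(table, participant_id, stage, prior_stage = 1,
                     exclude_lt = 1) {
  if (!stage %in% c(2L, 3L)) stopf("WoA is defined for advised stages 2 and 3")
  if (!prior_stage %in% c(1L, 2L)) stopf("prior_stage must be 1 or 2")
  if (prior_stage >= stage) stopf("prior_stage must precede stage")
  wide <- participant_wide(table, participant_id)
  prior <- wide[[paste0("est_", prior_stage)]]
  post <- wide[[paste0("est_", stage)]]
  if (is.null(prior) || anyNA(prior)) stopf("missing stage-%d records for participant %s", prior_stage, participant_id)
  if (is.null(post) || anyNA(post)) stopf("missing stage-%d records for participant %s", stage, participant_id)
  woa <- weight_of_advice(prior, post, wide$point_weeks, exclude_lt = exclude_lt)
  used <- woa$value[!woa$excluded]
  tibble::tibble(
    participant_id = participant_id,
    stage = as.integer(stage),
    mean_woa = if (length(used)) mean(used) else NA_real_,
    n_used = length(used),
    n_excluded = sum(woa$excluded)
  )
}

#' Classify reliance behaviour for one estimate revision
#'
#' Behaviour-based typing of whether a revision toward (or away from) the
#' model was warranted. With ground truth `y`, unaided estimate `p1`,
#' advised estimate `p2` and model value `m` (weeks):
#'
#' * absolute errors: `eps_p1 = |p1 - y|`, `eps_p2 = |p2 - y|`,
#'   `eps_m = |m - y|`;
#' * distances to the model: `delta1 = |p1 - m|`, `delta2 = |p2 - m|`;
#' * relied: `R = 1` iff `delta2 < delta1` (strictly moved toward the model);
#' * model better: `E_m = 1` iff `eps_m < eps_p1` (strictly);
#' * label: `appropriate` iff `R == E_m`, `under` iff the participant did not
#'   rely although the model was better, `over` iff they relied although it
#'   was worse.
#'
#' Ties are deliberate: an unchanged estimate is "not relying" and an
#' equally-accurate model is "not better", so both tie cases count as
#' appropriate. The classification judges the behaviour, not whether the
#' final estimate improved.
#'
#' @param y,p1,p2,m Numeric vectors in weeks (recycled to common length).
#' @return A tibble with `eps_p1`, `eps_p2`, `eps_m`, `delta1`, `delta2`,
#'   `relied`, `model_better` (0/1 integers) and `label` (factor with levels
#'   appropriate, under, over).
#' @export
classify_reliance <- function(y, p1, p2, m) {
  n <- max(length(y), length(p1), length(p2), length(m))
  y <- rep_len(as.numeric(y), n); p1 <- rep_len(as.numeric(p1), n)
  p2 <- rep_len(as.numeric(p2), n); m <- rep_len(as.numeric(m), n)
  if (!all(is.finite(y), is.finite(p1), is.finite(p2), is.finite(m))) {
    stopf("classify_reliance requires finite inputs")
  }
  eps_p1 <- abs(p1 - y); eps_p2 <- abs(p2 - y); eps_m <- abs(m - y)
  delta1 <- abs(p1 - m); delta2 <- abs(p2 - m)
  relied <- as.integer(delta2 < delta1)
  model_better <- as.integer(eps_m < eps_p1)
  label <- ifelse(relied == model_better, "appropriate",
                  ifelse(relied == 0L, "under", "over"))
  tibble::tibble(
    eps_p1 = eps_p1, eps_p2 = eps_p2, eps_m = eps_m,
    delta1 = delta1, delta2 = delta2,
    relied = relied, model_better = model_better,
    label = factor(label, levels = c("appropriate", "under", "over"))
  )
}

#' Reliance-type proportions for one participant and stage
#'
#' Classifies every image with [classify_reliance()] (prior = stage-1
#' estimate; no exclusion rule applies here) and reports the proportion of
#' images in each reliance type.
#'
#' @inheritParams mean_woa
#' @return One-row tibble: `participant_id`, `stage`, `p_appropriate`,
#'   `p_under`, `p_over`, `n`, plus raw counts `n_appropriate`, `n_under`,
#'   `n_over`.
#' @export
reliance_proportions <- function(table, participant_id, stage) {
  if (!stage %in% c(2L, 3L)) stopf("reliance typing needs an advised stage (2 or 3)")
  wide <- participant_wide(table, participant_id)
  post <- wide[[paste0("est_", stage)]]
  if (is.null(post) || anyNA(post)) stopf("missing stage-%d records for participant %s", stage, participant_id)
  if (!nrow(wide)) stopf("no images for participant %s", participant_id)
  cls <- classify_reliance(wide$true_ga_weeks, wide$est_1, post, wide$point_weeks)
  counts <- table(cls$label)
  n <- nrow(cls)
  tibble::tibble(
    participant_id = participant_id,
    stage = as.integer(stage),
    p_appropriate = as.numeric(counts[["appropriate"]]) / n,
    p_under = as.numeric(counts[["under"]]) / n,
    p_over = as.numeric(counts[["over"]]) / n,
    n = n,
    n_appropriate = as.integer(counts[["appropriate"]]),
    n_under = as.integer(counts[["under"]]),
    n_over = as.integer(counts[["over"]])
  )
}

#' Agreement with the model's predicted interval
#'
#' The proportion of a participant's estimates at a stage that fall inside
#' the GA bin the model predicted for the image (half-open bins, last bin
#' closed). Unlike WoA, agreement is defined at every stage and uses all
#' images.
#'
#' @inheritParams mean_woa
#' @param stage Stage 1, 2 or 3.
#' @return A single proportion in \[0, 1\].
#' @export
agreement <- function(table, participant_id, stage) {
  if (!stage %in% 1:3) stopf("stage must be 1, 2 or 3")
  wide <- participant_wide(table, participant_id)
  est <- wide[[paste0("est_", stage)]]
  if (is.null(est) || anyNA(est)) stopf("missing stage-%d records for participant %s", stage, participant_id)
  if (!nrow(wide)) stopf("no images for participant %s", participant_id)
  scheme_max <- max(table$bin_scheme$hi)
  mean(in_bin(est, wide$bin_lo_weeks, wide$bin_hi_weeks, scheme_max))
}

#' Natural log ratio of two proportions
#'
#' `log_ratio(p_a, p_b) = ln(p_a / p_b)`; e.g. a value of 1.1 means p_a is
#' about three times p_b. The natural base keeps the prose reading of study
#' results honest (exp of the ratio is the fold difference). Zero handling
#' for proportions derived from counts lives upstream: form them with a
#' Haldane-style half count via [haldane_proportions()].
#'
#' @param p_a,p_b Proportions (vectorised), each > 0; if both are 0 the
#'   result is NA with a warning.
#' @return Numeric vector `ln(p_a / p_b)`.
#' @export
log_ratio <- function(p_a, p_b) {
  n <- max(length(p_a), length(p_b))
  p_a <- rep_len(as.numeric(p_a), n); p_b <- rep_len(as.numeric(p_b), n)
  if (any(p_a < 0 | p_b < 0, na.rm = TRUE)) stopf("proportions must be non-negative")
  both_zero <- p_a == 0 & p_b == 0
  if (any(both_zero, na.rm = TRUE)) {
    warning("log_ratio undefined where both proportions are zero; returning NA")
  }
  out <- log(p_a / p_b)
  out[both_zero] <- NA_real_
  out
}

#' Haldane-smoothed proportions from counts
#'
#' Adds half a count to each category before forming proportions, so
#' log-ratios stay finite when a category is empty. Used for the paired
#' log-ratio tests on reliance-type counts.
#'
#' @param counts Non-negative integer vector (or matrix, smoothed row-wise).
#' @return Proportions after adding 0.5 to every count.
#' @export
haldane_proportions <- function(counts) {
  if (is.matrix(counts)) {
    sm <- counts + 0.5
    return(sm / rowSums(sm))
  }
  sm <- counts + 0.5
  sm / sum(sm)
}

#' Per-participant reliance summary table
#'
#' One row per participant x advised stage with reliance proportions, mean
#' WoA (with its exclusion count) and agreement; the shape of the
#' `reliance_summary.csv` artifact.
#'
#' @inheritParams mean_woa
#' @return Tibble with columns `participant_id`, `stage`, `p_appropriate`,
#'   `p_under`, `p_over`, `n`, `mean_woa`, `n_excluded`, `agreement`.
#' @export
reliance_summary <- function(table, prior_stage = 1, exclude_lt = 1) {
  rows <- list()
  for (pid in participants(table)) {
    for (s in c(2L, 3L)) {
      props <- reliance_proportions(table, pid, s)
      woa <- mean_woa(table, pid, s, prior_stage = prior_stage,
                      exclude_lt = exclude_lt)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = pid, stage = s,
        p_appropriate = props$p_appropriate, p_under = props$p_under,
        p_over = props$p_over, n = props$n,
        mean_woa = woa$mean_woa, n_excluded = woa$n_excluded,
        agreement = agreement(table, pid, s),
        n_appropriate = props$n_appropriate, n_under = props$n_under,
        n_over = props$n_over
      )
    }
  }
  dplyr::bind_rows(rows)
}
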