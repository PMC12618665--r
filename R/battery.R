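#' Run the full statistical battery on a study table
#'
#' Orchestrates every comparison the analysis reports, one row per test:
#'
#' * MAE (days) stage 1 vs 2 and 2 vs 3: independent t-test with Cohen's d
#'   on per-participant MAEs;
#' * agreement stage 1 vs 2 and 2 vs 3: independent t-test;
#' * mean WoA stage 2 vs 3: independent t-test;
#' * confidence stage 1 vs 2 and 2 vs 3: Wilcoxon signed-rank on
#'   per-estimate (participant x image) pairs -- the per-estimate pairing is
#'   what gives these comparisons their power (n = participants x images,
#'   not 10);
#' * confidence split by self-reported explanation helpfulness within
#'   stages 2 and 3: Mann-Whitney U on pooled per-estimate confidences;
#' * trust questionnaire items after stage 2 vs after stage 3: Wilcoxon
#'   signed-rank per item, paired within participant;
#' * helpfulness rating vs change in MAE between stages 2 and 3:
#'   Pearson correlation with least-squares p;
#' * reliance-type log-ratios (appropriate vs under, under vs over) within
#'   stages 2 and 3: paired t-test on per-participant natural-log ratios of
#'   Haldane-smoothed proportions;
#' * comfort with clinical adoption before vs after the study: Wilcoxon
#'   signed-rank;
#' * time per estimate stage 2 vs 3: independent t-test on per-participant
#'   mean seconds (stage 1 timing is not comparable).
#'
#' The stage-wise independent t-tests mirror the original analysis choice
#' even though the design is paired; a labelled paired companion row
#' (`variant = "paired"`) is emitted alongside each so both views are
#' available. No multiple-testing correction is applied; the report carries
#' raw p-values and the count of tests run.
#'
#' A comparison whose inputs are missing or degenerate never crashes the
#' battery: its row is kept with NA numbers and a `note` explaining why it
#' was not computed.
#'
#' @param table A [study_table()].
#' @param helpful_item Likert item id used for the helpfulness split
#'   (default `"explanations_helpful"`, rated at `post_stage3`).
#' @param helpful_cut Ratings `>= helpful_cut` define the "found helpful"
#'   group (default 4).
#' @return A tibble of [test_result()] rows with `comparison`, `variant`,
#'   and `note` columns; attribute `n_tests` holds the number of primary
#'   (non-companion) tests computed.
#' @export
run_full_battery <- function(table, helpful_item = "explanations_helpful",
                             helpful_cut = 4L) {
  metrics <- stage_metrics(table)
  rel <- try_or_null(reliance_summary(table))
  rows <- list()
  add <- function(comparison, variant, expr) {
    res <- tryCatch(expr, error = function(e) {
      dplyr::mutate(
        test_result("none", NA_real_, NA_real_, NA_real_, NA_integer_),
        note = paste("not computed:", conditionMessage(e))
      )
    })
    if (!"note" %in% names(res)) res$note <- ""
    rows[[length(rows) + 1L]] <<- dplyr::bind_cols(
      tibble::tibble(comparison = comparison, variant = variant), res
    )
  }
  per_stage <- function(col, s) {
    m <- metrics[metrics$stage == s, ]
    m <- m[order(m$participant_id), ]
    m[[col]]
  }

  # --- accuracy ---
  for (pair in list(c(1, 2), c(2, 3))) {
    lab <- sprintf("mae_days stage %d vs %d", pair[1], pair[2])
    a <- per_stage("mae_days", pair[1]); b <- per_stage("mae_days", pair[2])
    add(lab, "as_reported", independent_t(a, b))
    add(lab, "paired", paired_t(a - b))
  }

  # --- agreement and WoA (participant level) ---
  agr <- function(s) vapply(participants(table), function(p) agreement(table, p, s), numeric(1))
  for (pair in list(c(1, 2), c(2, 3))) {
    lab <- sprintf("agreement stage %d vs %d", pair[1], pair[2])
    a <- agr(pair[1]); b <- agr(pair[2])
    add(lab, "as_reported", independent_t(a, b))
    add(lab, "paired", paired_t(a - b))
  }
  woa_s <- function(s) {
    if (is.null(rel)) stopf("reliance summary unavailable")
    v <- rel$mean_woa[rel$stage == s]
    v[!is.na(v)]
  }
  add("mean_woa stage 2 vs 3", "as_reported", independent_t(woa_s(2), woa_s(3)))
  add("mean_woa stage 2 vs 3", "paired", {
    a <- rel$mean_woa[rel$stage == 2]; b <- rel$mean_woa[rel$stage == 3]
    keep <- !is.na(a) & !is.na(b)
    paired_t(a[keep] - b[keep])
  })

  # --- confidence across stages (per-estimate pairing) ---
  conf_wide <- tidyr::pivot_wider(
    table$estimates[, c("participant_id", "image_id", "stage", "confidence")],
    names_from = "stage", values_from = "confidence", names_prefix = "c"
  )
  add("confidence stage 1 vs 2", "as_reported",
      wilcoxon_signed_rank(conf_wide$c2, conf_wide$c1))
  add("confidence stage 2 vs 3", "as_reported",
      wilcoxon_signed_rank(conf_wide$c3, conf_wide$c2))

  # --- helpfulness split ---
  helped_ids <- helpful_participants(table, helpful_item, helpful_cut)
  for (s in c(2L, 3L)) {
    lab <- sprintf("confidence by helpfulness, stage %d", s)
    add(lab, "as_reported", {
      if (is.null(helped_ids)) stopf("no %s responses", helpful_item)
      est <- table$estimates[table$estimates$stage == s, ]
      grp_a <- est$confidence[est$participant_id %in% helped_ids]
      grp_b <- est$confidence[!(est$participant_id %in% helped_ids)]
      if (!length(grp_a) || !length(grp_b)) stopf("helpfulness split is degenerate")
      mann_whitney_u(grp_a, grp_b)
    })
  }

  # --- trust items, after stage 2 vs after stage 3 ---
  for (item in trust_items(table)) {
    lab <- sprintf("trust item '%s' post-stage2 vs post-stage3", item)
    add(lab, "as_reported", {
      w <- likert_pairs(table, item, "post_stage2", "post_stage3")
      wilcoxon_signed_rank(w$b, w$a)
    })
  }

  # --- helpfulness rating vs delta MAE(3 - 2) ---
  add("helpfulness rating vs delta MAE (3-2)", "as_reported", {
    lik <- table$likert
    hr <- lik[lik$item_id == helpful_item & lik$timepoint == "post_stage3", ]
    if (!nrow(hr)) stopf("no %s responses", helpful_item)
    hr <- hr[order(hr$participant_id), ]
    dmae <- vapply(hr$participant_id, function(p) delta_mae(table, p, 2, 3), numeric(1))
    pearson_ls(hr$value, dmae)
  })

  # --- reliance-type log ratios (paired t within stage) ---
  if (!is.null(rel)) {
    for (s in c(2L, 3L)) {
      sub <- rel[rel$stage == s, ]
      props <- haldane_proportions(as.matrix(sub[, c("n_appropriate", "n_under", "n_over")]))
      add(sprintf("log-ratio appropriate vs under, stage %d", s), "as_reported",
          paired_t(log_ratio(props[, 1], props[, 2])))
      add(sprintf("log-ratio under vs over, stage %d", s), "as_reported",
          paired_t(log_ratio(props[, 2], props[, 3])))
    }
  } else {
    for (s in c(2L, 3L)) {
      add(sprintf("log-ratio appropriate vs under, stage %d", s), "as_reported",
          stopf("reliance summary unavailable"))
      add(sprintf("log-ratio under vs over, stage %d", s), "as_reported",
          stopf("reliance summary unavailable"))
    }
  }

  # --- comfort with clinical adoption, pre vs post study ---
  add("comfort in practice pre vs post study", "as_reported", {
    w <- likert_pairs(table, "comfort_practice", "pre_study", "post_study")
    wilcoxon_signed_rank(w$b, w$a)
  })

  # --- timing ---
  add("time per estimate stage 2 vs 3", "as_reported",
      independent_t(per_stage("time_mean_sec", 2), per_stage("time_mean_sec", 3)))

  out <- dplyr::bind_rows(rows)
  attr(out, "n_tests") <- sum(out$variant == "as_reported" & out$note == "")
  out
}

try_or_null <- function(expr) tryCatch(expr, error = function(e) NULL)

helpful_participants <- function(table, item, cut) {
  lik <- table$likert
  hr <- lik[lik$item_id == item & lik$timepoint == "post_stage3", ]
  if (!nrow(hr)) return(NULL)
  hr$participant_id[hr$value >= cut]
}

trust_items <- function(table) {
  lik <- table$likert
  both <- intersect(
    unique(lik$item_id[lik$timepoint == "post_stage2"]),
    unique(lik$item_id[lik$timepoint == "post_stage3"])
  )
  sort(both)
}

likert_pairs <- function(table, item, tp_a, tp_b) {
  lik <- table$likert
  a <- lik[lik$item_id == item & lik$timepoint == tp_a, c("participant_id", "value")]
  b <- lik[lik$item_id == item & lik$timepoint == tp_b, c("participant_id", "value")]
  if (!nrow(a) || !nrow(b)) stopf("item '%s' missing at %s or %s", item, tp_a, tp_b)
  m <- merge(a, b, by = "participant_id", suffixes = c("_a", "_b"))
  if (!nrow(m)) stopf("no paired responses for item '%s'", item)
  list(a = m$value_a, b = m$value_b)
}

#' Write the battery report to disk
#'
#' Serialises the battery table as `results_report.json` (a list of test
#' objects) and `results_report.md` (a readable table grouped in the order
#' of the study's results narrative).
#'
#' @param battery Output of [run_full_battery()].
#' @param out_dir Directory for the two files.
#' @return Paths of the written files, invisibly.
#' @export
write_results_report <- function(battery, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(out_dir, "results_report.json")
  md_path <- file.path(out_dir, "results_report.md")
  payload <- list(
    n_tests = attr(battery, "n_tests") %||% sum(battery$variant == "as_reported"),
    results = battery
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  lines <- c(
    "# Statistical battery",
    "",
    sprintf("Primary tests computed: %d (raw p-values, no multiplicity correction).",
            payload$n_tests),
    "",
    "| comparison | variant | method | statistic | p | effect | n_a | n_b | note |",
    "|---|---|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s | %s | %s | %s | %s |",
            battery$comparison, battery$variant, battery$method,
            fmt_num(battery$statistic), fmt_num(battery$p_value),
            fmt_num(battery$effect), fmt_int(battery$n_a), fmt_int(battery$n_b),
            battery$note)
  )
  writeLines(lines, md_path)
  invisible(c(json = json_path, md = md_path))
}

fmt_num <- function(x) ifelse(is.na(x), "", formatC(x, format = "g", digits = 4))
fmt_int <- function(x) ifelse(is.na(x), "", as.character(x))
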