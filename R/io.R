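#' Read and write study tables as CSV
#'
#' Three UTF-8 CSV files with headers carry a study:
#'
#' * `estimates.csv`: `participant_id,image_id,stage,true_ga_weeks,`
#'   `estimate_weeks,confidence,time_sec,features` (features semicolon-joined,
#'   empty allowed);
#' * `predictions.csv`: `image_id,bin_lo_weeks,bin_hi_weeks,point_weeks`;
#' * `likert.csv`: `participant_id,timepoint,item_id,value`.
#'
#' `read_study_csv()` parses, then validates; a malformed row raises a parse
#' error naming the row, and an invariant violation raises a validation error
#' naming the rule. `write_study_csv()` is its inverse: writing then reading
#' reproduces the table.
#'
#' @param path_estimates,path_predictions,path_likert File paths. The likert
#'   path may point to a header-only file.
#' @param scheme Bin scheme to attach (default [default_bin_scheme()]).
#' @return A validated [study_table()].
#' @export
read_study_csv <- function(path_estimates, path_predictions,
                           path_likert = NULL, scheme = default_bin_scheme()) {
  for (p in c(path_estimates, path_predictions, path_likert)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  est <- read_checked(
    path_estimates,
    readr::cols(
      participant_id = readr::col_character(),
      image_id = readr::col_character(),
      stage = readr::col_integer(),
      true_ga_weeks = readr::col_double(),
      estimate_weeks = readr::col_double(),
      confidence = readr::col_integer(),
      time_sec = readr::col_double(),
      features = readr::col_character()
    )
  )
  est$features[is.na(est$features)] <- ""
  pred <- read_checked(
    path_predictions,
    readr::cols(
      image_id = readr::col_character(),
      bin_lo_weeks = readr::col_double(),
      bin_hi_weeks = readr::col_double(),
      point_weeks = readr::col_double()
    )
  )
  lik <- if (is.null(path_likert)) {
    empty_likert()
  } else {
    read_checked(
      path_likert,
      readr::cols(
        participant_id = readr::col_character(),
        timepoint = readr::col_character(),
        item_id = readr::col_character(),
        value = readr::col_integer()
      )
    )
  }
  study_table(est, pred, lik, scheme)
}

read_checked <- function(path, col_spec) {
  out <- suppressWarnings(
    readr::read_csv(path, col_types = col_spec, progress = FALSE,
                    show_col_types = FALSE)
  )
  probs <- readr::problems(out)
  if (nrow(probs)) {
    stopf("parse error in %s, row %d: expected %s, got %s",
          path, probs$row[1], probs$expected[1], probs$actual[1])
  }
  miss <- setdiff(names(col_spec$cols), names(out))
  if (length(miss)) {
    stopf("parse error in %s: missing columns %s", path, paste(miss, collapse = ", "))
  }
  out
}

#' @rdname read_study_csv
#' @param table A [study_table()].
#' @param out_dir Directory to write into (created if needed).
#' @return `write_study_csv()` returns the three file paths invisibly.
#' @export
write_study_csv <- function(table, out_dir) {
  validate_study_table(table)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  paths <- c(
    estimates = file.path(out_dir, "estimates.csv"),
    predictions = file.path(out_dir, "predictions.csv"),
    likert = file.path(out_dir, "likert.csv")
  )
  readr::write_csv(table$estimates, paths[["estimates"]], progress = FALSE)
  readr::write_csv(table$predictions, paths[["predictions"]], progress = FALSE)
  readr::write_csv(table$likert, paths[["likert"]], progress = FALSE)
  invisible(paths)
}
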