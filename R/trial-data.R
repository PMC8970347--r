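#' Column and label schema for trial tables
#'
#' Describes how a delimited text file maps onto the canonical trial layout:
#' one row per (subject, crossover replicate, condition, outcome) with a
#' pre-test and a post-test time in seconds.  The canonical dialect is
#' comma-separated UTF-8 with a header row `subject, replicate, condition,
#' outcome, pre_time, post_time`; a schema absorbs alternative column names
#' and condition labels so deposited tables with other headers can be read
#' without editing the file.
#'
#' Sprint times are stored already averaged over the repeated timing trials
#' of one test.  Where a table instead carries the individual trials,
#' `pre_trials`/`post_trials` name the columns to be averaged arithmetically
#' on ingest.
#'
#' @param subject,replicate,condition,outcome,pre_time,post_time Column names
#'   in the file for each canonical field.
#' @param intervention_label,control_label Values of the condition column that
#'   denote the intervention (e.g. `"CWI"`) and control condition.  They are
#'   normalised to `"intervention"` and `"control"` on read.
#' @param pre_trials,post_trials Optional character vectors of column names
#'   holding individual timing trials; when given they replace
#'   `pre_time`/`post_time` and are averaged row-wise.
#' @param max_replicate Largest admissible crossover replicate index
#'   (2 for the standard replicated crossover; configurable for generalised
#'   designs).
#'
#' @return An object of class `trial_schema`.
#' @export
#' @examples
#' trial_schema(condition = "recovery", intervention_label = "CWI")
trial_schema <- function(subject = "subject",
                         replicate = "replicate",
                         condition = "condition",
                         outcome = "outcome",
                         pre_time = "pre_time",
                         post_time = "post_time",
                         intervention_label = "intervention",
                         control_label = "control",
                         pre_trials = NULL,
                         post_trials = NULL,
                         max_replicate = 2L) {
  stopifnot(is.null(pre_trials) == is.null(post_trials))
  structure(
    list(
      columns = c(subject = subject, replicate = replicate,
                  condition = condition, outcome = outcome,
                  pre_time = pre_time, post_time = post_time),
      intervention_label = intervention_label,
      control_label = control_label,
      pre_trials = pre_trials,
      post_trials = post_trials,
      max_replicate = as.integer(max_replicate)
    ),
    class = "trial_schema"
  )
}

#' Read a replicated crossover trial table
#'
#' Reads a delimited text file of pre/post sprint times, applies the schema's
#' column and label mapping, and validates the result.  Row order in the file
#' is irrelevant to all downstream results.
#'
#' @param path Path to a CSV file.
#' @param schema A [trial_schema()] describing the file layout.
#'
#' @return A validated tibble with canonical columns `subject`, `replicate`,
#'   `condition` (`"intervention"`/`"control"`), `outcome`, `pre_time`,
#'   `post_time`.
#' @export
read_trial_table <- function(path, schema = trial_schema()) {
  if (!file.exists(path)) {
    abort(paste0("Trial table not found: ", path), class = "cob_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  time_cols <- if (is.null(schema$pre_trials)) {
    schema$columns[c("pre_time", "post_time")]
  } else {
    c(schema$pre_trials, schema$post_trials)
  }
  needed <- c(schema$columns[c("subject", "replicate", "condition", "outcome")],
              time_cols)
  missing_cols <- setdiff(unname(needed), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Column(s) missing from trial table: ",
                 paste(missing_cols, collapse = ", ")),
          class = "cob_schema_error", columns = missing_cols)
  }

  as_num <- function(x) suppressWarnings(as.numeric(x))
  if (is.null(schema$pre_trials)) {
    pre <- as_num(raw[[schema$columns[["pre_time"]]]])
    post <- as_num(raw[[schema$columns[["post_time"]]]])
  } else {
    pre <- rowMeans(do.call(cbind, lapply(schema$pre_trials,
                                          function(cl) as_num(raw[[cl]]))))
    post <- rowMeans(do.call(cbind, lapply(schema$post_trials,
                                           function(cl) as_num(raw[[cl]]))))
  }

  cond_raw <- raw[[schema$columns[["condition"]]]]
  cond <- dplyr::case_when(
    cond_raw == schema$intervention_label ~ "intervention",
    cond_raw == schema$control_label ~ "control",
    cond_raw %in% c("intervention", "control") ~ cond_raw,
    TRUE ~ NA_character_
  )
  bad_cond <- which(is.na(cond) & !is.na(cond_raw))
  if (length(bad_cond) > 0) {
    abort(paste0("Unrecognised condition label in row(s) ",
                 paste(head(bad_cond, 5), collapse = ", "),
                 " (expected '", schema$intervention_label, "' or '",
                 schema$control_label, "')"),
          class = "cob_validation_error", rows = bad_cond)
  }

  data <- tibble::tibble(
    subject = as.character(raw[[schema$columns[["subject"]]]]),
    replicate = as_num(raw[[schema$columns[["replicate"]]]]),
    condition = cond,
    outcome = as.character(raw[[schema$columns[["outcome"]]]]),
    pre_time = pre,
    post_time = post
  )
  validate_trial_data(data, max_replicate = schema$max_replicate)
}

#' Validate canonical trial data
#'
#' Checks the invariants of the canonical trial layout: strictly positive and
#' finite pre/post times, replicate indices within the design bound, condition
#' exactly one of the two levels, and uniqueness of the
#' (subject, replicate, condition, outcome) key.
#'
#' @param data A data frame in canonical layout (see [read_trial_table()]).
#' @param max_replicate Largest admissible replicate index.
#'
#' @return The validated data as a tibble (invisibly unchanged apart from
#'   type coercion of `replicate` to integer).
#' @export
validate_trial_data <- function(data, max_replicate = 2L) {
  data <- tibble::as_tibble(data)
  needed <- c("subject", "replicate", "condition", "outcome",
              "pre_time", "post_time")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Column(s) missing: ", paste(missing_cols, collapse = ", ")),
          class = "cob_schema_error", columns = missing_cols)
  }
  bad_time <- which(!is.finite(data$pre_time) | !is.finite(data$post_time) |
                      data$pre_time <= 0 | data$post_time <= 0)
  if (length(bad_time) > 0) {
    abort(paste0("Non-numeric, non-finite or non-positive time in row(s): ",
                 paste(head(bad_time, 10), collapse = ", ")),
          class = "cob_validation_error", rows = bad_time)
  }
  rep_num <- data$replicate
  bad_rep <- which(!is.finite(rep_num) | rep_num != round(rep_num) |
                     rep_num < 1 | rep_num > max_replicate)
  if (length(bad_rep) > 0) {
    abort(paste0("Replicate index outside 1..", max_replicate,
                 " in row(s): ", paste(head(bad_rep, 10), collapse = ", ")),
          class = "cob_validation_error", rows = bad_rep)
  }
  bad_cond <- which(!data$condition %in% c("intervention", "control"))
  if (length(bad_cond) > 0) {
    abort(paste0("Condition must be 'intervention' or 'control'; offending row(s): ",
                 paste(head(bad_cond, 10), collapse = ", ")),
          class = "cob_validation_error", rows = bad_cond)
  }
  key <- paste(data$subject, rep_num, data$condition, data$outcome, sep = "\r")
  if (anyDuplicated(key) > 0) {
    dup <- which(duplicated(key))
    abort(paste0("Duplicate (subject, replicate, condition, outcome) key in row(s): ",
                 paste(head(dup, 10), collapse = ", ")),
          class = "cob_integrity_error", rows = dup)
  }
  data$replicate <- as.integer(rep_num)
  data
}

#' Write a trial table in the canonical dialect
#'
#' Writes comma-separated UTF-8 with the canonical header.  Writing, reading
#' back and writing again is byte-stable.
#'
#' @param data Canonical trial data.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(data, path) {
  data <- validate_trial_data(data)
  readr::write_csv(data[, c("subject", "replicate", "condition", "outcome",
                            "pre_time", "post_time")], path, progress = FALSE)
  invisible(path)
}

#' Keep only subjects with a complete design
#'
#' A subject is complete when it has every (replicate x condition x outcome)
#' cell of the crossed design spanned by the dataset.  Incomplete subjects are
#' dropped (analysis of complete cases), and an exclusion report lists each
#' dropped subject together with the cells it lacks.
#'
#' @param data Canonical trial data.
#' @param n_replicates Number of crossover replicates the design requires;
#'   defaults to the largest replicate index present.
#' @param outcomes Outcomes the design requires; defaults to all outcomes
#'   present in `data`.
#'
#' @return A list with elements `data` (the filtered tibble) and `report`
#'   (tibble of excluded subjects and their missing cells, zero rows when the
#'   dataset was already complete).
#' @export
filter_complete_cases <- function(data, n_replicates = NULL, outcomes = NULL) {
  data <- validate_trial_data(data, max_replicate = max(data$replicate, 2L))
  if (is.null(n_replicates)) n_replicates <- max(data$replicate)
  if (is.null(outcomes)) outcomes <- unique(data$outcome)

  required <- tidyr::expand_grid(
    replicate = seq_len(n_replicates),
    condition = c("intervention", "control"),
    outcome = outcomes
  )
  have <- dplyr::distinct(data, .data$subject, .data$replicate,
                          .data$condition, .data$outcome)
  missing_cells <- tidyr::expand_grid(subject = unique(data$subject)) |>
    tidyr::crossing(required) |>
    dplyr::anti_join(have, by = c("subject", "replicate", "condition", "outcome"))

  excluded <- unique(missing_cells$subject)
  kept <- dplyr::filter(data, !.data$subject %in% excluded)
  if (nrow(kept) == 0) {
    abort("No subject has complete data for the requested design.",
          class = "cob_no_complete_cases")
  }
  list(
    data = kept,
    report = dplyr::arrange(missing_cells, .data$subject, .data$outcome,
                            .data$replicate, .data$condition)
  )
}

#' Write a completeness/validation report as JSON
#'
#' @param report The `report` element returned by [filter_complete_cases()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_completeness_report <- function(report, path) {
  out <- list(
    n_excluded_subjects = length(unique(report$subject)),
    excluded_subjects = unique(report$subject),
    missing_cells = report
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pre-post change scores for one outcome
#'
#' The analysis outcome is the change score d = post time - pre time for each
#' (subject, replicate, condition) cell.  Negative d means the post-test was
#' faster, i.e. better recovery of sprint performance.
#'
#' @param data Canonical trial data.
#' @param outcome Outcome label to extract.
#'
#' @return Tibble with columns `subject`, `replicate`, `condition`, `change`.
#' @export
#' @examples
#' d <- generate_trial(default_study_params(seed = 1))$data
#' pre_post_changes(d, "sprint5m")
pre_post_changes <- function(data, outcome) {
  data <- validate_trial_data(data, max_replicate = max(data$replicate, 2L))
  if (!outcome %in% data$outcome) {
    abort(paste0("Unknown outcome: ", outcome), class = "cob_lookup_error")
  }
  # canonical row order: keyed results (and all downstream floating-point
  # reductions) are invariant under permutation of the input rows
  data |>
    dplyr::filter(.data$outcome == !!outcome) |>
    dplyr::transmute(.data$subject, .data$replicate, .data$condition,
                     change = .data$post_time - .data$pre_time) |>
    dplyr::arrange(.data$subject, .data$replicate, .data$condition)
}
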