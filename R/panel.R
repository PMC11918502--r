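#' Panel datasets of repeated symptom sum-scores
#'
#' A `panel_dataset` holds a wide-format longitudinal panel: one row per
#' subject, up to `T` waves of PHQ-9 sum-scores (integers 0--27, missing
#' allowed), baseline covariates, and end-of-study binary outcomes. Missing
#' wave scores are `NA` in the score matrix and `FALSE` in the observation
#' mask; no sentinel numeric is ever used, since 0 is a valid score.
#'
#' @param y numeric matrix, subjects x waves; `NA` marks unobserved cells.
#' @param covariates data.frame of per-subject covariates (may have 0 columns).
#' @param outcomes data.frame with columns `treatment_seeking` and
#'   `diagnosis_T9` (binary, `NA` allowed), or `NULL`.
#' @param subject_id character vector of unique subject identifiers.
#' @param wave_labels character vector of wave names, default `T1..T<T>`.
#' @param score_range permitted closed score range, default `c(0, 27)`.
#'
#' @return An object of class `panel_dataset`: a list with elements `y`,
#'   `observed`, `covariates`, `outcomes`, `subject_id`, `wave_labels`,
#'   `n_subjects`, `n_waves`.
#' @export
panel_dataset <- function(y, covariates = NULL, outcomes = NULL,
                          subject_id = NULL, wave_labels = NULL,
                          score_range = c(0, 27)) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  n <- nrow(y); tt <- ncol(y)
  if (n < 1L || tt < 1L) stopf("panel needs at least one subject and one wave")
  if (is.null(subject_id)) subject_id <- as.character(seq_len(n))
  subject_id <- as.character(subject_id)
  if (length(subject_id) != n) stopf("subject_id length != number of rows")
  if (anyDuplicated(subject_id)) {
    dup <- subject_id[duplicated(subject_id)][1L]
    stopf("duplicate subject id: '%s'", dup)
  }
  if (is.null(wave_labels)) wave_labels <- paste0("T", seq_len(tt))
  if (length(wave_labels) != tt) stopf("wave_labels length != number of waves")
  observed <- !is.na(y)
  bad <- which(observed & (y < score_range[1] | y > score_range[2]),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("score out of range [%g, %g] for subject '%s' at wave %s (value %g)",
          score_range[1], score_range[2],
          subject_id[bad[1, 1]], wave_labels[bad[1, 2]], y[bad[1, , drop = FALSE]])
  }
  none <- which(rowSums(observed) == 0L)
  if (length(none) > 0L)
    stopf("subject '%s' has no observed waves", subject_id[none[1L]])
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stopf("covariates rows != number of subjects")
  } else covariates <- data.frame(row.names = seq_len(n))
  if (!is.null(outcomes)) {
    outcomes <- as.data.frame(outcomes)
    if (nrow(outcomes) != n) stopf("outcomes rows != number of subjects")
    for (nm in names(outcomes)) {
      v <- outcomes[[nm]]
      if (!all(is.na(v) | v %in% c(0, 1)))
        stopf("outcome '%s' must be binary 0/1 (NA allowed)", nm)
    }
  }
  dimnames(y) <- list(subject_id, wave_labels)
  dimnames(observed) <- dimnames(y)
  structure(list(y = y, observed = observed, covariates = covariates,
                 outcomes = outcomes, subject_id = subject_id,
                 wave_labels = wave_labels, n_subjects = n, n_waves = tt,
                 score_range = score_range),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("panel_dataset: %d subjects x %d waves (%s)\n",
              x$n_subjects, x$n_waves,
              paste(range(x$wave_labels[c(1, x$n_waves)]), collapse = "..")))
  cat(sprintf("  observed cells: %d of %d (%.1f%%)\n",
              sum(x$observed), length(x$observed),
              100 * mean(x$observed)))
  if (ncol(x$covariates)) {
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  if (!is.null(x$outcomes)) {
    cat("  outcomes:", paste(names(x$outcomes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' PHQ-9 sum score
#'
#' Sums the nine PHQ-9 item responses. Each item is scored 0 ("not at all")
#' to 3 ("nearly every day"); the sum ranges 0--27. Incomplete item sets are
#' refused rather than prorated: the downstream trajectory models operate on
#' complete sum scores, and silent single-item imputation on a 0-anchored
#' scale is a common source of bias.
#'
#' @param items numeric vector of exactly 9 item responses, each in 0..3.
#' @return Integer sum in 0..27.
#' @examples
#' phq9_sum(c(1, 0, 2, 1, 0, 0, 3, 1, 1))
#' @export
phq9_sum <- function(items) {
  if (length(items) != 9L) stopf("expected 9 items, got %d", length(items))
  if (anyNA(items)) stopf("missing item response; incomplete item sets are not scored")
  if (!all(items %in% 0:3)) stopf("item responses must be integers in 0..3")
  as.integer(sum(items))
}

# Severity band cut points: standard PHQ-9 convention (5/10/15/20).
.severity_breaks <- c(0, 5, 10, 15, 20, 28)
.severity_labels <- c("none", "mild", "moderate", "moderately_severe", "severe")

#' PHQ-9 severity band
#'
#' Maps a sum score to its conventional severity band: none `[0,4]`, mild
#' `[5,9]`, moderate `[10,14]`, moderately severe `[15,19]`, severe
#' `[20,27]`. Scores below 5 indicate no clinically relevant depression;
#' scores of 10 or more indicate at least moderate severity.
#'
#' @param score numeric vector of sum scores in 0..27.
#' @return Factor with levels `none < mild < moderate < moderately_severe <
#'   severe`.
#' @examples
#' severity_band(c(0, 4, 12, 27))
#' @export
severity_band <- function(score) {
  if (anyNA(score) || any(score < 0 | score > 27))
    stopf("scores must be in [0, 27]")
  cut(score, breaks = .severity_breaks, labels = .severity_labels,
      right = FALSE, ordered_result = TRUE)
}

# Covariate schema shared by the file reader and the generator.
.covariate_columns <- c("age_band", "sex", "living_alone", "relationship",
                        "education", "ethnic_minority", "binge_drinking",
                        "info_seeking", "physical_activity",
                        "psych_dx_baseline", "worry_job_economy")
.outcome_columns <- c("treatment_seeking", "diagnosis_T9")

.covariate_ranges <- list(
  age_band = c(1, 4), sex = c(0, 1), living_alone = c(0, 1),
  relationship = c(0, 1), education = c(1, 4), ethnic_minority = c(0, 1),
  binge_drinking = c(0, 1), info_seeking = c(0, 7),
  physical_activity = c(0, 7), psych_dx_baseline = c(0, 1),
  worry_job_economy = c(0, 6))

#' Read a wide panel table from a CSV file
#'
#' Expects a comma-separated UTF-8 table with columns `id`, `y_T1..y_T<T>`,
#' optionally the covariate columns (`age_band`, `sex`, `living_alone`,
#' `relationship`, `education`, `ethnic_minority`, `binge_drinking`,
#' `info_seeking`, `physical_activity`, `psych_dx_baseline`,
#' `worry_job_economy`) and outcome columns (`treatment_seeking`,
#' `diagnosis_T9`). Empty cells encode missing values. Validation failures
#' name the offending row and column.
#'
#' @param path path to the CSV file.
#' @return A [panel_dataset].
#' @seealso [write_panel()]
#' @export
load_panel <- function(path) {
  df <- utils::read.csv(path, na.strings = "", check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stopf("missing 'id' column in %s", path)
  wave_cols <- grep("^y_T[0-9]+$", names(df), value = TRUE)
  if (length(wave_cols) == 0L) stopf("no wave columns (y_T1, y_T2, ...) in %s", path)
  ord <- order(as.integer(sub("^y_T", "", wave_cols)))
  wave_cols <- wave_cols[ord]
  y <- as.matrix(df[, wave_cols, drop = FALSE])
  storage.mode(y) <- "double"
  # named validation before handing to the constructor, so errors carry
  # file row numbers (header = row 1)
  for (j in seq_along(wave_cols)) {
    v <- y[, j]
    bad <- which(!is.na(v) & (v < 0 | v > 27))
    if (length(bad))
      stopf("file row %d, column %s: score %g outside [0, 27]",
            bad[1L] + 1L, wave_cols[j], v[bad[1L]])
  }
  if (anyDuplicated(df$id))
    stopf("duplicate id '%s' in %s", df$id[duplicated(df$id)][1L], path)
  cov_present <- intersect(.covariate_columns, names(df))
  covariates <- if (length(cov_present)) df[, cov_present, drop = FALSE] else NULL
  if (!is.null(covariates)) {
    for (nm in cov_present) {
      rng <- .covariate_ranges[[nm]]
      v <- covariates[[nm]]
      bad <- which(!is.na(v) & (v < rng[1] | v > rng[2]))
      if (length(bad))
        stopf("file row %d, column %s: value %g outside [%g, %g]",
              bad[1L] + 1L, nm, v[bad[1L]], rng[1], rng[2])
    }
  }
  out_present <- intersect(.outcome_columns, names(df))
  outcomes <- if (length(out_present)) df[, out_present, drop = FALSE] else NULL
  panel_dataset(y, covariates = covariates, outcomes = outcomes,
                subject_id = df$id,
                wave_labels = sub("^y_", "", wave_cols))
}

#' Write a panel dataset to a CSV file
#'
#' Inverse of [load_panel()]: writes `id`, the wave columns as `y_T*`, any
#' covariates, and any outcomes; missing values become empty cells.
#'
#' @param data a [panel_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path) {
  stopifnot(inherits(data, "panel_dataset"))
  y <- data$y
  colnames(y) <- paste0("y_", data$wave_labels)
  df <- data.frame(id = data$subject_id, y, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(data$covariates)) df <- cbind(df, data$covariates)
  if (!is.null(data$outcomes)) df <- cbind(df, data$outcomes)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Attention-check filter
#'
#' Survey quality control: respondents were instructed to answer "A little"
#' (code 2 on the 1--5 response scale) to a directed item; any other response
#' fails the check and the subject is excluded.
#'
#' @param responses integer vector of response codes in 1..5.
#' @return A list with `keep` (logical vector, `TRUE` = passed) and
#'   `pass_rate` (fraction passing).
#' @export
attention_filter <- function(responses) {
  if (anyNA(responses) || !all(responses %in% 1:5))
    stopf("attention responses must be codes in 1..5")
  keep <- responses == 2L
  list(keep = keep, pass_rate = mean(keep))
}

#' Per-wave retention
#'
#' Counts subjects observed at each wave and expresses each count as a
#' fraction of the wave-1 count. Retention need not be monotone: panel
#' members may skip waves and return later.
#'
#' @param data a [panel_dataset].
#' @return data.frame with columns `wave`, `n_observed`, `fraction`.
#' @export
wave_retention <- function(data) {
  stopifnot(inherits(data, "panel_dataset"))
  counts <- colSums(data$observed)
  data.frame(wave = data$wave_labels, n_observed = as.integer(counts),
             fraction = counts / counts[1L], row.names = NULL)
}
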