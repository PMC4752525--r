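#' @keywords internal
"_PACKAGE"

# Canonical long-format columns.  One row per at-risk interval (gap); the
# six covariates are time-fixed and repeated on every row of a subject.
GAP_COLS <- c("subject_id", "rank", "gap_weeks", "event")
COVARIATE_COLS <- c("age_onset", "gender", "marital", "mode_onset",
                    "head_injury", "family_history")
BINARY_COVARIATES <- setdiff(COVARIATE_COLS, "age_onset")

# Reference codings: indicator = 1 for the first-named level.
COVARIATE_LEVELS <- list(
  gender         = c(`1` = "Male",    `0` = "Female"),
  marital        = c(`1` = "Single",  `0` = "Married"),
  mode_onset     = c(`1` = "Gradual", `0` = "Sudden"),
  head_injury    = c(`1` = "Yes",     `0` = "No"),
  family_history = c(`1` = "Yes",     `0` = "No")
)

#' Construct a recurrent gap-time dataset
#'
#' A `gap_dataset` is a long-format data frame with one row per at-risk
#' interval: columns `subject_id`, `rank` (event order, 1 = first gap),
#' `gap_weeks` (positive gap length in weeks), `event` (1 = relapse
#' observed, 0 = right-censored) and the six time-fixed covariates
#' `age_onset` (years, raw scale), `gender` (1 = male), `marital`
#' (1 = single), `mode_onset` (1 = gradual), `head_injury` (1 = yes),
#' `family_history` (1 = yes).  Rows are normalised to
#' `(subject_id, rank)` order.
#'
#' Validity rules: positive gap times; within-subject ranks consecutive
#' from 1; at most one censored record per subject and only at the last
#' rank; at least one observed event per subject (the study inclusion
#' rule); covariates constant within subject; indicators in \{0, 1\};
#' age positive and finite.
#'
#' @param data data frame holding all required columns.
#' @return A validated `gap_dataset` (a data frame).
#' @seealso [validate_gap_data()] for a non-throwing validity report,
#'   [read_gap_data()] / [write_gap_data()] for delimited-text I/O.
#' @examples
#' toy <- data.frame(
#'   subject_id = c("A", "A", "B"), rank = c(1, 2, 1),
#'   gap_weeks = c(12, 30, 55), event = c(1, 1, 1),
#'   age_onset = c(20, 20, 31), gender = c(1, 1, 0), marital = c(1, 1, 0),
#'   mode_onset = c(0, 0, 1), head_injury = c(0, 0, 1),
#'   family_history = c(0, 0, 0))
#' ds <- gap_dataset(toy)
#' n_subjects(ds)
#' @export
gap_dataset <- function(data) {
  data <- as.data.frame(data)
  required <- c(GAP_COLS, COVARIATE_COLS)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("gap_dataset: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[, required, drop = FALSE]
  data$subject_id <- as.character(data$subject_id)
  for (col in setdiff(required, "subject_id")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  data <- data[order(data$subject_id, data$rank), , drop = FALSE]
  rownames(data) <- NULL
  report <- validate_gap_data(data)
  if (nrow(report) > 0) {
    msg <- paste(sprintf("[%s] subject %s: %s", report$rule,
                         report$subject_id, report$message),
                 collapse = "\n  ")
    stop("gap_dataset: invalid recurrent-event data:\n  ", msg,
         call. = FALSE)
  }
  class(data) <- c("gap_dataset", "data.frame")
  data
}

#' Validate a recurrent gap-time table
#'
#' Checks every dataset invariant and reports all violations rather than
#' stopping at the first.  Used by [gap_dataset()], and exported so
#' pipelines can report problems in bulk before fitting.
#'
#' @param data data frame with the `gap_dataset` columns.
#' @return data frame with columns `subject_id`, `rule`, `message`;
#'   zero rows if and only if the data are valid.  Rule names:
#'   `nonpositive-gap`, `bad-indicator`, `bad-age`, `missing-value`,
#'   `rank-sequence`, `censored-not-last`, `no-observed-event`,
#'   `covariate-not-fixed`.
#' @export
validate_gap_data <- function(data) {
  data <- as.data.frame(data)
  problems <- list()
  note <- function(subject, rule, message) {
    problems[[length(problems) + 1]] <<- data.frame(
      subject_id = as.character(subject), rule = rule, message = message,
      stringsAsFactors = FALSE)
  }

  if (nrow(data) == 0) {
    return(data.frame(subject_id = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  }

  num_cols <- c("rank", "gap_weeks", "event", COVARIATE_COLS)
  na_rows <- !stats::complete.cases(data[, num_cols, drop = FALSE])
  for (s in unique(data$subject_id[na_rows])) {
    note(s, "missing-value", "missing value in gap or covariate fields")
  }
  ok <- !na_rows

  bad_gap <- ok & data$gap_weeks <= 0
  for (s in unique(data$subject_id[bad_gap])) {
    note(s, "nonpositive-gap",
         sprintf("gap_weeks must be > 0 (rows: %s)",
                 paste(which(bad_gap & data$subject_id == s), collapse = ",")))
  }

  ind_cols <- c("event", BINARY_COVARIATES)
  for (col in ind_cols) {
    bad <- ok & !(data[[col]] %in% c(0, 1))
    for (s in unique(data$subject_id[bad])) {
      note(s, "bad-indicator", sprintf("%s must be 0 or 1", col))
    }
  }

  bad_age <- ok & (!is.finite(data$age_onset) | data$age_onset <= 0)
  for (s in unique(data$subject_id[bad_age])) {
    note(s, "bad-age", "age_onset must be finite and positive")
  }

  # structural checks on a (subject, rank)-sorted copy, restricted to
  # subjects with no missing fields (already reported above); adjacency
  # on the sorted rows keeps this linear in the number of records
  na_subjects <- unique(data$subject_id[na_rows])
  sorted <- data[!(data$subject_id %in% na_subjects), , drop = FALSE]
  sorted <- sorted[order(sorted$subject_id, sorted$rank), , drop = FALSE]
  if (nrow(sorted) > 0) {
    id <- sorted$subject_id
    first <- !duplicated(id)
    last <- !duplicated(id, fromLast = TRUE)
    n <- nrow(sorted)
    same_subj <- !first[-1]

    bad_rank <- unique(c(
      id[first & sorted$rank != 1],
      id[-1][same_subj & diff(sorted$rank) != 1]))
    for (s in bad_rank) {
      note(s, "rank-sequence", "ranks must be consecutive 1..K")
    }

    for (s in unique(id[sorted$event == 0 & !last])) {
      note(s, "censored-not-last",
           "at most one censored record, and only at the maximal rank")
    }

    ev <- rowsum(sorted$event, id)
    for (s in rownames(ev)[ev[, 1] == 0]) {
      note(s, "no-observed-event",
           "every subject must contribute at least one observed relapse")
    }

    for (col in COVARIATE_COLS) {
      v <- sorted[[col]]
      varies <- unique(id[-1][same_subj & v[-1] != v[-n]])
      for (s in varies) {
        note(s, "covariate-not-fixed",
             sprintf("%s varies across the subject's gaps", col))
      }
    }
  }

  if (length(problems) == 0) {
    data.frame(subject_id = character(), rule = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, problems)
  }
}

#' @export
print.gap_dataset <- function(x, ...) {
  cat(sprintf("Recurrent gap-time dataset: %d subjects, %d gaps (%d events, %d censored)\n",
              n_subjects(x), nrow(x), sum(x$event == 1), sum(x$event == 0)))
  NextMethod()
  invisible(x)
}

#' Number of subjects in a gap dataset
#' @param ds a `gap_dataset`.
#' @return integer count of distinct subjects.
#' @export
n_subjects <- function(ds) length(unique(ds$subject_id))

#' Column dialect for gap-time text files
#'
#' Describes how a delimited file maps onto the canonical columns.  The
#' default dialect is comma-separated with the canonical header
#' `subject_id,rank,gap_weeks,event,age_onset,gender,marital,mode_onset,head_injury,family_history`.
#'
#' @param sep field separator.
#' @param columns named character vector mapping canonical names to the
#'   column names used in the file.
#' @return a `gap_dialect` list.
#' @export
gap_dialect <- function(sep = ",",
                        columns = stats::setNames(
                          c(GAP_COLS, COVARIATE_COLS),
                          c(GAP_COLS, COVARIATE_COLS))) {
  required <- c(GAP_COLS, COVARIATE_COLS)
  if (!all(required %in% names(columns))) {
    stop("gap_dialect: 'columns' must map every canonical column",
         call. = FALSE)
  }
  structure(list(sep = sep, columns = columns), class = "gap_dialect")
}

#' Read a long-format gap-time dataset from delimited text
#'
#' Subjects with any missing covariate value are excluded with a warning
#' (no imputation is attempted), mirroring complete-case handling of
#' medical-record extracts.
#'
#' @param path file to read.
#' @param dialect a [gap_dialect()] describing separator and column names.
#' @return a validated [gap_dataset()].
#' @export
read_gap_data <- function(path, dialect = gap_dialect()) {
  if (!file.exists(path)) {
    stop("read_gap_data: file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(dialect$columns), names(raw))
  if (length(missing_cols) > 0) {
    stop("read_gap_data: file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  canonical <- names(dialect$columns)
  out <- raw[, unname(dialect$columns), drop = FALSE]
  names(out) <- canonical

  cov_na <- !stats::complete.cases(out[, COVARIATE_COLS, drop = FALSE])
  if (any(cov_na)) {
    dropped <- unique(out$subject_id[cov_na])
    warning(sprintf(
      "read_gap_data: excluding %d subject(s) with missing covariates: %s",
      length(dropped), paste(dropped, collapse = ", ")), call. = FALSE)
    out <- out[!(out$subject_id %in% dropped), , drop = FALSE]
  }
  gap_dataset(out)
}

#' Write a gap-time dataset as delimited text
#'
#' Numeric fields are written with 17 significant digits so that
#' `read_gap_data(write_gap_data(ds))` reproduces `ds` exactly.
#'
#' @param ds a `gap_dataset`.
#' @param path output file.
#' @param dialect a [gap_dialect()].
#' @return `path`, invisibly.
#' @export
write_gap_data <- function(ds, path, dialect = gap_dialect()) {
  stopifnot(inherits(ds, "gap_dataset") || is.data.frame(ds))
  canonical <- c(GAP_COLS, COVARIATE_COLS)
  out <- as.data.frame(ds)[, canonical, drop = FALSE]
  for (col in setdiff(canonical, "subject_id")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  names(out) <- unname(dialect$columns[canonical])
  utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Build gap times from one subject's admission history
#'
#' Converts an onset week, hospital stays and a follow-up horizon into
#' at-risk gap records.  The first gap runs from illness onset to the
#' first admission; gap `k` (k >= 2) runs from discharge `k - 1` to
#' admission `k`; in-hospital time never enters any gap.  If follow-up
#' extends past the last discharge, the remaining time is a final
#' right-censored record.
#'
#' @param subject_id identifier for the subject.
#' @param onset_week week of illness onset (time origin).
#' @param admissions,discharges equal-length vectors of admission and
#'   discharge weeks, in increasing, non-overlapping order.
#' @param followup_end_week end of observation; must be at or after the
#'   last discharge.
#' @return data frame with columns `subject_id`, `rank`, `gap_weeks`,
#'   `event` (one row per gap).
#' @examples
#' build_gap_times("A", 0, admissions = c(10, 20), discharges = c(14, 25),
#'                 followup_end_week = 40)
#' @export
build_gap_times <- function(subject_id, onset_week, admissions, discharges,
                            followup_end_week) {
  if (length(admissions) != length(discharges)) {
    stop("build_gap_times: admissions and discharges differ in length",
         call. = FALSE)
  }
  if (length(admissions) == 0) {
    stop("build_gap_times: at least one hospital stay is required",
         call. = FALSE)
  }
  if (onset_week > admissions[1]) {
    stop("build_gap_times: onset_week must not exceed the first admission",
         call. = FALSE)
  }
  if (any(admissions >= discharges)) {
    stop("build_gap_times: each admission must precede its discharge",
         call. = FALSE)
  }
  if (length(admissions) > 1 &&
      any(admissions[-1] < discharges[-length(discharges)])) {
    stop("build_gap_times: stays must be non-overlapping and increasing",
         call. = FALSE)
  }
  if (followup_end_week < discharges[length(discharges)]) {
    stop("build_gap_times: followup_end_week precedes the last discharge",
         call. = FALSE)
  }
  at_risk_start <- c(onset_week, discharges[-length(discharges)])
  gaps <- admissions - at_risk_start
  if (any(gaps <= 0)) {
    stop("build_gap_times: zero-length gap (readmission at discharge week) ",
         "for subject ", subject_id, call. = FALSE)
  }
  ranks <- seq_along(gaps)
  events <- rep(1, length(gaps))
  tail_time <- followup_end_week - discharges[length(discharges)]
  if (tail_time > 0) {
    gaps <- c(gaps, tail_time)
    ranks <- c(ranks, length(ranks) + 1)
    events <- c(events, 0)
  }
  data.frame(subject_id = as.character(subject_id), rank = ranks,
             gap_weeks = as.numeric(gaps), event = events,
             stringsAsFactors = FALSE)
}

#' Cross-tabulate per-subject relapse counts by covariate strata
#'
#' Counts observed relapses (records with `event == 1`) per subject, bins
#' them as 1, 2, 3, 4, 5+ and cross-tabulates against one or more binary
#' covariate strata with within-stratum percentages.
#'
#' @param ds a `gap_dataset`.
#' @param strata character vector of binary covariate names, e.g.
#'   `c("family_history", "gender")`.
#' @return data frame with one row per stratum x relapse-count bin:
#'   stratum label columns, `relapses`, `n`, `pct` (percent within the
#'   stratum; `NaN` for empty strata).
#' @export
relapse_frequency_table <- function(ds,
                                    strata = c("family_history", "gender")) {
  unknown <- setdiff(strata, BINARY_COVARIATES)
  if (length(unknown) > 0) {
    stop("relapse_frequency_table: unknown stratum covariate(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bins <- c("1", "2", "3", "4", "5+")
  per_subject <- unique(as.data.frame(ds)[, c("subject_id", strata),
                                          drop = FALSE])
  if (nrow(per_subject) == 0) {
    out <- data.frame(matrix(character(), 0, length(strata)))
    names(out) <- strata
    out$relapses <- character()
    out$n <- integer()
    out$pct <- numeric()
    return(out)
  }
  counts <- tapply(ds$event, ds$subject_id, sum)
  per_subject$n_relapses <- as.numeric(counts[per_subject$subject_id])
  per_subject$bin <- factor(
    ifelse(per_subject$n_relapses >= 5, "5+",
           as.character(per_subject$n_relapses)),
    levels = bins)

  label <- function(col, v) {
    lv <- COVARIATE_LEVELS[[col]]
    unname(lv[as.character(v)])
  }
  stratum_levels <- lapply(strata, function(col)
    unname(COVARIATE_LEVELS[[col]]))
  grid <- expand.grid(c(stratum_levels, list(bins)),
                      stringsAsFactors = FALSE)
  names(grid) <- c(strata, "relapses")

  key_of <- function(df) do.call(paste, c(df[strata], list(sep = "\r")))
  per_subject_labels <- per_subject
  for (col in strata) {
    per_subject_labels[[col]] <- label(col, per_subject[[col]])
  }
  tab_key <- paste(key_of(per_subject_labels),
                   as.character(per_subject_labels$bin), sep = "\r")
  grid_key <- paste(key_of(grid), grid$relapses, sep = "\r")
  grid$n <- as.integer(table(factor(tab_key, levels = grid_key)))
  stratum_totals <- tapply(grid$n, key_of(grid), sum)
  grid$pct <- 100 * grid$n / as.numeric(stratum_totals[key_of(grid)])
  grid[order(key_of(grid), match(grid$relapses, bins)), , drop = FALSE]
}
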