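# standard column names a cohort table may carry; numeric ones are coerced
# (unparseable values become NA)
cohort_numeric_cols <- c(
  "survival_months", "event", "n_pln", "n_nln", "ajcc_n", "age",
  "tumor_size", "met_bone", "met_brain", "met_liver", "met_lung",
  "surgery_flag", "cause_specific"
)
cohort_character_cols <- c(
  "id", "sex", "race", "tumor_site", "grade", "ajcc_group", "radiation_sequence"
)

#' Read a patient-level case listing into a cohort tibble
#'
#' Ingests a delimited case-listing export (SEER*Stat style: one row per
#' patient, header row, arbitrary column names). Columns are renamed to the
#' package's standard schema via `field_map`; numeric fields that fail to
#' parse, and values in `na_codes`, become missing. Row order is preserved.
#'
#' @param path Path to a delimited text file with a header row.
#' @param field_map Optional named character vector mapping standard names to
#'   file column names, e.g. `c(survival_months = "Survival months")`.
#'   Columns already bearing standard names need no mapping.
#' @param delim Field delimiter (default comma).
#' @param na_codes Strings treated as missing (SEER "unknown" codes can be
#'   appended here).
#' @return A cohort tibble; its `provenance` attribute records the source
#'   path. Records without an `id` column are numbered by row.
#' @export
read_cohort <- function(path, field_map = NULL, delim = ",",
                        na_codes = c("", "NA", "Unknown", "unknown")) {
  assert_that(is.character(path) && length(path) == 1 && file.exists(path),
              sprintf("file not found: %s", path))
  data <- readr::read_delim(
    path, delim = delim, na = na_codes, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  assert_that(nrow(data) > 0, sprintf("empty input: %s contains no records", path))

  if (!is.null(field_map)) {
    assert_that(!is.null(names(field_map)) && all(nzchar(names(field_map))),
                "field_map must be a named character vector (standard = file column)")
    missing <- setdiff(unname(field_map), names(data))
    assert_that(length(missing) == 0,
                sprintf("schema error: mapped column(s) not in file: %s",
                        paste(missing, collapse = ", ")))
    data <- dplyr::rename(data, !!!setNames(unname(field_map), names(field_map)))
  }

  for (col in intersect(cohort_numeric_cols, names(data))) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  }
  if (!"id" %in% names(data)) {
    data$id <- sprintf("R%06d", seq_len(nrow(data)))
  }
  for (col in c("n_pln", "n_nln")) {
    if (col %in% names(data)) {
      bad <- !is.na(data[[col]]) & (data[[col]] < 0 | !is_whole(data[[col]]))
      data[[col]][bad] <- NA_real_
    }
  }
  attr(data, "provenance") <- path
  data
}

#' Apply the cohort inclusion criteria
#'
#' Retains patients who (1) underwent radical lymphadenectomy
#' (`surgery_flag == 1`), (2) have both regional node counts recorded, and
#' (3) if deceased, died of the disease under study (`cause_specific == 1`).
#' A record failing several criteria is tallied under the first failing one,
#' in that order. Criteria whose columns are absent from the table are not
#' applied.
#'
#' @param cohort A cohort tibble.
#' @return A list with `cohort` (retained records, original order),
#'   `exclusions` (tibble of `criterion`, `n_excluded`), `n_input`, and
#'   `n_retained`. Always `n_retained + sum(n_excluded) == n_input`.
#' @export
apply_inclusion_criteria <- function(cohort) {
  assert_that(is.data.frame(cohort), "cohort must be a data frame")
  n <- nrow(cohort)
  has <- function(col) col %in% names(cohort)
  fail_surgery <- if (has("surgery_flag")) {
    !(cohort$surgery_flag %in% 1)
  } else rep(FALSE, n)
  fail_ln <- if (has("n_pln") && has("n_nln")) {
    is.na(cohort$n_pln) | is.na(cohort$n_nln)
  } else rep(FALSE, n)
  fail_cause <- if (has("event") && has("cause_specific")) {
    cohort$event %in% 1 & !(cohort$cause_specific %in% 1)
  } else rep(FALSE, n)

  reason <- rep(NA_character_, n)
  reason[fail_cause] <- "other_cause"
  reason[fail_ln] <- "unclear_ln"      # earlier criteria overwrite later ones
  reason[fail_surgery] <- "no_surgery"

  tally <- tibble::tibble(
    criterion = c("no_surgery", "unclear_ln", "other_cause"),
    n_excluded = c(sum(reason == "no_surgery", na.rm = TRUE),
                   sum(reason == "unclear_ln", na.rm = TRUE),
                   sum(reason == "other_cause", na.rm = TRUE))
  )
  list(
    cohort = cohort[is.na(reason), , drop = FALSE],
    exclusions = tally,
    n_input = n,
    n_retained = sum(is.na(reason))
  )
}
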