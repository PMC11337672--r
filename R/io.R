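# Readers and writers for the four study tables: delimited text (CSV) with a
# header row and ISO-8601 dates. Every column is type-checked up front; a
# violation aborts with the file, row and column named, before any
# computation touches the data.

parse_column <- function(x, type, file, column, required = TRUE) {
  blank <- is.na(x) | x == ""
  out <- switch(type,
    integer = suppressWarnings(as.integer(x)),
    numeric = suppressWarnings(as.numeric(x)),
    date = as.Date(x, format = "%Y-%m-%d"),
    character = as.character(x)
  )
  bad <- !blank & is.na(out)
  if (type == "character") bad <- rep(FALSE, length(out))
  if (any(bad)) {
    stop(sprintf(
      "validation error in %s, row %d, column '%s': cannot parse '%s' as %s",
      file, which(bad)[1], column, x[which(bad)[1]], type
    ), call. = FALSE)
  }
  if (required && any(blank)) {
    stop(sprintf(
      "validation error in %s, row %d, column '%s': missing value",
      file, which(blank)[1], column
    ), call. = FALSE)
  }
  out
}

read_study_table <- function(path, schema, optional = character(0)) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(setdiff(names(schema), optional), names(raw))
  if (length(missing_cols)) {
    stop(sprintf(
      "validation error in %s: missing column(s) %s",
      path, paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  out <- tibble::as_tibble(purrr::imap(
    schema[names(schema) %in% names(raw)],
    function(spec, col) {
      parse_column(raw[[col]], spec$type, path, col, required = spec$required)
    }
  ))
  out
}

#' Read the women table
#'
#' Columns: `woman_id` (integer), `birth_date` (ISO date),
#' `medea_quintile` (integer 1-5, may be missing), `rurality`
#' (`urban`/`rural`).
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_women_table <- function(path) {
  out <- read_study_table(path, list(
    woman_id = list(type = "integer", required = TRUE),
    birth_date = list(type = "date", required = TRUE),
    medea_quintile = list(type = "integer", required = FALSE),
    rurality = list(type = "character", required = TRUE)
  ))
  bad <- !out$rurality %in% c("urban", "rural")
  if (any(bad)) {
    stop(sprintf(
      "validation error in %s, row %d, column 'rurality': '%s'",
      path, which(bad)[1], out$rurality[which(bad)[1]]
    ), call. = FALSE)
  }
  out
}

#' Read the pregnancy-episodes table
#'
#' Columns: `episode_id`, `woman_id` (integers), `lmp_date`, `end_date`
#' (ISO dates, onset strictly before end), `outcome_code`,
#' `gestational_weeks` (numeric, derived as `(end - lmp)/7` when absent).
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_episodes_table <- function(path) {
  out <- read_study_table(
    path,
    list(
      episode_id = list(type = "integer", required = TRUE),
      woman_id = list(type = "integer", required = TRUE),
      lmp_date = list(type = "date", required = TRUE),
      end_date = list(type = "date", required = TRUE),
      outcome_code = list(type = "character", required = TRUE),
      gestational_weeks = list(type = "numeric", required = FALSE)
    ),
    optional = "gestational_weeks"
  )
  bad <- out$lmp_date >= out$end_date
  if (any(bad)) {
    stop(sprintf(
      "validation error in %s, row %d: lmp_date is not before end_date",
      path, which(bad)[1]
    ), call. = FALSE)
  }
  if (!"gestational_weeks" %in% names(out)) {
    out$gestational_weeks <- as.numeric(out$end_date - out$lmp_date) / 7
  }
  out
}

#' Read the prescriptions table
#'
#' Columns: `woman_id` (integer), `atc_code` (ATC syntax), `start_date`,
#' `end_date` (ISO dates, closed range).
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_prescriptions_table <- function(path) {
  out <- read_study_table(path, list(
    woman_id = list(type = "integer", required = TRUE),
    atc_code = list(type = "character", required = TRUE),
    start_date = list(type = "date", required = TRUE),
    end_date = list(type = "date", required = TRUE)
  ))
  bad <- !grepl("^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$", out$atc_code)
  if (any(bad)) {
    stop(sprintf(
      "validation error in %s, row %d, column 'atc_code': '%s'",
      path, which(bad)[1], out$atc_code[which(bad)[1]]
    ), call. = FALSE)
  }
  bad <- out$start_date > out$end_date
  if (any(bad)) {
    stop(sprintf(
      "validation error in %s, row %d: start_date after end_date",
      path, which(bad)[1]
    ), call. = FALSE)
  }
  out
}

#' Read the diagnoses table
#'
#' Columns: `woman_id` (integer), `icd10_code`, `onset_date` (ISO date),
#' `end_date` (ISO date, blank = open-ended).
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_diagnoses_table <- function(path) {
  out <- read_study_table(path, list(
    woman_id = list(type = "integer", required = TRUE),
    icd10_code = list(type = "character", required = TRUE),
    onset_date = list(type = "date", required = TRUE),
    end_date = list(type = "date", required = FALSE)
  ))
  bad <- !is.na(out$end_date) & out$onset_date > out$end_date
  if (any(bad)) {
    stop(sprintf(
      "validation error in %s, row %d: onset_date after end_date",
      path, which(bad)[1]
    ), call. = FALSE)
  }
  out
}

#' Write a study table as CSV with ISO-8601 dates
#'
#' @param x Tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}
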