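#' Do two closed date ranges share at least one day?
#'
#' Exposure classification uses the 1-day overlap rule: a window counts as
#' exposed if it shares at least one calendar day with an active
#' prescription. For closed ranges this is `max(starts) <= min(ends)`.
#' All four arguments recycle, so the function is fully vectorised.
#'
#' @param start1,end1 First range (Date).
#' @param start2,end2 Second range (Date).
#' @return Logical vector.
#' @export
ranges_overlap <- function(start1, end1, start2, end2) {
  pmax(start1, start2) <= pmin(end1, end2)
}

atc_matches <- function(atc_code, atc_prefix) {
  startsWith(as.character(atc_code), atc_prefix)
}

#' Prevalent (current-user) exposure of one interval
#'
#' An interval is prevalent-exposed to a drug when any prescription whose ATC
#' code starts with `atc_prefix` overlaps it by at least one day.
#'
#' @param prescriptions Tibble with `atc_code`, `start_date`, `end_date`,
#'   already restricted to the interval's woman.
#' @param interval One-row tibble (or list) with `start_date`, `end_date`.
#' @param atc_prefix ATC prefix, e.g. `"N03AG01"` for valproate or `"N03AG"`
#'   for the chemical subgroup.
#' @return Logical flag.
#' @export
classify_prevalent <- function(prescriptions, interval, atc_prefix) {
  rx <- prescriptions[atc_matches(prescriptions$atc_code, atc_prefix), , drop = FALSE]
  nrow(rx) > 0 && any(ranges_overlap(
    rx$start_date, rx$end_date,
    interval$start_date, interval$end_date
  ))
}

#' Incident (new-user) exposure of one interval under a washout
#'
#' A woman is washout-eligible for an interval when (i) the interval starts
#' at least `washout_days` after the earliest observable date, so the washout
#' period is fully verifiable in the data, and (ii) no matching prescription
#' is active on any day of the `washout_days` preceding the interval start
#' (activity, not merely initiation: a long-running prescription started two
#' years earlier still blocks eligibility). The interval is incident when it
#' is washout-eligible and a matching prescription starts inside it.
#'
#' @inheritParams classify_prevalent
#' @param washout_days Drug-free look-back length in days (default 365).
#' @param observation_start Earliest date observable in the data.
#' @return List with logical `incident` and `washout_eligible`.
#' @export
classify_incident <- function(prescriptions, interval, atc_prefix,
                              washout_days = 365L, observation_start) {
  if (washout_days <= 0) stop("'washout_days' must be positive", call. = FALSE)
  observation_start <- as_date_checked(observation_start, "observation_start")
  rx <- prescriptions[atc_matches(prescriptions$atc_code, atc_prefix), , drop = FALSE]
  ws <- interval$start_date
  in_window <- as.numeric(ws - observation_start) >= washout_days
  clean <- !(nrow(rx) > 0 && any(ranges_overlap(
    rx$start_date, rx$end_date, ws - washout_days, ws - 1L
  )))
  eligible <- in_window && clean
  incident <- eligible && nrow(rx) > 0 &&
    any(rx$start_date >= ws & rx$start_date <= interval$end_date)
  list(incident = incident, washout_eligible = eligible)
}

#' Was a pregnancy exposed at any point during gestation?
#'
#' @param prescriptions Prescription tibble with `woman_id`.
#' @param episodes Episode tibble with `episode_id`, `woman_id`, `lmp_date`,
#'   `end_date`.
#' @param atc_prefix ATC prefix of the drug of interest.
#' @return Logical vector, one flag per episode row: any matching
#'   prescription overlapping `[lmp_date, end_date]`.
#' @export
episode_exposed <- function(prescriptions, episodes, atc_prefix) {
  rx <- prescriptions[atc_matches(prescriptions$atc_code, atc_prefix), , drop = FALSE]
  if (!nrow(episodes)) {
    return(logical(0))
  }
  if (!nrow(rx)) {
    return(rep(FALSE, nrow(episodes)))
  }
  hits <- dplyr::inner_join(
    dplyr::select(episodes, dplyr::all_of(c("episode_id", "woman_id", "lmp_date", "end_date"))),
    dplyr::select(rx, dplyr::all_of(c("woman_id", "start_date", "end_date"))),
    by = "woman_id", suffix = c("", ".rx"), relationship = "many-to-many"
  )
  hits <- dplyr::filter(hits, ranges_overlap(
    .data$start_date, .data$end_date.rx, .data$lmp_date, .data$end_date
  ))
  episodes$episode_id %in% hits$episode_id
}

#' Classify every (interval, drug) pair as prevalent and/or incident
#'
#' Vectorised workhorse applying the current-user overlap rule and the
#' washout-based new-user rule to a whole interval table at once. Results do
#' not depend on the ordering of prescription rows.
#'
#' @param intervals Interval tibble from [build_intervals()] (optionally
#'   filtered by [filter_observable_intervals()]).
#' @param episodes Episode tibble linking `episode_id` to `woman_id`.
#' @param prescriptions Prescription tibble (`woman_id`, `atc_code`,
#'   `start_date`, `end_date`).
#' @param atc_prefix ATC prefix of the drug of interest.
#' @param washout_days Drug-free look-back in days.
#' @param observation_start Earliest observable date, anchoring washout
#'   verifiability.
#' @return Tibble with one row per interval: `episode_id`, `label`,
#'   `atc_code` (the prefix), `prevalent`, `incident`, `washout_eligible`.
#'   Satisfies `incident => prevalent` and `incident => washout_eligible`.
#' @export
classify_exposure <- function(intervals, episodes, prescriptions, atc_prefix,
                              washout_days = 365L, observation_start) {
  if (washout_days <= 0) stop("'washout_days' must be positive", call. = FALSE)
  observation_start <- as_date_checked(observation_start, "observation_start")
  out <- dplyr::left_join(
    dplyr::select(intervals, dplyr::all_of(c("episode_id", "label", "start_date", "end_date"))),
    dplyr::select(episodes, dplyr::all_of(c("episode_id", "woman_id"))),
    by = "episode_id"
  )
  if (anyNA(out$woman_id)) {
    stop("some intervals reference an episode_id absent from 'episodes'", call. = FALSE)
  }
  rx <- prescriptions[atc_matches(prescriptions$atc_code, atc_prefix), , drop = FALSE]
  out$row_id <- seq_len(nrow(out))
  if (nrow(rx)) {
    pairs <- dplyr::inner_join(
      dplyr::select(out, dplyr::all_of(c("row_id", "woman_id", "start_date", "end_date"))),
      dplyr::select(rx, dplyr::all_of(c("woman_id", "start_date", "end_date"))),
      by = "woman_id", suffix = c("", ".rx"), relationship = "many-to-many"
    )
    flags <- pairs |>
      dplyr::group_by(.data$row_id) |>
      dplyr::summarise(
        prevalent = any(ranges_overlap(
          .data$start_date.rx, .data$end_date.rx, .data$start_date, .data$end_date
        )),
        washout_clean = !any(ranges_overlap(
          .data$start_date.rx, .data$end_date.rx,
          .data$start_date - washout_days, .data$start_date - 1L
        )),
        starts_inside = any(.data$start_date.rx >= .data$start_date &
          .data$start_date.rx <= .data$end_date),
        .groups = "drop"
      )
    out <- dplyr::left_join(out, flags, by = "row_id")
    out$prevalent[is.na(out$prevalent)] <- FALSE
    out$washout_clean[is.na(out$washout_clean)] <- TRUE
    out$starts_inside[is.na(out$starts_inside)] <- FALSE
  } else {
    out$prevalent <- FALSE
    out$washout_clean <- TRUE
    out$starts_inside <- FALSE
  }
  out$washout_eligible <- out$washout_clean &
    as.numeric(out$start_date - observation_start) >= washout_days
  out$incident <- out$washout_eligible & out$starts_inside
  tibble::as_tibble(out[order(out$row_id), c(
    "episode_id", "label", "prevalent", "incident", "washout_eligible"
  )]) |>
    dplyr::mutate(atc_code = atc_prefix, .after = "label")
}
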