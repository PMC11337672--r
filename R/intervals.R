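#' Labels of the six pregnancy exposure windows
#'
#' In chronological order: the 90 days before conception (`PRE90`), the three
#' trimesters (`T1`, `T2`, `T3`), and the two post-partum phases of 3 months
#' (`POST90`) and a further 3 months (`POST180`, days 91-180 after the end of
#' pregnancy).
#'
#' @return Character vector of length six.
#' @export
interval_labels <- function() {
  c("PRE90", "T1", "T2", "T3", "POST90", "POST180")
}

#' Keep only pregnancy episodes fully dated inside the observation window
#'
#' An episode is complete when both its onset (last menstrual period, LMP)
#' and its end date fall inside the study window; episodes straddling either
#' boundary are removed. Row order is preserved.
#'
#' @param episodes Tibble with at least `lmp_date` and `end_date` (Date).
#' @param window_start,window_end Observation window bounds (closed).
#' @return The filtered episode tibble.
#' @export
filter_complete_episodes <- function(episodes, window_start, window_end) {
  window_start <- as_date_checked(window_start, "window_start")
  window_end <- as_date_checked(window_end, "window_end")
  if (window_start >= window_end) {
    stop("'window_start' must precede 'window_end'", call. = FALSE)
  }
  dplyr::filter(
    episodes,
    .data$lmp_date >= window_start, .data$end_date <= window_end
  )
}

check_episodes <- function(episodes, max_weeks = 45) {
  bad <- episodes$lmp_date >= episodes$end_date
  if (any(bad)) {
    stop(sprintf(
      "episode(s) %s have end_date on or before lmp_date",
      paste(head(which(bad), 5), collapse = ", ")
    ), call. = FALSE)
  }
  weeks <- as.numeric(episodes$end_date - episodes$lmp_date) / 7
  if (any(weeks > max_weeks)) {
    stop(sprintf(
      "episode(s) %s exceed %s gestational weeks",
      paste(head(which(weeks > max_weeks), 5), collapse = ", "), max_weeks
    ), call. = FALSE)
  }
  invisible(episodes)
}

#' Carve pregnancy episodes into labelled exposure windows
#'
#' Each episode yields up to six closed date intervals: `PRE90 = [lmp-90,
#' lmp-1]`, `T1 = [lmp, min(lmp + t1_end_day, end)]`, `T2` and `T3` only when
#' gestation extends beyond the respective cut-off, `POST90 = [end+1,
#' end+margin]` and `POST180 = [end+margin+1, end+2*margin]`. Consecutive
#' emitted intervals are contiguous, so they partition `[lmp-90, end+180]`
#' with no gaps or overlaps.
#'
#' Default trimester cut-offs follow the obstetric convention: the first
#' trimester runs through gestational day 97 (week 13+6), the second through
#' day 195 (week 27+6).
#'
#' @param episodes Tibble with `episode_id`, `lmp_date`, `end_date`.
#' @param t1_end_day,t2_end_day Last gestational day (0-based, day 0 = LMP)
#'   of the first and second trimester.
#' @param margin_days Length of the pre-conception window and of each
#'   post-partum phase.
#' @return Tibble with one row per interval: `episode_id`, `label`
#'   (factor over [interval_labels()]), `start_date`, `end_date`.
#' @export
build_intervals <- function(episodes, t1_end_day = 97L, t2_end_day = 195L,
                            margin_days = 90L) {
  if (!(t1_end_day > 0 && t1_end_day < t2_end_day)) {
    stop("need 0 < t1_end_day < t2_end_day", call. = FALSE)
  }
  if (margin_days <= 0) stop("'margin_days' must be positive", call. = FALSE)
  if (!nrow(episodes)) {
    return(tibble::tibble(
      episode_id = integer(0),
      label = factor(character(0), levels = interval_labels()),
      start_date = as.Date(character(0)), end_date = as.Date(character(0))
    ))
  }
  check_episodes(episodes)
  lmp <- episodes$lmp_date
  end <- episodes$end_date
  gd <- as.integer(end - lmp)
  piece <- function(label, start, stop, keep = TRUE) {
    tibble::tibble(
      episode_id = episodes$episode_id[keep], label = label,
      start_date = start[keep], end_date = stop[keep]
    )
  }
  out <- dplyr::bind_rows(
    piece("PRE90", lmp - margin_days, lmp - 1L),
    piece("T1", lmp, pmin(lmp + t1_end_day, end)),
    piece("T2", lmp + t1_end_day + 1L, pmin(lmp + t2_end_day, end), gd > t1_end_day),
    piece("T3", lmp + t2_end_day + 1L, end, gd > t2_end_day),
    piece("POST90", end + 1L, end + margin_days),
    piece("POST180", end + margin_days + 1L, end + 2L * margin_days)
  )
  out$label <- factor(out$label, levels = interval_labels())
  dplyr::arrange(out, .data$episode_id, .data$label)
}

#' Keep only intervals with complete observation inside the study window
#'
#' An interval is observable when it lies entirely inside the window; an
#' episode's intervals are filtered independently, so losing (say) a
#' pre-conception window never removes the trimesters. Downstream
#' denominators are therefore label-specific.
#'
#' @param intervals Tibble from [build_intervals()].
#' @param window_start,window_end Observation window bounds (closed).
#' @return The filtered interval tibble.
#' @export
filter_observable_intervals <- function(intervals, window_start, window_end) {
  window_start <- as_date_checked(window_start, "window_start")
  window_end <- as_date_checked(window_end, "window_end")
  dplyr::filter(
    intervals,
    .data$start_date >= window_start, .data$end_date <= window_end
  )
}
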