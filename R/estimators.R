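#' Binomial proportion per 1000 with a 95% confidence interval
#'
#' Point estimate `1000 * numerator / denominator` with either the exact
#' Clopper-Pearson interval (beta-quantile relation: lower bound
#' `qbeta(alpha/2, x, n - x + 1)`, upper `qbeta(1 - alpha/2, x + 1, n - x)`,
#' with the conventional 0 and 1 at the boundaries) or the Wald normal
#' approximation `p +/- z * sqrt(p (1 - p) / n)`, floored at 0 and capped at
#' 1. Exact intervals are the default for interval-level prevalence and
#' cumulative incidence; Wald is conventional for descriptive tables.
#'
#' @param numerator,denominator Counts, `0 <= numerator <= denominator`,
#'   `denominator > 0`.
#' @param ci_method `"clopper_pearson"` or `"wald"`.
#' @param conf_level Two-sided confidence level.
#' @return One-row tibble: `numerator`, `denominator`, `rate_per_1000`,
#'   `ci_low`, `ci_high` (per 1000), `ci_method`.
#' @export
rate_per_1000 <- function(numerator, denominator,
                          ci_method = c("clopper_pearson", "wald"),
                          conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (length(numerator) != 1 || length(denominator) != 1) {
    stop("'numerator' and 'denominator' must be scalars", call. = FALSE)
  }
  if (denominator <= 0) stop("undefined rate: denominator is zero", call. = FALSE)
  if (numerator < 0 || numerator > denominator) {
    stop("need 0 <= numerator <= denominator", call. = FALSE)
  }
  x <- numerator
  n <- denominator
  p <- x / n
  alpha <- 1 - conf_level
  if (ci_method == "clopper_pearson") {
    low <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
    high <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  } else {
    z <- qnorm(1 - alpha / 2)
    half <- z * sqrt(p * (1 - p) / n)
    low <- max(0, p - half)
    high <- min(1, p + half)
  }
  tibble::tibble(
    numerator = x, denominator = n,
    rate_per_1000 = 1000 * p,
    ci_low = 1000 * low, ci_high = 1000 * high,
    ci_method = ci_method
  )
}

#' Per-1000 prevalence or cumulative incidence by interval label
#'
#' Prevalence: prevalent-exposed intervals over all observable intervals of
#' the label. Cumulative incidence: incident (new-user) intervals over the
#' washout-eligible intervals of the label. Denominators are label-specific
#' because observability is decided per interval, not per episode.
#'
#' @param statuses Exposure-status tibble from [classify_exposure()].
#' @param mode `"prevalence"` or `"incidence"`.
#' @param ci_method Passed to [rate_per_1000()].
#' @return Tibble with one row per label present in `statuses`.
#' @export
interval_rates <- function(statuses, mode = c("prevalence", "incidence"),
                           ci_method = c("clopper_pearson", "wald")) {
  mode <- match.arg(mode)
  ci_method <- match.arg(ci_method)
  if (!all(as.character(unique(statuses$label)) %in% interval_labels())) {
    stop("unknown interval label in 'statuses'", call. = FALSE)
  }
  counts <- statuses |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      numerator = if (mode == "prevalence") sum(.data$prevalent) else sum(.data$incident),
      denominator = if (mode == "prevalence") dplyr::n() else sum(.data$washout_eligible),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$denominator > 0)
  dplyr::bind_cols(
    dplyr::select(counts, dplyr::all_of("label")),
    purrr::map2_dfr(
      counts$numerator, counts$denominator,
      function(x, n) rate_per_1000(x, n, ci_method = ci_method)
    )
  )
}

#' Monthly prevalence of prescriptions during ongoing pregnancies
#'
#' For each calendar month in the window, the denominator is the number of
#' pregnancies ongoing during any day of the month (gestation `[lmp, end]`
#' overlapping the month) and the numerator counts those with a matching
#' prescription overlapping the intersection of the gestation and the month
#' -- the prescription must cover a pregnant day of that month, not merely
#' any day of it. Months with no ongoing pregnancy are omitted.
#'
#' @param episodes Episode tibble (`episode_id`, `woman_id`, `lmp_date`,
#'   `end_date`).
#' @param prescriptions Prescription tibble.
#' @param atc_prefix ATC prefix of the drug.
#' @param window_start,window_end Bounds; expanded to whole calendar months.
#' @return Tibble of monthly points: `month` (first day), `numerator`,
#'   `denominator`, `rate_per_1000`.
#' @export
monthly_prevalence_series <- function(episodes, prescriptions, atc_prefix,
                                      window_start, window_end) {
  window_start <- as_date_checked(window_start, "window_start")
  window_end <- as_date_checked(window_end, "window_end")
  if (window_start > window_end) stop("empty month window", call. = FALSE)
  months <- month_seq(window_start, window_end)
  rx <- prescriptions[atc_matches(prescriptions$atc_code, atc_prefix), , drop = FALSE]
  pairs <- if (nrow(rx) && nrow(episodes)) {
    dplyr::inner_join(
      dplyr::select(episodes, dplyr::all_of(c("episode_id", "woman_id", "lmp_date", "end_date"))),
      dplyr::select(rx, dplyr::all_of(c("woman_id", "start_date", "end_date"))),
      by = "woman_id", suffix = c("", ".rx"), relationship = "many-to-many"
    )
  } else {
    NULL
  }
  rows <- purrr::map(months, function(ms) {
    me <- month_end(ms)
    ongoing <- episodes$lmp_date <= me & episodes$end_date >= ms
    den <- sum(ongoing)
    if (den == 0) {
      return(NULL)
    }
    num <- 0L
    if (!is.null(pairs)) {
      preg_start <- pmax(pairs$lmp_date, ms)
      preg_end <- pmin(pairs$end_date, me)
      hit <- preg_start <= preg_end &
        pmax(pairs$start_date, preg_start) <= pmin(pairs$end_date.rx, preg_end)
      num <- length(unique(pairs$episode_id[hit]))
    }
    tibble::tibble(
      month = ms, numerator = num, denominator = den,
      rate_per_1000 = 1000 * num / den
    )
  })
  dplyr::bind_rows(purrr::compact(rows))
}
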