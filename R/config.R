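#' Study configuration
#'
#' Collects every analysis setting in one validated object. The defaults
#' reproduce the reference study design: observation window January 2011 to
#' June 2020, trimester cut-offs at gestational days 97 and 195 with 90-day
#' pre/post margins, a 365-day washout for the new-user definition, the
#' October 2014 regulatory intervention, and a 96-month analysis window
#' (January 2012 to December 2019) for the monthly series.
#'
#' @param window_start,window_end Observation window (complete-episode and
#'   observable-interval filters).
#' @param t1_end_day,t2_end_day,margin_days Interval boundaries, see
#'   [build_intervals()].
#' @param washout_days New-user washout length in days.
#' @param intervention_date Intervention date for the interrupted time
#'   series; the first post month is the following calendar month.
#' @param analysis_start,analysis_end Calendar window of the monthly series;
#'   trimmed relative to the observation window because only complete
#'   episodes contribute, which thins the series at both ends.
#' @param index_atc ATC prefix of the index drug (valproate).
#' @param comparator_atc ATC prefixes of substitution drugs (lamotrigine,
#'   levetiracetam).
#' @param exclusion_prefixes ICD-10 prefixes excluded from comorbidity
#'   profiling (chapter O: pregnancy-related).
#' @param smoking_codes Mapping from status codes in the diagnoses table to
#'   smoking-status labels.
#' @param ci_method_rates CI method for interval-level rates (exact binomial
#'   by default).
#' @param ci_method_descriptives CI method for descriptive proportions
#'   (Wald by default).
#' @param n_lags Lagged-outcome covariates in the ITS design (0 or 1).
#' @param n_boot Bootstrap draws for the counterfactual contrast.
#' @param seed Integer seed governing simulation and bootstrap.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(window_start = as.Date("2011-01-01"),
                         window_end = as.Date("2020-06-30"),
                         t1_end_day = 97L,
                         t2_end_day = 195L,
                         margin_days = 90L,
                         washout_days = 365L,
                         intervention_date = as.Date("2014-10-01"),
                         analysis_start = as.Date("2012-01-01"),
                         analysis_end = as.Date("2019-12-31"),
                         index_atc = "N03AG01",
                         comparator_atc = c("N03AX09", "N03AX14"),
                         exclusion_prefixes = "O",
                         smoking_codes = c(
                           "Z72.0" = "active_smoker",
                           "Z87.8" = "ex_smoker",
                           "Z71.6" = "non_smoker"
                         ),
                         ci_method_rates = "clopper_pearson",
                         ci_method_descriptives = "wald",
                         n_lags = 0L,
                         n_boot = 1000L,
                         seed = 1L) {
  window_start <- as_date_checked(window_start, "window_start")
  window_end <- as_date_checked(window_end, "window_end")
  intervention_date <- as_date_checked(intervention_date, "intervention_date")
  analysis_start <- as_date_checked(analysis_start, "analysis_start")
  analysis_end <- as_date_checked(analysis_end, "analysis_end")
  if (!(window_start < window_end)) {
    stop("'window_start' must precede 'window_end'", call. = FALSE)
  }
  if (!(window_start <= analysis_start && analysis_start < analysis_end &&
    analysis_end <= window_end)) {
    stop("analysis window must be ordered and lie inside the observation window",
      call. = FALSE
    )
  }
  if (!(analysis_start < intervention_date && intervention_date < analysis_end)) {
    stop("'intervention_date' must lie strictly inside the analysis window",
      call. = FALSE
    )
  }
  if (!(t1_end_day > 0 && t1_end_day < t2_end_day)) {
    stop("need 0 < t1_end_day < t2_end_day", call. = FALSE)
  }
  if (margin_days <= 0 || washout_days <= 0) {
    stop("'margin_days' and 'washout_days' must be positive", call. = FALSE)
  }
  if (!n_lags %in% c(0L, 1L)) stop("'n_lags' must be 0 or 1", call. = FALSE)
  structure(
    list(
      window_start = window_start, window_end = window_end,
      t1_end_day = as.integer(t1_end_day), t2_end_day = as.integer(t2_end_day),
      margin_days = as.integer(margin_days),
      washout_days = as.integer(washout_days),
      intervention_date = intervention_date,
      analysis_start = analysis_start, analysis_end = analysis_end,
      index_atc = index_atc, comparator_atc = comparator_atc,
      exclusion_prefixes = exclusion_prefixes,
      smoking_codes = smoking_codes,
      ci_method_rates = ci_method_rates,
      ci_method_descriptives = ci_method_descriptives,
      n_lags = as.integer(n_lags), n_boot = as.integer(n_boot),
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' Read a study configuration from a YAML file
#'
#' Any subset of [study_config()] arguments may be given; the rest keep
#' their defaults. `smoking_codes` may be written as a YAML mapping.
#'
#' @param path Path to a YAML file.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$smoking_codes)) {
    raw$smoking_codes <- unlist(raw$smoking_codes)
  }
  do.call(study_config, raw)
}
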