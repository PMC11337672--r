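#' Diagnoses active in the year before conception
#'
#' Returns the set of ICD-10 codes with a record overlapping the 365 days
#' before the last menstrual period (`[lmp - 365, lmp - 1]`). Open-ended
#' records (missing end date) are treated as still active. Codes matching any
#' exclusion prefix are removed; the default drops ICD-10 chapter O
#' (pregnancy-related conditions), which would otherwise contaminate the
#' comorbidity profile with artefacts of an earlier pregnancy.
#'
#' @param diagnoses Tibble with `woman_id`, `icd10_code`, `onset_date`,
#'   `end_date` (NA = open-ended).
#' @param episode One-row tibble or list with `woman_id` and `lmp_date`.
#' @param exclusion_prefixes Character vector of code prefixes to drop.
#' @param lookback_days Length of the pre-conception window.
#' @return Character vector of unique ICD-10 codes.
#' @export
active_diagnoses_year_prior <- function(diagnoses, episode,
                                        exclusion_prefixes = "O",
                                        lookback_days = 365L) {
  lmp <- episode$lmp_date
  dx <- diagnoses[diagnoses$woman_id == episode$woman_id, , drop = FALSE]
  if (!nrow(dx)) {
    return(character(0))
  }
  dx_end <- dx$end_date
  dx_end[is.na(dx_end)] <- as.Date("9999-12-31")
  active <- ranges_overlap(dx$onset_date, dx_end, lmp - lookback_days, lmp - 1L)
  codes <- unique(dx$icd10_code[active])
  if (length(exclusion_prefixes)) {
    drop <- Reduce(`|`, lapply(exclusion_prefixes, function(p) startsWith(codes, p)))
    codes <- codes[!drop]
  }
  codes
}

# Vectorised variant: (episode_id, icd10_code) pairs for many episodes.
active_diagnoses_table <- function(diagnoses, episodes,
                                   exclusion_prefixes = "O",
                                   lookback_days = 365L) {
  if (!nrow(diagnoses) || !nrow(episodes)) {
    return(tibble::tibble(episode_id = integer(0), icd10_code = character(0)))
  }
  dx <- diagnoses
  dx$end_filled <- dx$end_date
  dx$end_filled[is.na(dx$end_filled)] <- as.Date("9999-12-31")
  if (length(exclusion_prefixes)) {
    drop <- Reduce(`|`, lapply(
      exclusion_prefixes,
      function(p) startsWith(as.character(dx$icd10_code), p)
    ))
    dx <- dx[!drop, , drop = FALSE]
  }
  pairs <- dplyr::inner_join(
    dplyr::select(episodes, dplyr::all_of(c("episode_id", "woman_id", "lmp_date"))),
    dplyr::select(dx, dplyr::all_of(c("woman_id", "icd10_code", "onset_date", "end_filled"))),
    by = "woman_id", relationship = "many-to-many"
  )
  pairs <- dplyr::filter(pairs, ranges_overlap(
    .data$onset_date, .data$end_filled,
    .data$lmp_date - lookback_days, .data$lmp_date - 1L
  ))
  dplyr::distinct(pairs, .data$episode_id, .data$icd10_code)
}

descriptive_row <- function(category, count, n, with_ci = TRUE,
                            conf_level = 0.95) {
  pct <- 100 * count / n
  if (with_ci && n > 0) {
    z <- qnorm(1 - (1 - conf_level) / 2)
    p <- count / n
    half <- z * sqrt(p * (1 - p) / n)
    low <- 100 * max(0, p - half)
    high <- 100 * min(1, p + half)
  } else {
    low <- high <- NA_real_
  }
  tibble::tibble(
    category = as.character(category), count = as.integer(count),
    percent = pct, ci_low = low, ci_high = high
  )
}

#' Table-1-style descriptive rows for a cohort of exposed pregnancies
#'
#' One row per category with count, percent of the cohort and a Wald
#' confidence interval. Attributes:
#' \describe{
#'   \item{health_issue}{ICD-10 codes active in the year before conception
#'     (chapter O excluded by default); rows need not sum to 100% because of
#'     multimorbidity.}
#'   \item{smoking}{Recorded smoking status, read from status codes in the
#'     diagnoses table active in the pre-conception year (see
#'     `smoking_codes`); a `missing` row (no CI) counts episodes without any
#'     record.}
#'   \item{medea_quintile}{Deprivation quintile of the woman (1 = least
#'     deprived), with a `missing` row.}
#'   \item{rurality}{Urban/rural residence.}
#'   \item{outcome}{Pregnancy outcome; rows partition the cohort.
#'     `voluntary_interruption` codes are merged into `abortion`.}
#' }
#'
#' @param episodes Episodes of the (exposed) cohort being described, with
#'   `episode_id`, `woman_id`, `lmp_date`, `outcome_code`.
#' @param attribute One of `health_issue`, `smoking`, `medea_quintile`,
#'   `rurality`, `outcome`.
#' @param women Women table (needed for `medea_quintile`, `rurality`).
#' @param diagnoses Diagnoses table (needed for `health_issue`, `smoking`).
#' @param exclusion_prefixes ICD-10 prefixes excluded from `health_issue`.
#' @param smoking_codes Named character vector mapping status codes in the
#'   diagnoses table to status labels.
#' @param conf_level Wald confidence level.
#' @return Tibble of descriptive rows: `attribute`, `category`, `count`,
#'   `percent`, `ci_low`, `ci_high`.
#' @export
tabulate_cohort <- function(episodes, attribute, women = NULL,
                            diagnoses = NULL,
                            exclusion_prefixes = "O",
                            smoking_codes = c(
                              "Z72.0" = "active_smoker",
                              "Z87.8" = "ex_smoker",
                              "Z71.6" = "non_smoker"
                            ),
                            conf_level = 0.95) {
  choices <- c("health_issue", "smoking", "medea_quintile", "rurality", "outcome")
  if (!attribute %in% choices) {
    stop(
      "unknown attribute; must be one of ", paste(choices, collapse = ", "),
      call. = FALSE
    )
  }
  n <- nrow(episodes)
  if (n == 0) stop("empty cohort", call. = FALSE)
  rows <- switch(attribute,
    health_issue = {
      if (is.null(diagnoses)) stop("'diagnoses' required", call. = FALSE)
      tab <- active_diagnoses_table(diagnoses, episodes, exclusion_prefixes)
      tab <- tab[!tab$icd10_code %in% names(smoking_codes), , drop = FALSE]
      counts <- dplyr::count(tab, .data$icd10_code, sort = TRUE)
      purrr::map2_dfr(counts$icd10_code, counts$n, descriptive_row, n = n)
    },
    smoking = {
      if (is.null(diagnoses)) stop("'diagnoses' required", call. = FALSE)
      status_dx <- diagnoses[diagnoses$icd10_code %in% names(smoking_codes), , drop = FALSE]
      tab <- active_diagnoses_table(status_dx, episodes, exclusion_prefixes = character(0))
      tab$status <- unname(smoking_codes[tab$icd10_code])
      # one status per episode; if several recorded, the heavier exposure wins
      pref <- c("active_smoker", "ex_smoker", "non_smoker")
      tab <- tab |>
        dplyr::mutate(rank = match(.data$status, pref)) |>
        dplyr::group_by(.data$episode_id) |>
        dplyr::slice_min(.data$rank, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
      known <- purrr::map_dfr(pref, function(s) {
        descriptive_row(s, sum(tab$status == s), n)
      })
      dplyr::bind_rows(
        known,
        descriptive_row("missing", n - nrow(tab), n, with_ci = FALSE)
      )
    },
    medea_quintile = {
      if (is.null(women)) stop("'women' required", call. = FALSE)
      q <- women$medea_quintile[match(episodes$woman_id, women$woman_id)]
      known <- purrr::map_dfr(1:5, function(k) {
        descriptive_row(paste0("Q", k), sum(q == k, na.rm = TRUE), n)
      })
      dplyr::bind_rows(
        known,
        descriptive_row("missing", sum(is.na(q)), n, with_ci = FALSE)
      )
    },
    rurality = {
      if (is.null(women)) stop("'women' required", call. = FALSE)
      r <- women$rurality[match(episodes$woman_id, women$woman_id)]
      purrr::map_dfr(c("urban", "rural"), function(k) {
        descriptive_row(k, sum(r == k, na.rm = TRUE), n)
      })
    },
    outcome = {
      oc <- as.character(episodes$outcome_code)
      oc[oc == "voluntary_interruption"] <- "abortion"
      cats <- c(
        "vaginal_delivery", "abortion", "caesarean", "prematurity",
        "fetal_death", "ectopic", "hydatiform_mole", "unknown"
      )
      oc[!oc %in% cats] <- "unknown"
      purrr::map_dfr(cats, function(k) descriptive_row(k, sum(oc == k), n))
    }
  )
  dplyr::mutate(rows, attribute = attribute, .before = 1)
}
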