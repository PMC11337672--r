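#' Parameters for the synthetic EHR generator
#'
#' Bundles and validates every knob of the synthetic cohort world: a
#' population of women observed over a fixed calendar window, pregnancies
#' arising at a constant monthly conception hazard, valproate (ATC N03AG01)
#' prescriptions active at conception in ~3 per 1000 pregnancies, prescription
#' continuation declining across trimesters with a post-partum rebound, a
#' step-and-slope reduction in prescription rates after a regulatory
#' intervention, growth of substitution antiseizure drugs, and comorbidity
#' codes concentrated on epilepsy and anxiety among the exposed.
#'
#' Trend dynamics: the probability that a pregnancy starting in calendar month
#' `t` (months since `observation_start`) carries an active index-drug
#' prescription is `baseline_exposure_prob * exp(pre_slope*t +
#' level_change*post + slope_change*t_post)`, where `post` switches on in the
#' first month after `intervention_date`.
#'
#' @param n_women Number of women to simulate.
#' @param observation_start,observation_end Calendar bounds of the data window.
#' @param monthly_conception_prob Per-month probability that an eligible
#'   (not pregnant, out of post-partum) woman conceives. The default 0.0014,
#'   combined with the gestation mixture, keeps roughly 1% of women pregnant
#'   in any given month.
#' @param baseline_exposure_prob Probability that a prescription of the index
#'   drug is active on the conception date, before trend adjustment.
#' @param trimester_continuation_probs Length-3 probabilities of carrying an
#'   active prescription through T1, into T2, and into T3 (each conditional
#'   on the previous).
#' @param postpartum_continuation_prob Probability that a prescription still
#'   active at delivery continues into the post-partum windows.
#' @param postpartum_restart_prob Probability that a woman who discontinued
#'   during pregnancy restarts in the 3 months after the end of pregnancy.
#' @param interval_initiation_probs Named per-window probabilities (before
#'   trend adjustment) that a previously unexposed pregnancy initiates the
#'   index drug in that window; names from [interval_labels()].
#' @param intervention_date Calendar date of the regulatory intervention.
#' @param pre_slope,level_change,slope_change Log-scale monthly trend
#'   coefficients of the exposure probability (see Details).
#' @param substitution_baseline_probs,substitution_rates Named by ATC code:
#'   probability of an active prescription at conception at
#'   `observation_start`, and its log-scale monthly growth.
#' @param comorbidity_probs Named ICD-10-code probabilities of each chronic
#'   health issue among exposed pregnancies.
#' @param background_comorbidity_probs Same, for unexposed pregnancies.
#' @param smoking_probs Named probabilities of a recorded smoking status
#'   (status codes in the diagnoses table); the remainder have no record.
#' @param outcome_probs Probabilities of pregnancy outcomes
#'   (`vaginal_delivery`, `abortion`, `caesarean`). The abortion mass doubles
#'   as the early-termination component of the gestation-length mixture.
#' @param rx_days Length in days of one prescription issue; coverage periods
#'   are emitted as consecutive renewals of this length.
#' @param washout_days Drug-free look-back used when recording new-user
#'   ground truth.
#' @param series_denominator Pregnancies ongoing per month assumed by
#'   [simulate_monthly_series()].
#' @param seed Integer master seed; per-woman substreams are derived from it
#'   so that enlarging the cohort never perturbs already-simulated women.
#'
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_women = 10000,
                              observation_start = as.Date("2011-01-01"),
                              observation_end = as.Date("2020-06-30"),
                              monthly_conception_prob = 0.0014,
                              baseline_exposure_prob = 0.003,
                              trimester_continuation_probs = c(T1 = 0.97, T2 = 0.67, T3 = 0.86),
                              postpartum_continuation_prob = 0.6,
                              postpartum_restart_prob = 0.2,
                              interval_initiation_probs = c(
                                PRE90 = 5e-4, T1 = 6e-4, T2 = 3e-4,
                                T3 = 4e-4, POST90 = 8e-4, POST180 = 5e-4
                              ),
                              intervention_date = as.Date("2014-10-01"),
                              pre_slope = -0.001,
                              level_change = log(0.95),
                              slope_change = log(0.973),
                              substitution_baseline_probs = c(N03AX09 = 0.003, N03AX14 = 0.0015),
                              substitution_rates = c(N03AX09 = 0.005, N03AX14 = 0.007),
                              comorbidity_probs = c(
                                G40 = 0.7913, F41 = 0.6887, F17 = 0.3708,
                                E66 = 0.2350, L29 = 0.2317, F32 = 0.1920,
                                J44 = 0.1490
                              ),
                              background_comorbidity_probs = c(
                                G40 = 0.006, F41 = 0.15, F17 = 0.12,
                                E66 = 0.12, L29 = 0.05, F32 = 0.06,
                                J44 = 0.02
                              ),
                              smoking_probs = c(
                                "Z71.6" = 0.096, "Z72.0" = 0.0662, "Z87.8" = 0.0264
                              ),
                              outcome_probs = c(
                                vaginal_delivery = 0.543, abortion = 0.295,
                                caesarean = 0.162
                              ),
                              rx_days = 90,
                              washout_days = 365,
                              series_denominator = 1000,
                              seed = 1L) {
  observation_start <- as_date_checked(observation_start, "observation_start")
  observation_end <- as_date_checked(observation_end, "observation_end")
  intervention_date <- as_date_checked(intervention_date, "intervention_date")
  if (!(observation_start < intervention_date && intervention_date < observation_end)) {
    stop("dates must satisfy observation_start < intervention_date < observation_end",
      call. = FALSE
    )
  }
  check_prob(monthly_conception_prob, "monthly_conception_prob")
  check_prob(baseline_exposure_prob, "baseline_exposure_prob")
  check_prob(trimester_continuation_probs, "trimester_continuation_probs")
  check_prob(postpartum_continuation_prob, "postpartum_continuation_prob")
  check_prob(postpartum_restart_prob, "postpartum_restart_prob")
  check_prob(interval_initiation_probs, "interval_initiation_probs")
  check_prob(comorbidity_probs, "comorbidity_probs")
  check_prob(background_comorbidity_probs, "background_comorbidity_probs")
  check_prob(smoking_probs, "smoking_probs")
  check_prob(outcome_probs, "outcome_probs")
  check_prob(substitution_baseline_probs, "substitution_baseline_probs")
  if (length(trimester_continuation_probs) != 3L) {
    stop("'trimester_continuation_probs' must have length 3", call. = FALSE)
  }
  if (!all(interval_labels() %in% names(interval_initiation_probs))) {
    stop("'interval_initiation_probs' must be named by the six interval labels",
      call. = FALSE
    )
  }
  if (n_women < 1 || n_women != round(n_women)) {
    stop("'n_women' must be a positive integer", call. = FALSE)
  }
  if (washout_days <= 0) stop("'washout_days' must be positive", call. = FALSE)
  structure(
    list(
      n_women = as.integer(n_women),
      observation_start = observation_start,
      observation_end = observation_end,
      monthly_conception_prob = monthly_conception_prob,
      baseline_exposure_prob = baseline_exposure_prob,
      trimester_continuation_probs = unname(trimester_continuation_probs),
      postpartum_continuation_prob = postpartum_continuation_prob,
      postpartum_restart_prob = postpartum_restart_prob,
      interval_initiation_probs = interval_initiation_probs[interval_labels()],
      intervention_date = intervention_date,
      pre_slope = pre_slope,
      level_change = level_change,
      slope_change = slope_change,
      substitution_baseline_probs = substitution_baseline_probs,
      substitution_rates = substitution_rates,
      comorbidity_probs = comorbidity_probs,
      background_comorbidity_probs = background_comorbidity_probs,
      smoking_probs = smoking_probs,
      outcome_probs = outcome_probs,
      rx_days = as.integer(rx_days),
      washout_days = as.integer(washout_days),
      series_denominator = as.integer(series_denominator),
      seed = as.integer(seed)
    ),
    class = "simulation_params"
  )
}

# Deterministic per-woman substream seed, kept below 2^31.
woman_seed <- function(seed, woman_id) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(woman_id) * 10007) %% 2147483629)
}

# Trend multiplier on the exposure probability for a pregnancy whose LMP falls
# in calendar month `tm` (months since observation_start).
trend_multiplier <- function(tm, m_int, pre_slope, level_change, slope_change) {
  post <- as.numeric(tm > m_int)
  t_post <- pmax(0, tm - m_int)
  exp(pre_slope * tm + level_change * post + slope_change * t_post)
}

# The six exposure windows of one episode, as a small data.frame.
# Deliberately inlined (not shared with build_intervals) so the generator's
# ground truth is an independent code path.
episode_windows <- function(lmp, end, t1_end_day = 97L, t2_end_day = 195L,
                            margin_days = 90L) {
  gd <- as.integer(end - lmp)
  w <- list(
    PRE90 = c(lmp - margin_days, lmp - 1L),
    T1 = c(lmp, min(lmp + t1_end_day, end))
  )
  if (gd > t1_end_day) w$T2 <- c(lmp + t1_end_day + 1L, min(lmp + t2_end_day, end))
  if (gd > t2_end_day) w$T3 <- c(lmp + t2_end_day + 1L, end)
  w$POST90 <- c(end + 1L, end + margin_days)
  w$POST180 <- c(end + margin_days + 1L, end + 2L * margin_days)
  w
}

# Simulate one woman's full record. Returns NULL-padded list of data frames.
simulate_one_woman <- function(wid, p, m_int) {
  set.seed(woman_seed(p$seed, wid))
  obs_len <- as.integer(p$observation_end - p$observation_start)

  birth_date <- p$observation_start - round(runif(1, 18, 40) * 365.25)
  rural <- runif(1) < 0.232
  medea <- if (rural || runif(1) < 0.12) {
    NA_integer_
  } else {
    sample.int(5L, 1L, prob = c(0.125, 0.16, 0.255, 0.23, 0.23))
  }
  u <- runif(1)
  cum <- cumsum(p$smoking_probs)
  smoking_code <- if (u < cum[length(cum)]) names(cum)[which(u < cum)[1]] else NA_character_

  # conception process: geometric waits in 30-day months
  lmp <- end <- as.Date(character(0))
  outcome <- character(0)
  d <- 0L
  p_ab <- p$outcome_probs[["abortion"]]
  vag_share <- p$outcome_probs[["vaginal_delivery"]] /
    (p$outcome_probs[["vaginal_delivery"]] + p$outcome_probs[["caesarean"]])
  for (k in seq_len(15L)) {
    wait <- rgeom(1L, p$monthly_conception_prob)
    cday <- d + wait * 30L + sample.int(30L, 1L) - 1L
    if (cday > obs_len) break
    this_lmp <- p$observation_start + cday
    early <- runif(1) < p_ab
    weeks <- if (early) runif(1, 6, 14) else min(max(rnorm(1, 39.5, 1.2), 37), 42)
    gd <- as.integer(round(weeks * 7))
    lmp <- c(lmp, this_lmp)
    end <- c(end, this_lmp + gd)
    outcome <- c(
      outcome,
      if (early) "abortion" else if (runif(1) < vag_share) "vaginal_delivery" else "caesarean"
    )
    d <- cday + gd + 180L + sample.int(60L, 1L)
  }
  n_ep <- length(lmp)

  women_row <- data.frame(
    woman_id = wid, birth_date = birth_date,
    medea_quintile = medea, rurality = if (rural) "rural" else "urban",
    stringsAsFactors = FALSE
  )
  dx <- list()
  if (!is.na(smoking_code)) {
    dx[[length(dx) + 1L]] <- data.frame(
      woman_id = wid, icd10_code = smoking_code,
      onset_date = p$observation_start - sample.int(1000L, 1L),
      end_date = as.Date(NA), stringsAsFactors = FALSE
    )
  }
  if (n_ep == 0L) {
    return(list(
      women = women_row, episodes = NULL, prescriptions = NULL,
      diagnoses = if (length(dx)) do.call(rbind, dx) else NULL,
      truth = NULL, comorbidity = NULL
    ))
  }

  cont <- p$trimester_continuation_probs
  labels <- interval_labels()
  vpa_ranges <- list() # latent coverage periods, per episode
  other_rx <- list()
  exposed0 <- logical(n_ep)
  init_label <- rep(NA_character_, n_ep)
  init_date <- rep(as.Date(NA), n_ep)
  ep_month <- month_index(lmp, p$observation_start)

  for (i in seq_len(n_ep)) {
    gd <- as.integer(end[i] - lmp[i])
    mult <- trend_multiplier(ep_month[i], m_int, p$pre_slope, p$level_change, p$slope_change)
    ranges <- list()
    exposed0[i] <- runif(1) < min(1, p$baseline_exposure_prob * mult)
    if (exposed0[i]) {
      rx_start <- lmp[i] - sample(30:200, 1L)
      t1_end_day <- 97L
      t2_end_day <- 195L
      if (runif(1) >= cont[1]) {
        cov_end <- lmp[i] + sample.int(min(t1_end_day + 1L, gd), 1L) - 1L
      } else if (gd <= t1_end_day) {
        cov_end <- end[i]
      } else if (runif(1) >= cont[2]) {
        cov_end <- lmp[i] + t1_end_day
      } else if (gd <= t2_end_day) {
        cov_end <- end[i]
      } else if (runif(1) >= cont[3]) {
        cov_end <- lmp[i] + t2_end_day
      } else {
        cov_end <- end[i]
      }
      if (cov_end >= end[i] && runif(1) < p$postpartum_continuation_prob) {
        cov_end <- end[i] + sample.int(180L, 1L)
      }
      ranges[[length(ranges) + 1L]] <- c(rx_start, cov_end)
      if (cov_end < end[i] && runif(1) < p$postpartum_restart_prob) {
        rs <- end[i] + sample.int(90L, 1L)
        ranges[[length(ranges) + 1L]] <- c(rs, rs + sample(60:180, 1L))
      }
    } else {
      win <- episode_windows(lmp[i], end[i])
      for (lab in labels) {
        if (is.null(win[[lab]])) next
        if (runif(1) < min(1, p$interval_initiation_probs[[lab]] * mult)) {
          span <- as.integer(win[[lab]][2] - win[[lab]][1])
          s <- win[[lab]][1] + sample.int(span + 1L, 1L) - 1L
          ranges[[length(ranges) + 1L]] <- c(s, s + sample(90:270, 1L))
          init_label[i] <- lab
          init_date[i] <- s
          break
        }
      }
    }
    vpa_ranges[[i]] <- ranges

    # substitution antiseizure drugs with calendar growth
    for (atc in names(p$substitution_baseline_probs)) {
      pr <- min(1, p$substitution_baseline_probs[[atc]] *
        exp(p$substitution_rates[[atc]] * ep_month[i]))
      if (runif(1) < pr) {
        s <- lmp[i] - sample(0:150, 1L)
        other_rx[[length(other_rx) + 1L]] <- data.frame(
          woman_id = wid, atc_code = atc,
          start_date = s, end_date = s + sample(120:400, 1L),
          stringsAsFactors = FALSE
        )
      }
    }
  }

  # all latent valproate coverage of this woman
  flat <- unlist(vpa_ranges, recursive = FALSE)
  if (length(flat)) {
    all_s <- as.Date(vapply(flat, function(r) as.numeric(r[1]), 0), origin = "1970-01-01")
    all_e <- as.Date(vapply(flat, function(r) as.numeric(r[2]), 0), origin = "1970-01-01")
  } else {
    all_s <- all_e <- as.Date(character(0))
  }

  # episode-level exposure flag: any coverage overlapping gestation
  exposed_ep <- vapply(seq_len(n_ep), function(i) {
    length(all_s) > 0 && any(pmax(all_s, lmp[i]) <= pmin(all_e, end[i]))
  }, logical(1))

  # per-window ground truth
  truth_rows <- vector("list", n_ep)
  for (i in seq_len(n_ep)) {
    win <- episode_windows(lmp[i], end[i])
    prev <- elig <- inc <- setNames(rep(NA, length(labels)), labels)
    for (lab in labels) {
      if (is.null(win[[lab]])) next
      ws <- win[[lab]][1]
      we <- win[[lab]][2]
      prev[lab] <- length(all_s) > 0 && any(pmax(all_s, ws) <= pmin(all_e, we))
      in_window <- as.integer(ws - p$observation_start) >= p$washout_days
      clean <- !(length(all_s) > 0 &&
        any(pmax(all_s, ws - p$washout_days) <= pmin(all_e, ws - 1L)))
      elig[lab] <- in_window && clean
      inc[lab] <- elig[lab] && length(all_s) > 0 && any(all_s >= ws & all_s <= we)
    }
    truth_rows[[i]] <- data.frame(
      woman_id = wid, ep_index = i, lmp_date = lmp[i], end_date = end[i],
      month_index = ep_month[i], exposed_at_conception = exposed0[i],
      exposed_episode = exposed_ep[i],
      init_label = init_label[i], init_date = init_date[i],
      prevalent = I(list(prev)), washout_eligible = I(list(elig)),
      incident = I(list(inc)), stringsAsFactors = FALSE
    )
  }

  # comorbidities drawn per episode; every drawn record is active in the year
  # before the LMP, so counts are recoverable exactly
  com_rows <- list()
  for (i in seq_len(n_ep)) {
    probs <- if (exposed_ep[i]) p$comorbidity_probs else p$background_comorbidity_probs
    hits <- names(probs)[runif(length(probs)) < probs]
    for (code in hits) {
      onset <- lmp[i] - sample(30:1500, 1L)
      dx_end <- if (runif(1) < 0.85) as.Date(NA) else lmp[i] - sample.int(300L, 1L)
      dx[[length(dx) + 1L]] <- data.frame(
        woman_id = wid, icd10_code = code, onset_date = onset,
        end_date = dx_end, stringsAsFactors = FALSE
      )
    }
    if (length(hits)) {
      com_rows[[length(com_rows) + 1L]] <- data.frame(
        woman_id = wid, ep_index = i, icd10_code = hits,
        stringsAsFactors = FALSE
      )
    }
    # distractors: resolved long before the window, and pregnancy-chapter codes
    if (runif(1) < 0.10) {
      dx[[length(dx) + 1L]] <- data.frame(
        woman_id = wid, icd10_code = "M54.5",
        onset_date = lmp[i] - 2000L, end_date = lmp[i] - 1800L,
        stringsAsFactors = FALSE
      )
    }
    if (runif(1) < 0.05) {
      dx[[length(dx) + 1L]] <- data.frame(
        woman_id = wid, icd10_code = "O26.8",
        onset_date = lmp[i] - sample(10:300, 1L), end_date = as.Date(NA),
        stringsAsFactors = FALSE
      )
    }
  }

  # emit valproate coverage as consecutive renewals of rx_days
  rx <- list()
  for (ranges in vpa_ranges) {
    for (r in ranges) {
      starts <- seq(r[1], r[2], by = p$rx_days)
      rx[[length(rx) + 1L]] <- data.frame(
        woman_id = wid, atc_code = "N03AG01",
        start_date = starts, end_date = pmin(starts + p$rx_days - 1L, r[2]),
        stringsAsFactors = FALSE
      )
    }
  }
  rx <- c(rx, other_rx)

  gw <- as.numeric(end - lmp) / 7
  list(
    women = women_row,
    episodes = data.frame(
      woman_id = wid, lmp_date = lmp, end_date = end, outcome_code = outcome,
      gestational_weeks = gw, stringsAsFactors = FALSE
    ),
    prescriptions = if (length(rx)) do.call(rbind, rx) else NULL,
    diagnoses = if (length(dx)) do.call(rbind, dx) else NULL,
    truth = do.call(rbind, truth_rows),
    comorbidity = if (length(com_rows)) do.call(rbind, com_rows) else NULL
  )
}

#' Simulate a linked synthetic EHR cohort
#'
#' Generates the four study tables (women, pregnancy episodes, prescriptions,
#' diagnoses) together with a ground-truth record of every latent exposure
#' draw, so that downstream classification and estimation can be verified by
#' exact recount. The generator is deterministic given `params$seed`, and each
#' woman has her own derived random substream: growing `n_women` appends new
#' women without perturbing existing ones.
#'
#' @param params A [simulation_params()] object.
#' @return A list with tibbles `women`, `episodes`, `prescriptions`,
#'   `diagnoses`, and a `ground_truth` list holding per-episode latent
#'   exposure flags (`episodes`), per-episode comorbidity draws
#'   (`comorbidities`), and the true trend coefficients (`trend`).
#' @export
simulate_cohort <- function(params) {
  if (!inherits(params, "simulation_params")) {
    stop("'params' must be created by simulation_params()", call. = FALSE)
  }
  m_int <- month_index(params$intervention_date, params$observation_start)
  res <- with_preserved_rng(
    lapply(seq_len(params$n_women), simulate_one_woman, p = params, m_int = m_int)
  )
  empty_schema <- list(
    women = tibble::tibble(
      woman_id = integer(0), birth_date = as.Date(character(0)),
      medea_quintile = integer(0), rurality = character(0)
    ),
    episodes = tibble::tibble(
      woman_id = integer(0), lmp_date = as.Date(character(0)),
      end_date = as.Date(character(0)), outcome_code = character(0),
      gestational_weeks = numeric(0)
    ),
    prescriptions = tibble::tibble(
      woman_id = integer(0), atc_code = character(0),
      start_date = as.Date(character(0)), end_date = as.Date(character(0))
    ),
    diagnoses = tibble::tibble(
      woman_id = integer(0), icd10_code = character(0),
      onset_date = as.Date(character(0)), end_date = as.Date(character(0))
    ),
    truth = tibble::tibble(),
    comorbidity = tibble::tibble(
      woman_id = integer(0), ep_index = integer(0), icd10_code = character(0)
    )
  )
  pull <- function(field) {
    parts <- purrr::compact(purrr::map(res, field))
    if (!length(parts)) {
      return(empty_schema[[field]])
    }
    tibble::as_tibble(do.call(rbind, parts))
  }
  women <- pull("women")
  episodes <- pull("episodes")
  prescriptions <- pull("prescriptions")
  diagnoses <- pull("diagnoses")
  truth <- pull("truth")
  comorbidity <- pull("comorbidity")

  if (nrow(episodes)) {
    episodes <- dplyr::mutate(episodes, episode_id = dplyr::row_number(), .before = 1)
  }
  if (nrow(truth)) {
    truth <- dplyr::mutate(truth, episode_id = dplyr::row_number(), .before = 1)
    # unpack the per-window flag lists into flat columns
    unpack <- function(col, prefix) {
      m <- do.call(rbind, truth[[col]])
      colnames(m) <- paste0(prefix, "_", colnames(m))
      tibble::as_tibble(m)
    }
    truth <- dplyr::bind_cols(
      dplyr::select(truth, -dplyr::all_of(c("prevalent", "washout_eligible", "incident"))),
      unpack("prevalent", "prev"),
      unpack("washout_eligible", "elig"),
      unpack("incident", "inc")
    )
    if (nrow(comorbidity)) {
      comorbidity <- dplyr::left_join(
        comorbidity,
        dplyr::select(truth, dplyr::all_of(c("woman_id", "ep_index", "episode_id"))),
        by = c("woman_id", "ep_index")
      )
    }
  }
  if (nrow(prescriptions)) prescriptions <- dplyr::arrange(prescriptions, .data$woman_id, .data$atc_code, .data$start_date)
  if (nrow(diagnoses)) diagnoses <- dplyr::arrange(diagnoses, .data$woman_id, .data$icd10_code, .data$onset_date)

  list(
    women = women,
    episodes = episodes,
    prescriptions = prescriptions,
    diagnoses = diagnoses,
    ground_truth = list(
      episodes = truth,
      comorbidities = comorbidity,
      trend = list(
        pre_slope = params$pre_slope,
        level_change = params$level_change,
        slope_change = params$slope_change,
        intervention_date = params$intervention_date
      ),
      params = params
    )
  )
}

#' Simulate a monthly exposure-count series from the segmented Poisson model
#'
#' Draws one calendar-month series of exposed-pregnancy counts directly from
#' the segmented log-linear Poisson model used to evaluate the regulatory
#' intervention: `E[y_t] = denominator * exp(b0 + b1*t + b2*post_t +
#' b3*tpost_t)` with `exp(b0)` the baseline exposure proportion. This is the
#' counterfactual-world generator used for parameter-recovery testing of the
#' interrupted-time-series fit.
#'
#' @param params A [simulation_params()] object; uses `baseline_exposure_prob`,
#'   the trend coefficients, `series_denominator`, `observation_start` (first
#'   month of the series), `intervention_date` and `seed`.
#' @param n_months Number of calendar months (>= 24); the intervention month
#'   must lie strictly inside the series.
#' @return A tibble of monthly points (`month`, `numerator`, `denominator`,
#'   `rate_per_1000`) with attribute `truth` holding the expected counts and
#'   generating coefficients.
#' @export
simulate_monthly_series <- function(params, n_months) {
  if (!inherits(params, "simulation_params")) {
    stop("'params' must be created by simulation_params()", call. = FALSE)
  }
  if (n_months < 24) stop("'n_months' must be at least 24", call. = FALSE)
  months <- seq(month_floor(params$observation_start), by = "month", length.out = n_months)
  m_int <- month_index(params$intervention_date, params$observation_start)
  if (m_int < 0 || m_int >= n_months - 1) {
    stop("'intervention_date' must fall strictly inside the series", call. = FALSE)
  }
  t <- seq_len(n_months) - 1
  post <- as.numeric(t > m_int)
  t_post <- pmax(0, t - m_int)
  mu <- params$series_denominator * params$baseline_exposure_prob *
    exp(params$pre_slope * t + params$level_change * post + params$slope_change * t_post)
  y <- with_preserved_rng({
    set.seed(params$seed)
    rpois(n_months, mu)
  })
  out <- tibble::tibble(
    month = months,
    numerator = y,
    denominator = params$series_denominator,
    rate_per_1000 = 1000 * y / params$series_denominator
  )
  attr(out, "truth") <- list(
    expected = mu,
    coefficients = c(
      intercept = log(params$baseline_exposure_prob),
      pre_slope = params$pre_slope,
      level_change = params$level_change,
      slope_change = params$slope_change
    ),
    intervention_index = m_int
  )
  out
}
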