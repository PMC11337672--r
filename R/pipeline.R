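#' Run the full drug-utilisation pipeline
#'
#' Executes the whole analysis in order: (optionally) simulate the cohort,
#' filter complete pregnancy episodes, carve and filter exposure windows,
#' classify prevalent/incident exposure, estimate per-1000 prevalence and
#' cumulative incidence by window, build monthly prevalence series for the
#' index and substitution drugs, fit the segmented Poisson interrupted time
#' series around the intervention, and tabulate descriptives of the exposed
#' pregnancies. Every filtering step logs its in/out counts, giving a
#' reproducible attrition trail. Identical config and seed give identical
#' results (and byte-identical files when `outdir` is set).
#'
#' @param config A [study_config()].
#' @param tables Either `NULL` (simulate with `params`), a named list of the
#'   four tables (`women`, `episodes`, `prescriptions`, `diagnoses`), or a
#'   named list of four CSV paths, which are read and validated first.
#' @param params A [simulation_params()]; used when `tables` is `NULL`.
#'   Defaults to `simulation_params(seed = config$seed)`.
#' @param outdir Optional output directory; result tables are written as CSV
#'   plus a JSON manifest recording the config hash, seed and attrition
#'   counts.
#' @param quiet Suppress the attrition log.
#' @return A result bundle (list): input `tables`, `intervals`, `statuses`,
#'   `prevalence`, `incidence`, `series` (one tibble per drug), `its`
#'   (fit, counterfactual contrast, autocorrelation check), `descriptives`,
#'   `exposed_episodes`, and `manifest`.
#' @export
run_pipeline <- function(config = study_config(), tables = NULL, params = NULL,
                         outdir = NULL, quiet = FALSE) {
  if (!inherits(config, "study_config")) {
    stop("'config' must come from study_config()", call. = FALSE)
  }
  say <- function(...) if (!quiet) message(sprintf(...))

  if (is.null(tables)) {
    if (is.null(params)) params <- simulation_params(seed = config$seed)
    say("simulating cohort: %d women, seed %d", params$n_women, params$seed)
    sim <- simulate_cohort(params)
    tables <- sim[c("women", "episodes", "prescriptions", "diagnoses")]
    ground_truth <- sim$ground_truth
  } else {
    ground_truth <- NULL
    need <- c("women", "episodes", "prescriptions", "diagnoses")
    if (!all(need %in% names(tables))) {
      stop("'tables' must contain ", paste(need, collapse = ", "), call. = FALSE)
    }
    if (is.character(tables$women)) {
      tables <- list(
        women = read_women_table(tables$women),
        episodes = read_episodes_table(tables$episodes),
        prescriptions = read_prescriptions_table(tables$prescriptions),
        diagnoses = read_diagnoses_table(tables$diagnoses)
      )
    }
  }

  episodes <- tables$episodes
  say("episodes read: %d", nrow(episodes))
  complete <- filter_complete_episodes(episodes, config$window_start, config$window_end)
  say("complete episodes inside %s..%s: %d (dropped %d)",
    format(config$window_start), format(config$window_end),
    nrow(complete), nrow(episodes) - nrow(complete)
  )

  intervals <- build_intervals(
    complete,
    t1_end_day = config$t1_end_day,
    t2_end_day = config$t2_end_day,
    margin_days = config$margin_days
  )
  observable <- filter_observable_intervals(
    intervals, config$window_start, config$window_end
  )
  say(
    "exposure windows built: %d, fully observable: %d",
    nrow(intervals), nrow(observable)
  )

  statuses <- classify_exposure(
    observable, complete, tables$prescriptions,
    atc_prefix = config$index_atc,
    washout_days = config$washout_days,
    observation_start = config$window_start
  )
  say(
    "windows washout-eligible: %d of %d",
    sum(statuses$washout_eligible), nrow(statuses)
  )

  prevalence <- interval_rates(statuses, "prevalence", ci_method = config$ci_method_rates)
  incidence <- interval_rates(statuses, "incidence", ci_method = config$ci_method_rates)

  drugs <- c(config$index_atc, config$comparator_atc)
  series <- lapply(stats::setNames(drugs, drugs), function(atc) {
    monthly_prevalence_series(
      complete, tables$prescriptions, atc,
      config$analysis_start, config$analysis_end
    )
  })

  its <- NULL
  index_series <- series[[config$index_atc]]
  if (nrow(index_series) >= 24 && sum(index_series$numerator > 0) >= 5) {
    design <- build_its_design(index_series, config$intervention_date,
      n_lags = config$n_lags
    )
    fit <- tryCatch(fit_its(design, family = "poisson"), error = function(e) NULL)
    if (!is.null(fit)) {
      its <- list(
        fit = fit,
        counterfactual = counterfactual_contrast(fit,
          n_boot = config$n_boot, seed = config$seed
        ),
        autocorrelation = autocorrelation_check(fit,
          max_lag = min(12L, nrow(design) - 1L)
        )
      )
      say(
        "ITS fitted: monthly trend change %.2f%%, counterfactual contrast %.1f%%",
        fit$monthly_pct_change$estimate, its$counterfactual$pct_change
      )
    }
  }
  if (is.null(its)) say("ITS skipped: monthly series too sparse to fit")

  exposed_flag <- episode_exposed(tables$prescriptions, complete, config$index_atc)
  exposed <- complete[exposed_flag, , drop = FALSE]
  say("episodes exposed to %s during gestation: %d", config$index_atc, nrow(exposed))
  descriptives <- NULL
  if (nrow(exposed)) {
    descriptives <- dplyr::bind_rows(lapply(
      c("health_issue", "smoking", "medea_quintile", "rurality", "outcome"),
      function(a) {
        tabulate_cohort(exposed, a,
          women = tables$women, diagnoses = tables$diagnoses,
          exclusion_prefixes = config$exclusion_prefixes,
          smoking_codes = config$smoking_codes
        )
      }
    ))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dupreg")),
    config_hash = rlang::hash(config),
    seed = config$seed,
    attrition = list(
      episodes_read = nrow(episodes),
      episodes_complete = nrow(complete),
      intervals_built = nrow(intervals),
      intervals_observable = nrow(observable),
      intervals_washout_eligible = sum(statuses$washout_eligible),
      episodes_exposed = nrow(exposed)
    )
  )

  bundle <- list(
    tables = tables,
    ground_truth = ground_truth,
    episodes_complete = complete,
    intervals = observable,
    statuses = statuses,
    prevalence = prevalence,
    incidence = incidence,
    series = series,
    its = its,
    exposed_episodes = exposed,
    descriptives = descriptives,
    manifest = manifest
  )
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

# Serialise the result bundle as CSV/JSON files; deterministic content so
# that identical config+seed yields byte-identical output.
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_study_table(bundle$tables$women, p("women.csv"))
  write_study_table(bundle$tables$episodes, p("episodes.csv"))
  write_study_table(bundle$tables$prescriptions, p("prescriptions.csv"))
  write_study_table(bundle$tables$diagnoses, p("diagnoses.csv"))
  write_study_table(bundle$intervals, p("intervals.csv"))
  write_study_table(bundle$statuses, p("exposure_status.csv"))
  write_study_table(bundle$prevalence, p("interval_prevalence.csv"))
  write_study_table(bundle$incidence, p("interval_incidence.csv"))
  for (atc in names(bundle$series)) {
    write_study_table(bundle$series[[atc]], p(sprintf("monthly_series_%s.csv", atc)))
  }
  if (!is.null(bundle$descriptives)) {
    write_study_table(bundle$descriptives, p("descriptives.csv"))
  }
  if (!is.null(bundle$its)) {
    fit <- bundle$its$fit
    report <- list(
      family = fit$family,
      coefficients = as.list(fit$coefficients),
      aic = fit$aic,
      dispersion = fit$dispersion,
      monthly_pct_change = as.list(fit$monthly_pct_change),
      p_value = fit$p_value,
      counterfactual_pct_change = bundle$its$counterfactual$pct_change,
      counterfactual_ci = bundle$its$counterfactual$ci,
      autocorrelation = bundle$its$autocorrelation[c("statistic", "p_value", "refit_with_lag")]
    )
    jsonlite::write_json(report, p("its_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    write_study_table(its_series(fit), p("its_fitted_series.csv"))
  }
  if (!is.null(bundle$ground_truth)) {
    write_study_table(bundle$ground_truth$episodes, p("ground_truth_episodes.csv"))
  }
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(outdir)
}
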