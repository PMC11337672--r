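# Shared fixtures. Simulations are cached per-key so several test files can
# reuse one cohort without regenerating it.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, params) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, simulate_cohort(params), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# Default-world cohort, large enough for rate recounts.
default_sim <- function() {
  cached_sim("default", simulation_params(n_women = 6000, seed = 42L))
}

# Structure-testing cohort with exposure inflated so every flag type occurs.
dense_sim <- function() {
  cached_sim("dense", simulation_params(
    n_women = 1500, seed = 202L,
    baseline_exposure_prob = 0.08,
    interval_initiation_probs = c(
      PRE90 = 0.008, T1 = 0.008, T2 = 0.008, T3 = 0.008,
      POST90 = 0.008, POST180 = 0.008
    )
  ))
}

make_episodes <- function(lmp, end, woman_id = seq_along(lmp),
                          outcome = "vaginal_delivery") {
  tibble::tibble(
    episode_id = seq_along(lmp),
    woman_id = woman_id,
    lmp_date = as.Date(lmp),
    end_date = as.Date(end),
    outcome_code = outcome,
    gestational_weeks = as.numeric(as.Date(end) - as.Date(lmp)) / 7
  )
}

make_rx <- function(woman_id, start, end, atc = "N03AG01") {
  tibble::tibble(
    woman_id = woman_id,
    atc_code = atc,
    start_date = as.Date(start),
    end_date = as.Date(end)
  )
}

# Pull ground-truth per-window flags for one flag family ("prev", "elig",
# "inc") as a long tibble comparable to classify_exposure() output.
truth_long <- function(gt, prefix) {
  cols <- paste0(prefix, "_", interval_labels())
  out <- tidyr::pivot_longer(
    gt[, c("episode_id", cols)],
    cols = dplyr::all_of(cols),
    names_to = "label", values_to = "flag",
    names_prefix = paste0(prefix, "_")
  )
  out[!is.na(out$flag), ]
}
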