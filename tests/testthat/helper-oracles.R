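# Independent oracles used across the suite.

# Brute-force overlap: enumerate the days of both ranges and intersect.
day_overlap_oracle <- function(s1, e1, s2, e2) {
  length(intersect(
    as.integer(seq(s1, e1, by = "day")),
    as.integer(seq(s2, e2, by = "day"))
  )) > 0
}

# Clopper-Pearson bounds by inverting the binomial tail probabilities with
# root-finding (does not use the beta-quantile relation the package uses).
cp_oracle <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  low <- if (x == 0) {
    0
  } else {
    stats::uniroot(
      function(p) 1 - stats::pbinom(x - 1, n, p) - alpha / 2,
      c(1e-12, 1 - 1e-12),
      tol = 1e-14
    )$root
  }
  high <- if (x == n) {
    1
  } else {
    stats::uniroot(
      function(p) stats::pbinom(x, n, p) - alpha / 2,
      c(1e-12, 1 - 1e-12),
      tol = 1e-14
    )$root
  }
  c(low, high)
}

# Monthly prevalence by day enumeration: a pregnancy counts in a month when
# it overlaps the month; it is exposed there when a matching prescription
# covers at least one pregnant day of that month.
monthly_series_oracle <- function(episodes, prescriptions, atc_prefix,
                                  window_start, window_end) {
  months <- seq(as.Date(format(window_start, "%Y-%m-01")),
    as.Date(format(window_end, "%Y-%m-01")),
    by = "month"
  )
  rx <- prescriptions[startsWith(prescriptions$atc_code, atc_prefix), , drop = FALSE]
  out <- NULL
  for (ms in as.list(months)) {
    me <- seq(ms, by = "month", length.out = 2)[2] - 1
    month_days <- seq(ms, me, by = "day")
    den <- 0L
    num <- 0L
    for (i in seq_len(nrow(episodes))) {
      preg_days <- seq(episodes$lmp_date[i], episodes$end_date[i], by = "day")
      shared <- intersect(as.integer(month_days), as.integer(preg_days))
      if (!length(shared)) next
      den <- den + 1L
      wrx <- rx[rx$woman_id == episodes$woman_id[i], , drop = FALSE]
      covered <- FALSE
      for (j in seq_len(nrow(wrx))) {
        rx_days <- as.integer(seq(wrx$start_date[j], wrx$end_date[j], by = "day"))
        if (length(intersect(shared, rx_days))) {
          covered <- TRUE
          break
        }
      }
      if (covered) num <- num + 1L
    }
    if (den > 0) {
      out <- rbind(out, data.frame(month = ms, numerator = num, denominator = den))
    }
  }
  out
}
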