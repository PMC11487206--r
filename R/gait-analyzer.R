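#' Detect steps in an ankle accelerometer stream
#'
#' Steps are local maxima of the triaxial vector magnitude
#' sqrt(ax^2 + ay^2 + az^2) that exceed a threshold, thinned by a refractory
#' interval so one heel strike yields one event. The magnitude signal is
#' orientation-independent, which suits ankle placement where device
#' orientation drifts.
#'
#' @param accel Accelerometer tibble with columns `t_s` (seconds, strictly
#'   increasing), `ax_g`, `ay_g`, `az_g` (acceleration in g).
#' @param min_peak_g Detection threshold on the vector magnitude (g);
#'   default 1.2 g, i.e. 0.2 g above the 1-g gravity baseline.
#' @param min_interval_s Refractory period between events (s); default 0.25 s
#'   (cadence ceiling of 4 steps/s).
#' @return A tibble of step events: `t_s` (time of the peak) and `peak_g`
#'   (magnitude at the peak), ordered in time. Empty stream gives zero rows.
#' @export
detect_steps <- function(accel, min_peak_g = 1.2, min_interval_s = 0.25) {
  if (min_interval_s <= 0) abort_config("min_interval_s must be positive")
  require_columns(accel, c("t_s", "ax_g", "ay_g", "az_g"), "accelerometer stream")
  n <- nrow(accel)
  empty <- tibble(t_s = numeric(0), peak_g = numeric(0))
  if (n == 0) return(empty)
  t <- accel$t_s
  if (n > 1 && any(diff(t) <= 0)) {
    abort_input("accelerometer timestamps must be strictly increasing")
  }
  mag <- sqrt(accel$ax_g^2 + accel$ay_g^2 + accel$az_g^2)
  if (n < 3) return(empty)

  # local maxima: >= previous, > next (plateaus keep their first sample)
  core <- 2:(n - 1)
  is_peak <- mag[core] >= mag[core - 1] & mag[core] > mag[core + 1] &
    mag[core] > min_peak_g
  idx <- core[is_peak]
  if (length(idx) == 0) return(empty)

  # greedy refractory thinning in time order
  keep <- logical(length(idx))
  last_t <- -Inf
  for (k in seq_along(idx)) {
    if (t[idx[k]] - last_t >= min_interval_s) {
      keep[k] <- TRUE
      last_t <- t[idx[k]]
    }
  }
  idx <- idx[keep]
  tibble(t_s = t[idx], peak_g = mag[idx])
}

#' Group detected steps into walking bouts
#'
#' Consecutive steps separated by at most `max_gap_s` belong to one bout;
#' a larger gap starts a new bout. A bout qualifies for gait analysis only
#' when it holds a continuous run of at least 40 steps — shorter runs are
#' segmented but never contribute to gait metrics or step counts.
#'
#' @param steps Step-event tibble from [detect_steps()], time-ordered.
#' @param max_gap_s Maximum inter-step gap within a bout (s); default 3 s.
#' @param min_steps_qualify Qualification rule; default 40 steps.
#' @return A tibble with one row per bout: `bout_id`, `n_steps`, `t_first_s`,
#'   `t_last_s`, `cadence_sps` = (n_steps - 1) / (t_last - t_first) (NA for a
#'   single-step bout), `qualifies`, and a `steps` list-column of the member
#'   step events.
#' @export
segment_bouts <- function(steps, max_gap_s = 3, min_steps_qualify = 40) {
  if (max_gap_s <= 0) abort_config("max_gap_s must be positive")
  cols <- c("t_s", "peak_g")
  out0 <- tibble(
    bout_id = integer(0), n_steps = integer(0), t_first_s = numeric(0),
    t_last_s = numeric(0), cadence_sps = numeric(0), qualifies = logical(0),
    steps = list()
  )
  if (is.null(steps) || nrow(steps) == 0) return(out0)
  require_columns(steps, cols, "step events")
  if (is.unsorted(steps$t_s, strictly = TRUE)) {
    abort_input("step events must be strictly time-ordered")
  }
  bout_id <- cumsum(c(1, as.integer(diff(steps$t_s) > max_gap_s)))
  steps |>
    mutate(bout_id = bout_id) |>
    group_by(.data$bout_id) |>
    summarise(
      n_steps = n(),
      t_first_s = first(.data$t_s),
      t_last_s = last(.data$t_s),
      cadence_sps = if (n() >= 2) (n() - 1) / (last(.data$t_s) - first(.data$t_s)) else NA_real_,
      steps = list(pick("t_s", "peak_g")),
      .groups = "drop"
    ) |>
    mutate(qualifies = .data$n_steps >= min_steps_qualify) |>
    select("bout_id", "n_steps", "t_first_s", "t_last_s", "cadence_sps",
           "qualifies", "steps")
}

#' Gait metrics over qualifying walking bouts
#'
#' Summarises gait quality from qualifying (>= 40-step) bouts only:
#' * `mean_cadence_sps` — step-count-weighted mean of bout cadences;
#' * `swing_power_proxy` — mean squared magnitude deviation (g^2) of the
#'   accelerometer signal inside qualifying bout windows, a vigor surrogate;
#' * `toe_off_proxy` — mean step peak magnitude (g), a push-off surrogate;
#' * `step_time_cv` — coefficient of variation of within-bout inter-step
#'   intervals (gait variability);
#' * `qualified_step_count` — total steps in qualifying bouts.
#'
#' With no qualifying bout the participant has insufficient gait data: the
#' row is returned with all metrics `NA` and `insufficient = TRUE` (not an
#' error), so downstream validation can exclude and log the participant.
#'
#' @param bouts Bout tibble from [segment_bouts()].
#' @param accel The accelerometer stream the bouts came from.
#' @return A one-row tibble: the five metrics plus `n_qualifying_bouts` and
#'   `insufficient`.
#' @export
compute_gait_metrics <- function(bouts, accel) {
  qual <- bouts[bouts$qualifies, , drop = FALSE]
  if (nrow(qual) == 0) {
    return(tibble(
      mean_cadence_sps = NA_real_, swing_power_proxy = NA_real_,
      toe_off_proxy = NA_real_, step_time_cv = NA_real_,
      qualified_step_count = 0L, n_qualifying_bouts = 0L, insufficient = TRUE
    ))
  }
  require_columns(accel, c("t_s", "ax_g", "ay_g", "az_g"), "accelerometer stream")
  mag <- sqrt(accel$ax_g^2 + accel$ay_g^2 + accel$az_g^2)

  in_bout <- rep(FALSE, nrow(accel))
  for (i in seq_len(nrow(qual))) {
    in_bout <- in_bout |
      (accel$t_s >= qual$t_first_s[i] & accel$t_s <= qual$t_last_s[i])
  }
  swing_power <- mean((mag[in_bout] - 1)^2)

  all_steps <- bind_rows(qual$steps)
  intervals <- unlist(lapply(qual$steps, function(s) diff(s$t_s)))
  cv <- if (length(intervals) >= 2 && mean(intervals) > 0) {
    stats::sd(intervals) / mean(intervals)
  } else {
    0
  }
  tibble(
    mean_cadence_sps = weighted.mean(qual$cadence_sps, qual$n_steps),
    swing_power_proxy = swing_power,
    toe_off_proxy = mean(all_steps$peak_g),
    step_time_cv = cv,
    qualified_step_count = sum(qual$n_steps),
    n_qualifying_bouts = nrow(qual),
    insufficient = FALSE
  )
}

#' Feature cutoffs for the gait risk score
#'
#' Absolute cutoffs are used where population norms exist (cadence,
#' step-timing variability); device-relative lowest-quartile cutoffs are used
#' for the magnitude proxies and the qualified step count, computed from a
#' cohort metrics table when one is supplied.
#'
#' @param cohort_metrics Optional tibble of per-participant gait metrics
#'   (rows from [compute_gait_metrics()]); quartile cutoffs are derived from
#'   its non-missing rows.
#' @param cadence_min Impaired when mean cadence < value (steps/s); default 1.4.
#' @param step_time_cv_max Impaired when CV > value; default 0.10.
#' @param swing_power_min,toe_off_min,qualified_steps_min Absolute fallbacks
#'   used when no cohort table is given.
#' @return Named list of the five cutoffs.
#' @export
gait_thresholds <- function(cohort_metrics = NULL,
                            cadence_min = 1.4,
                            step_time_cv_max = 0.10,
                            swing_power_min = 0.02,
                            toe_off_min = 1.3,
                            qualified_steps_min = 200) {
  if (!is.null(cohort_metrics)) {
    ok <- !cohort_metrics$insufficient
    if (sum(ok) >= 4) {
      q1 <- function(v) unname(quantile(v[ok], 0.25, na.rm = TRUE, type = 7))
      swing_power_min <- q1(cohort_metrics$swing_power_proxy)
      toe_off_min <- q1(cohort_metrics$toe_off_proxy)
      qualified_steps_min <- q1(cohort_metrics$qualified_step_count)
    }
  }
  list(
    cadence_min = cadence_min,
    step_time_cv_max = step_time_cv_max,
    swing_power_min = swing_power_min,
    toe_off_min = toe_off_min,
    qualified_steps_min = qualified_steps_min
  )
}

#' Integer gait risk score
#'
#' The gait analyzer's screener statistic: a 0-5 count of impaired gait
#' features — low cadence, low swing-power proxy, low toe-off proxy, high
#' step-timing variability, low qualified step count. Higher scores indicate
#' worse gait; the validation engine treats the score as
#' higher-is-screen-positive.
#'
#' @param metrics Gait metrics tibble (one or more rows, e.g. a cohort of
#'   [compute_gait_metrics()] results).
#' @param thresholds Cutoff list from [gait_thresholds()].
#' @return `metrics` with `gait_risk_score` (integer, `NA` when the metrics
#'   row is marked insufficient) and a `features_flagged` list-column of
#'   flagged feature names appended.
#' @export
gait_risk_score <- function(metrics, thresholds = gait_thresholds()) {
  require_columns(
    metrics,
    c("mean_cadence_sps", "swing_power_proxy", "toe_off_proxy",
      "step_time_cv", "qualified_step_count", "insufficient"),
    "gait metrics"
  )
  flags <- cbind(
    low_cadence = metrics$mean_cadence_sps < thresholds$cadence_min,
    low_swing_power = metrics$swing_power_proxy < thresholds$swing_power_min,
    low_toe_off = metrics$toe_off_proxy < thresholds$toe_off_min,
    high_step_time_cv = metrics$step_time_cv > thresholds$step_time_cv_max,
    low_step_count = metrics$qualified_step_count < thresholds$qualified_steps_min
  )
  score <- as.integer(rowSums(flags))
  score[metrics$insufficient] <- NA_integer_
  flagged <- lapply(seq_len(nrow(flags)), function(i) {
    if (is.na(score[i])) character(0) else colnames(flags)[which(flags[i, ])]
  })
  metrics |>
    as_tibble() |>
    mutate(gait_risk_score = score, features_flagged = flagged)
}

#' Full gait analysis of one accelerometer stream
#'
#' Convenience pipeline: [detect_steps()] then [segment_bouts()] then
#' [compute_gait_metrics()].
#'
#' @inheritParams detect_steps
#' @inheritParams segment_bouts
#' @return One-row gait metrics tibble.
#' @export
analyze_gait <- function(accel, min_peak_g = 1.2, min_interval_s = 0.25,
                         max_gap_s = 3, min_steps_qualify = 40) {
  steps <- detect_steps(accel, min_peak_g, min_interval_s)
  bouts <- segment_bouts(steps, max_gap_s, min_steps_qualify)
  compute_gait_metrics(bouts, accel)
}
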