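#' Epoch energy from acceleration
#'
#' Tiles the recording into fixed epochs and computes each epoch's energy as
#' the mean squared deviation of the triaxial vector magnitude from the 1-g
#' gravity baseline, in g^2 — the standard accelerometer energy surrogate.
#' (The device's own energy formula is unpublished; this reconstruction keeps
#' the quadratic scaling the intensity normalization relies on.) A resting
#' stream has zero energy.
#'
#' @param accel Accelerometer tibble (`t_s`, `ax_g`, `ay_g`, `az_g`).
#' @param epoch_s Epoch length in seconds; default 60 s. Must span at least
#'   two samples at the stream's sampling rate.
#' @return A tibble of epochs: `t_start_s`, `duration_s`, `energy_raw` (g^2),
#'   with `intensity_pct` and `category` left for [classify_epochs()].
#' @export
epoch_energy <- function(accel, epoch_s = 60) {
  if (epoch_s <= 0) abort_config("epoch_s must be positive")
  require_columns(accel, c("t_s", "ax_g", "ay_g", "az_g"), "accelerometer stream")
  if (nrow(accel) == 0) abort_input("accelerometer stream is empty")
  rate <- attr(accel, "rate_hz") %||%
    (1 / median(diff(accel$t_s[seq_len(min(nrow(accel), 1000))])))
  if (epoch_s * rate < 2) {
    abort_config(sprintf(
      "epoch_s = %g spans fewer than 2 samples at %.3g Hz", epoch_s, rate
    ))
  }
  t0 <- accel$t_s[1]
  dev2 <- (sqrt(accel$ax_g^2 + accel$ay_g^2 + accel$az_g^2) - 1)^2
  ep <- floor((accel$t_s - t0) / epoch_s)
  energy <- tapply(dev2, ep, mean)
  idx <- as.numeric(names(energy))
  tibble(
    t_start_s = t0 + idx * epoch_s,
    duration_s = epoch_s,
    energy_raw = as.numeric(energy),
    intensity_pct = NA_real_,
    category = factor(NA, levels = c("light", "moderate", "high"))
  )
}

#' Walking energy reference (1 step/second)
#'
#' Intensity bands are defined relative to the energy of walking at a cadence
#' of 1 step/second. The reference is measured from the participant's own
#' qualifying walking bouts: each bout's mean magnitude-deviation power is
#' rescaled by 1/cadence^2 (signal power scales with the square of cadence for
#' a fixed gait pattern), then averaged with step-count weights. Without any
#' qualifying bout a configured fallback reference is used.
#'
#' @param accel Accelerometer tibble.
#' @param bouts Bout tibble from [segment_bouts()].
#' @param configured_e_ref Optional fallback reference energy (g^2) for
#'   recordings with no qualifying walking.
#' @return A one-row tibble: `e_ref` (g^2, > 0) and `source`
#'   (`"measured-from-bouts"` or `"configured"`).
#' @export
walking_reference <- function(accel, bouts, configured_e_ref = NULL) {
  qual <- bouts[bouts$qualifies & !is.na(bouts$cadence_sps), , drop = FALSE]
  if (nrow(qual) == 0) {
    if (is.null(configured_e_ref)) {
      abort_input(paste(
        "no qualifying walking bout to measure the 1-step/s reference from;",
        "supply configured_e_ref"
      ))
    }
    if (configured_e_ref <= 0) abort_config("configured_e_ref must be positive")
    return(tibble(e_ref = configured_e_ref, source = "configured"))
  }
  require_columns(accel, c("t_s", "ax_g", "ay_g", "az_g"), "accelerometer stream")
  dev2 <- (sqrt(accel$ax_g^2 + accel$ay_g^2 + accel$az_g^2) - 1)^2
  e_bout <- vapply(seq_len(nrow(qual)), function(i) {
    w <- accel$t_s >= qual$t_first_s[i] & accel$t_s <= qual$t_last_s[i]
    mean(dev2[w])
  }, numeric(1))
  e_ref <- weighted.mean(e_bout / qual$cadence_sps^2, qual$n_steps)
  if (!is.finite(e_ref) || e_ref <= 0) {
    abort_input("measured walking reference is not positive; check the stream")
  }
  tibble(e_ref = e_ref, source = "measured-from-bouts")
}

#' Classify epochs into intensity bands
#'
#' Expresses epoch energy as a percentage of the 1-step/second walking
#' reference and assigns the three daily-living bands: light (< 10%, sitting
#' level), moderate (>= 10% and < 30%, household-task level), high (>= 30%,
#' continuous-walking level). Boundaries are exact: 10.0% is moderate and
#' 30.0% is high.
#'
#' @param epochs Epoch tibble from [epoch_energy()].
#' @param ref Walking reference from [walking_reference()].
#' @return The epochs with `intensity_pct` and `category` filled in.
#' @export
classify_epochs <- function(epochs, ref) {
  require_columns(epochs, c("t_start_s", "duration_s", "energy_raw"), "epochs")
  if (ref$e_ref <= 0) abort_config("reference energy must be positive")
  pct <- 100 * epochs$energy_raw / ref$e_ref
  epochs |>
    as_tibble() |>
    mutate(
      intensity_pct = pct,
      category = factor(
        ifelse(pct < 10, "light", ifelse(pct < 30, "moderate", "high")),
        levels = c("light", "moderate", "high")
      )
    )
}

#' Classify daily kilocalories
#'
#' The three daily energy classes: low (< 521 kcal/day), middle (521-770,
#' both ends included), high (> 770).
#'
#' @param kcal Numeric vector of daily kilocalories.
#' @return Factor with levels low/middle/high.
#' @export
kcal_class <- function(kcal) {
  factor(
    ifelse(kcal < 521, "low", ifelse(kcal <= 770, "middle", "high")),
    levels = c("low", "middle", "high")
  )
}

#' Daily energy summary
#'
#' Aggregates classified epochs into per-day energy. Daily kilocalories are
#' modelled as a basal term plus a calibrated conversion of
#' intensity-weighted activity time:
#' `kcal = basal_kcal + kcal_per_walk_hour * sum(intensity_pct/100 * hours)`,
#' i.e. one hour at the 1-step/s walking reference adds `kcal_per_walk_hour`.
#' The default conversion (400 + 250/walking-hour) places a day of about two
#' moderate-activity hours plus half an hour of walking-level activity inside
#' the middle 521-770 kcal band. Hourly energy is normalized per day by the
#' maximum hourly energy so the most active hour scores 1.
#'
#' @param epochs Classified epoch tibble from [classify_epochs()].
#' @param kcal_per_walk_hour Kilocalories per walking-reference-equivalent
#'   hour; default 250.
#' @param basal_kcal Basal daily expenditure term; default 400 kcal.
#' @return A tibble with one row per day: `date_index` (0-based day number),
#'   `kcal`, `kcal_class`, `partial` (TRUE when the day has less than 24 h of
#'   epochs; still computed), and `hourly_energy` (list-column, 24-vector of
#'   normalized hourly energy).
#' @export
daily_summary <- function(epochs, kcal_per_walk_hour = 250, basal_kcal = 400) {
  if (kcal_per_walk_hour <= 0) abort_config("kcal_per_walk_hour must be positive")
  require_columns(epochs, c("t_start_s", "duration_s", "intensity_pct"), "epochs")
  if (anyNA(epochs$intensity_pct)) {
    abort_input("epochs must be classified before daily aggregation")
  }
  epochs |>
    mutate(
      date_index = floor(.data$t_start_s / 86400),
      hour = floor((.data$t_start_s %% 86400) / 3600)
    ) |>
    group_by(.data$date_index) |>
    summarise(
      kcal = basal_kcal + kcal_per_walk_hour *
        sum(.data$intensity_pct / 100 * .data$duration_s / 3600),
      partial = sum(.data$duration_s) < 86400,
      hourly_energy = list({
        e <- tapply(
          .data$intensity_pct * .data$duration_s, .data$hour, sum
        )
        v <- numeric(24)
        v[as.integer(names(e)) + 1] <- as.numeric(e)
        if (max(v) > 0) v / max(v) else v
      }),
      .groups = "drop"
    ) |>
    mutate(kcal_class = kcal_class(.data$kcal)) |>
    select("date_index", "kcal", "kcal_class", "partial", "hourly_energy")
}

#' Full daily-living analysis of one accelerometer stream
#'
#' Convenience pipeline: epoch energy, walking reference from the stream's
#' own qualifying bouts (with optional configured fallback), intensity
#' classification, daily summary.
#'
#' @inheritParams epoch_energy
#' @inheritParams walking_reference
#' @param bouts Optional precomputed bout tibble; detected from the stream
#'   when omitted.
#' @param ... Passed to [daily_summary()].
#' @return List with `epochs` (classified), `reference`, and `days`.
#' @export
analyze_daily_living <- function(accel, epoch_s = 60, bouts = NULL,
                                 configured_e_ref = NULL, ...) {
  if (is.null(bouts)) {
    bouts <- segment_bouts(detect_steps(accel))
  }
  epochs <- epoch_energy(accel, epoch_s)
  ref <- walking_reference(accel, bouts, configured_e_ref)
  epochs <- classify_epochs(epochs, ref)
  list(epochs = epochs, reference = ref, days = daily_summary(epochs, ...))
}
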