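#' Analyze one participant's sensor streams with both screeners
#'
#' Runs the gait analyzer (steps, bouts, metrics) and the heart-rate analyzer
#' (intensity epochs, HRR episodes, per-participant average) over one pair of
#' streams, sharing the step/bout computation between them.
#'
#' @param accel Accelerometer tibble.
#' @param hr Heart-rate tibble.
#' @param epoch_s Intensity epoch length (s); default 60.
#' @param configured_e_ref Fallback walking reference for recordings with no
#'   qualifying bout (see [walking_reference()]).
#' @return A one-row tibble: gait metrics columns plus `mean_hrr_bpm`,
#'   `mean_screener_delta_bpm`, `n_episodes`.
#' @export
analyze_participant <- function(accel, hr, epoch_s = 60,
                                configured_e_ref = NULL) {
  steps <- detect_steps(accel)
  bouts <- segment_bouts(steps)
  metrics <- compute_gait_metrics(bouts, accel)

  hrr <- tryCatch({
    epochs <- epoch_energy(accel, epoch_s)
    ref <- walking_reference(accel, bouts, configured_e_ref)
    epochs <- classify_epochs(epochs, ref)
    average_hrr(detect_episodes(hr, epochs))
  }, fs_input_error = function(e) average_hrr(NULL))

  bind_cols(metrics, hrr)
}

#' Simulate and screen a whole cohort
#'
#' Generates each participant's accelerometer and heart-rate streams from the
#' cohort's latent state, analyzes them with [analyze_participant()], derives
#' cohort-relative gait feature cutoffs, and assembles the long screener
#' table the validation engine consumes: the integer gait risk score and the
#' heart-rate screener delta (recovered minus peak, in bpm) per participant.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param config The matching [cohort_config()].
#' @return A list: `results` (per-participant metrics + screener statistics)
#'   and `screeners` (long tibble `id`, `screener`, `value`).
#' @export
screen_cohort <- function(cohort, config) {
  results <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    p <- cohort[i, ]
    accel <- generate_accel_stream(p, config)
    hr <- generate_hr_stream(p, accel, config)
    bind_cols(tibble(id = p$id),
              analyze_participant(accel, hr, epoch_s = config$epoch_s))
  })
  thr <- gait_thresholds(results)
  results <- gait_risk_score(results, thr)
  screeners <- bind_rows(
    tibble(id = results$id, screener = "gait_risk_score",
           value = as.numeric(results$gait_risk_score)),
    tibble(id = results$id, screener = "hrr_screener_delta",
           value = results$mean_screener_delta_bpm)
  )
  list(results = results, screeners = screeners, thresholds = thr)
}

#' Run the full simulated screening study
#'
#' End-to-end pipeline: generate a cohort, synthesize and analyze its sensor
#' streams, score and dichotomize the clinical reference standards, and
#' validate both screeners against every standard with ROC / Youden /
#' trapezoidal-AUC diagnostics.
#'
#' @param config A [cohort_config()].
#' @param thresholds Reference dichotomization rules from
#'   [reference_thresholds()].
#' @param standards Reference standards to score; defaults to the eight
#'   screener comparators.
#' @return A list: `cohort`, `results`, `screeners`, `labels`, `report`
#'   (an `fs_validation` tibble).
#' @export
run_screening_study <- function(config = cohort_config(),
                                thresholds = reference_thresholds(),
                                standards = setdiff(reference_standard_names(), "faller")) {
  cohort <- generate_cohort(config)
  scr <- screen_cohort(cohort, config)
  labels <- score_references(cohort, standards, thresholds)
  report <- validation_report(scr$screeners, labels)
  list(cohort = cohort, results = scr$results, screeners = scr$screeners,
       labels = labels, report = report)
}

#' Cohort composition summary
#'
#' Tabulates assessed frailty categories (via the FRAIL scale) and faller
#' status with counts and rounded percentages, the way a demographics table
#' reports them.
#'
#' @param cohort Assessment tibble with the FRAIL item columns and
#'   `falls_12mo`.
#' @return A tibble with `measure`, `n`, `pct` (percentage of the cohort,
#'   rounded half-up to the nearest integer).
#' @export
cohort_summary <- function(cohort) {
  scored <- frail_classify(cohort)
  n <- nrow(scored)
  counts <- table(scored$frail_category)
  out <- tibble(
    measure = c(names(counts), "faller"),
    n = c(as.integer(counts), sum(cohort$falls_12mo >= 1))
  )
  out$pct <- round_half_up(100 * out$n / n, 0)
  out
}
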