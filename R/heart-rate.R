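#' Detect heart-rate-recovery episodes
#'
#' The automated free-living HRR protocol: exertion is flagged wherever the
#' daily-living intensity enters the high band (>= 30% of the walking
#' reference). Within each maximal run of high-intensity epochs the maximum
#' heart-rate sample is the episode peak (earliest sample on ties, which
#' maximizes the recovery window); the next heart-rate measurement after the
#' peak — expected within one sampling interval, 5 minutes at the default
#' rate — is the recovered heart rate. HRR is the drop from peak to recovered
#' value; a higher HRR means better cardiovascular fitness. A run whose peak
#' is the final recorded sample yields no episode.
#'
#' @param hr Heart-rate tibble with columns `t_s` (strictly increasing) and
#'   `hr_bpm`; its nominal sampling interval is read from the `interval_s`
#'   attribute or the median spacing.
#' @param epochs Classified epoch tibble from [classify_epochs()] (must carry
#'   `category`).
#' @param tolerance_frac Slack on the recovery window as a fraction of the
#'   sampling interval (for jittered streams); default 0.1.
#' @return A tibble of episodes: `t_peak_s`, `hr_max_bpm`, `hr_recovered_bpm`,
#'   `hrr_bpm` (= max - recovered) and `screener_delta_bpm` (= recovered -
#'   max, the negative sign convention the screening cutoffs use). Zero rows
#'   when no high-intensity run produced a usable episode.
#' @export
detect_episodes <- function(hr, epochs, tolerance_frac = 0.1) {
  require_columns(hr, c("t_s", "hr_bpm"), "heart-rate stream")
  require_columns(epochs, c("t_start_s", "duration_s"), "epochs")
  if (!"category" %in% names(epochs) || anyNA(epochs$category)) {
    abort_protocol("epochs must carry intensity categories (run classify_epochs first)")
  }
  empty <- tibble(
    t_peak_s = numeric(0), hr_max_bpm = numeric(0),
    hr_recovered_bpm = numeric(0), hrr_bpm = numeric(0),
    screener_delta_bpm = numeric(0)
  )
  if (nrow(hr) == 0) abort_input("heart-rate stream is empty")
  if (nrow(hr) > 1 && any(diff(hr$t_s) <= 0)) {
    abort_input("heart-rate timestamps must be strictly increasing")
  }
  interval_s <- attr(hr, "interval_s") %||%
    (if (nrow(hr) > 1) median(diff(hr$t_s)) else 300)

  epochs <- arrange(as_tibble(epochs), .data$t_start_s)
  high <- epochs$category == "high"
  if (!any(high)) return(empty)
  r <- rle(high)
  run_end_idx <- cumsum(r$lengths)
  run_start_idx <- run_end_idx - r$lengths + 1
  hi <- which(r$values)
  runs <- tibble(
    start_s = epochs$t_start_s[run_start_idx[hi]],
    end_s = epochs$t_start_s[run_end_idx[hi]] + epochs$duration_s[run_end_idx[hi]]
  )

  out <- purrr::pmap_dfr(runs, function(start_s, end_s) {
    in_run <- which(hr$t_s >= start_s & hr$t_s < end_s)
    if (length(in_run) == 0) return(empty)
    peak <- in_run[which.max(hr$hr_bpm[in_run])]   # earliest max (which.max ties)
    if (peak == nrow(hr)) return(empty)            # no next sample exists
    rec <- peak + 1
    if (hr$t_s[rec] - hr$t_s[peak] > interval_s * (1 + tolerance_frac)) {
      return(empty)                                # recovery sample too late
    }
    tibble(
      t_peak_s = hr$t_s[peak],
      hr_max_bpm = hr$hr_bpm[peak],
      hr_recovered_bpm = hr$hr_bpm[rec],
      hrr_bpm = hr$hr_bpm[peak] - hr$hr_bpm[rec],
      screener_delta_bpm = hr$hr_bpm[rec] - hr$hr_bpm[peak]
    )
  })
  out
}

#' Average heart-rate recovery per participant
#'
#' Reduces a participant's episodes to the single screener statistic: the
#' arithmetic mean HRR and its negated form, the screener delta (recovered
#' minus peak), whose higher / less negative values indicate weaker recovery
#' and screen positive. With zero episodes the statistic is marked missing
#' (`NA`); validation then drops the participant pairwise.
#'
#' @param episodes Episode tibble from [detect_episodes()].
#' @return One-row tibble: `mean_hrr_bpm`, `mean_screener_delta_bpm`,
#'   `n_episodes`.
#' @examples
#' average_hrr(tibble::tibble(hrr_bpm = c(20, 30),
#'                            screener_delta_bpm = c(-20, -30)))
#' @export
average_hrr <- function(episodes) {
  n <- if (is.null(episodes)) 0L else nrow(episodes)
  if (n == 0) {
    return(tibble(
      mean_hrr_bpm = NA_real_, mean_screener_delta_bpm = NA_real_,
      n_episodes = 0L
    ))
  }
  require_columns(episodes, c("hrr_bpm", "screener_delta_bpm"), "episodes")
  tibble(
    mean_hrr_bpm = mean(episodes$hrr_bpm),
    mean_screener_delta_bpm = mean(episodes$screener_delta_bpm),
    n_episodes = as.integer(n)
  )
}

#' Full heart-rate analysis for one participant
#'
#' Convenience pipeline: classify the accelerometer stream's epochs (via the
#' daily-living analyzer), detect HRR episodes against the heart-rate stream,
#' and average them.
#'
#' @param accel Accelerometer tibble.
#' @param hr Heart-rate tibble.
#' @param epoch_s Epoch length for intensity classification; default 60 s.
#' @param configured_e_ref Fallback walking reference (see
#'   [walking_reference()]).
#' @param tolerance_frac Recovery-window slack; see [detect_episodes()].
#' @return List with `episodes` and the one-row `summary`.
#' @export
analyze_hrr <- function(accel, hr, epoch_s = 60, configured_e_ref = NULL,
                        tolerance_frac = 0.1) {
  bouts <- segment_bouts(detect_steps(accel))
  epochs <- epoch_energy(accel, epoch_s)
  ref <- walking_reference(accel, bouts, configured_e_ref)
  epochs <- classify_epochs(epochs, ref)
  episodes <- detect_episodes(hr, epochs, tolerance_frac)
  list(episodes = episodes, summary = average_hrr(episodes))
}
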