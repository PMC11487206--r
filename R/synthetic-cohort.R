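#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the simulated study: cohort composition, latent
#' physiology per frailty class, activity budgets, sensor timing and noise.
#' Defaults emulate a small community-dwelling older-adult cohort: a
#' robust/prefrail/frail mix of 41/45/14%, heart-rate recovery (HRR) that
#' weakens from robust (25 bpm) through prefrail (18 bpm) to frail (10 bpm),
#' 4-m gait speed falling with frailty, and heart rate sampled every 5
#' minutes (300 s) as interval-recording wearables do.
#'
#' @param n_participants Cohort size; default 22.
#' @param frailty_mix Probabilities for robust/prefrail/frail; must sum to 1.
#' @param hrr_means_bpm Per-class mean true HRR (bpm), strictly decreasing
#'   from robust to frail.
#' @param hrr_sd_bpm Between-participant HRR spread (bpm); default 4.
#' @param gait_speed_means_mps Per-class mean 4-m gait speed (m/s).
#' @param gait_speed_sd_mps Between-participant gait-speed spread; default 0.12.
#' @param activity_budget Data frame with columns `class`, `high_min`,
#'   `moderate_min`: daily minutes of walking-level (high-band) and
#'   household-level (moderate-band) activity per class; the rest of the day
#'   is light. Defaults: robust 60/180, prefrail 40/150, frail 15/90 min.
#' @param accel_rate_hz Accelerometer sampling rate; >= 20 Hz, default 50.
#' @param hr_interval_s Heart-rate sampling interval (s); default 300.
#' @param duration_days Recording length in days (fractions allowed);
#'   default 1.
#' @param epoch_s Intensity epoch length (s); default 60. Activity blocks are
#'   scheduled on this grid so band boundaries are clean.
#' @param accel_noise_sd_g Per-axis accelerometer noise SD (g); default 0.02.
#' @param hr_noise_sd_bpm Heart-rate measurement noise SD (bpm); default 4.
#' @param assessment_noise Probability that a reference-standard score is
#'   perturbed away from its class-typical value; default 0.1.
#' @param step_amp_g Step impulse amplitude at 1 step/s cadence (g); the
#'   amplitude scales with sqrt(cadence) so signal power scales with
#'   cadence^2. Default 0.6 g.
#' @param step_width_s Step impulse width (s); default 0.3.
#' @param moderate_intensity_frac Target intensity of moderate-activity
#'   blocks as a fraction of the walking reference; default 0.18 (inside the
#'   10-30% band).
#' @param exertion_gain_bpm Heart-rate rise over resting during exertion;
#'   default 55 bpm.
#' @param seed Integer random seed driving every draw.
#' @return A list of class `fs_cohort_config`.
#' @export
cohort_config <- function(n_participants = 22,
                          frailty_mix = c(robust = 0.41, prefrail = 0.45, frail = 0.14),
                          hrr_means_bpm = c(robust = 25, prefrail = 18, frail = 10),
                          hrr_sd_bpm = 4,
                          gait_speed_means_mps = c(robust = 1.00, prefrail = 0.78, frail = 0.50),
                          gait_speed_sd_mps = 0.12,
                          activity_budget = default_activity_budget(),
                          accel_rate_hz = 50,
                          hr_interval_s = 300,
                          duration_days = 1,
                          epoch_s = 60,
                          accel_noise_sd_g = 0.02,
                          hr_noise_sd_bpm = 4,
                          assessment_noise = 0.1,
                          step_amp_g = 0.6,
                          step_width_s = 0.3,
                          moderate_intensity_frac = 0.18,
                          exertion_gain_bpm = 55,
                          seed = 1L) {
  if (length(n_participants) != 1 || n_participants < 1) {
    abort_config("n_participants must be at least 1")
  }
  if (length(frailty_mix) != 3 || any(frailty_mix < 0) ||
      abs(sum(frailty_mix) - 1) > 1e-9) {
    abort_config("frailty_mix must be three nonnegative probabilities summing to 1")
  }
  if (length(hrr_means_bpm) != 3 || any(diff(hrr_means_bpm) >= 0)) {
    abort_config("hrr_means_bpm must be strictly decreasing from robust to frail")
  }
  if (hr_interval_s <= 0) abort_config("hr_interval_s must be positive")
  if (accel_rate_hz < 20) abort_config("accel_rate_hz must be at least 20 Hz")
  if (duration_days <= 0) abort_config("duration_days must be positive")
  if (hrr_sd_bpm < 0 || accel_noise_sd_g < 0 || hr_noise_sd_bpm < 0) {
    abort_config("noise parameters must be nonnegative")
  }
  if (assessment_noise < 0 || assessment_noise > 1) {
    abort_config("assessment_noise must be in [0, 1]")
  }
  stopifnot(is.data.frame(activity_budget))
  require_columns(activity_budget, c("class", "high_min", "moderate_min"),
                  "activity_budget")
  if (!setequal(activity_budget$class, c("robust", "prefrail", "frail"))) {
    abort_config("activity_budget needs one row per class robust/prefrail/frail")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      frailty_mix = stats::setNames(as.numeric(frailty_mix),
                                    c("robust", "prefrail", "frail")),
      hrr_means_bpm = stats::setNames(as.numeric(hrr_means_bpm),
                                      c("robust", "prefrail", "frail")),
      hrr_sd_bpm = hrr_sd_bpm,
      gait_speed_means_mps = stats::setNames(as.numeric(gait_speed_means_mps),
                                             c("robust", "prefrail", "frail")),
      gait_speed_sd_mps = gait_speed_sd_mps,
      activity_budget = as_tibble(activity_budget),
      accel_rate_hz = accel_rate_hz,
      hr_interval_s = hr_interval_s,
      duration_days = duration_days,
      epoch_s = epoch_s,
      accel_noise_sd_g = accel_noise_sd_g,
      hr_noise_sd_bpm = hr_noise_sd_bpm,
      assessment_noise = assessment_noise,
      step_amp_g = step_amp_g,
      step_width_s = step_width_s,
      moderate_intensity_frac = moderate_intensity_frac,
      exertion_gain_bpm = exertion_gain_bpm,
      seed = as.integer(seed)
    ),
    class = "fs_cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_activity_budget <- function() {
  tibble(
    class = c("robust", "prefrail", "frail"),
    high_min = c(60, 40, 15),
    moderate_min = c(180, 150, 90)
  )
}

frailty_levels <- function() c("robust", "prefrail", "frail")

#' Generate a synthetic cohort with reference-standard assessments
#'
#' Draws each participant's latent state (frailty class, true HRR, gait speed
#' and the cadence coupled to it, resting heart rate) and class-conditional
#' clinical assessments: FRAIL items, SPPB components, TUG, 4-m gait speed,
#' FROP-Com, 12-month falls, ADL/IADL limitations. Frailer participants get
#' more FRAIL deficits, lower SPPB, slower TUG and gait speed, higher
#' FROP-Com and more falls; `assessment_noise` occasionally perturbs a score
#' so assessed and latent class disagree, as real instruments do. Identical
#' configs (including seed) give identical cohorts.
#'
#' @param config An [cohort_config()] object.
#' @return A tibble with one row per participant: `id`, latent columns
#'   (`frailty_class`, `true_hrr_bpm`, `true_gait_speed_mps`,
#'   `true_cadence_sps`, `resting_hr_bpm`) and assessment columns
#'   (`frail_*` items, `sppb_*` components, `tug_s`, `gait_speed_mps`,
#'   `frop_com`, `falls_12mo`, `adl_limit`, `iadl_limit`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "fs_cohort_config"))
  n <- config$n_participants
  set.seed(config$seed)

  cls <- sample(frailty_levels(), n, replace = TRUE, prob = config$frailty_mix)
  ci <- match(cls, frailty_levels())

  true_hrr <- pmax(0, rnorm(n, config$hrr_means_bpm[ci], config$hrr_sd_bpm))
  speed <- clamp(rnorm(n, config$gait_speed_means_mps[ci],
                       config$gait_speed_sd_mps), 0.2, 2)
  # cadence tracks gait speed (shorter, slower steps when frail)
  cadence <- pmax(0.6, 0.55 + 1.35 * speed + rnorm(n, 0, 0.03))
  resting <- rnorm(n, 65, 5)

  # FRAIL: class-typical deficit count, occasionally perturbed by +/- 1
  target <- integer(n)
  target[ci == 1] <- 0L
  target[ci == 2] <- sample(1:2, sum(ci == 2), replace = TRUE)
  target[ci == 3] <- sample(3:5, sum(ci == 3), replace = TRUE)
  flip <- runif(n) < config$assessment_noise
  target[flip] <- clamp(target[flip] +
                          sample(c(-1L, 1L), sum(flip), replace = TRUE), 0L, 5L)
  item_w <- c(1.5, 1.3, 1.3, 0.8, 0.8)  # functional deficits accrue first
  items <- t(vapply(target, function(k) {
    on <- logical(5)
    if (k > 0) on[sample.int(5, k, prob = item_w)] <- TRUE
    on
  }, logical(5)))

  draw_comp <- function(means, sd = 0.9) {
    as.integer(clamp(round(rnorm(n, means[ci], sd)), 0, 4))
  }
  sppb_gait <- draw_comp(c(4.0, 3.1, 2.0))
  sppb_balance <- draw_comp(c(3.7, 2.7, 1.9))
  sppb_chair <- draw_comp(c(3.0, 2.0, 1.0))

  tug <- stats::rlnorm(n, log(c(9, 13.5, 24))[ci], 0.3)
  gait_speed <- clamp(speed + rnorm(n, 0, 0.05), 0.1, 2)
  frop <- as.integer(clamp(round(rnorm(n, c(8, 14, 22)[ci], 3)), 0, 60))
  faller <- rbinom(n, 1, c(0.2, 0.4, 0.7)[ci])
  falls <- as.integer(faller * (1L + rpois(n, 0.6)))
  adl <- rbinom(n, 1, c(0.05, 0.2, 0.5)[ci]) == 1
  iadl <- rbinom(n, 1, c(0.05, 0.2, 0.5)[ci]) == 1

  tibble(
    id = sprintf("P%03d", seq_len(n)),
    frailty_class = factor(cls, levels = frailty_levels()),
    true_hrr_bpm = true_hrr,
    true_gait_speed_mps = speed,
    true_cadence_sps = cadence,
    resting_hr_bpm = resting,
    frail_fatigue = items[, 1],
    frail_resistance = items[, 2],
    frail_aerobic = items[, 3],
    frail_illnesses = items[, 4],
    frail_weight_loss = items[, 5],
    sppb_gait = sppb_gait,
    sppb_balance = sppb_balance,
    sppb_chair = sppb_chair,
    tug_s = tug,
    gait_speed_mps = gait_speed,
    frop_com = frop,
    falls_12mo = falls,
    adl_limit = adl,
    iadl_limit = iadl
  )
}

participant_seed <- function(config, participant, offset = 0L) {
  pid <- suppressWarnings(as.integer(gsub("\\D", "", participant$id)))
  if (is.na(pid)) pid <- 1L
  as.integer((config$seed %% 100000L) * 20011L + pid * 13L + offset) %% 2147483647L
}

#' Build a raw accelerometer stream from an explicit activity schedule
#'
#' Low-level signal synthesizer: a 1-g gravity baseline on the vertical axis,
#' raised-cosine step impulses for each walking bout (amplitude
#' `step_amp_g * sqrt(cadence)` so signal power scales with cadence^2),
#' sinusoidal moderate-activity blocks tuned to a target fraction of the
#' 1-step/s walking energy, and Gaussian per-axis noise. The injected ground
#' truth (step times, bout table, exertion and moderate windows) is attached
#' as the `truth` attribute for generator/analyzer closure checks.
#'
#' @param duration_s Total stream length (s).
#' @param rate_hz Sampling rate (>= 20 Hz).
#' @param walk Tibble of walking bouts: `t_start_s`, `n_steps`, `cadence_sps`.
#' @param moderate Tibble of moderate blocks: `t_start_s`, `duration_s`.
#' @param noise_sd_g Per-axis noise SD (g).
#' @param step_amp_g,step_width_s Step impulse shape (see [cohort_config()]).
#' @param moderate_intensity_frac Moderate-block energy as a fraction of the
#'   1-step/s walking energy.
#' @param epoch_s Epoch grid used to align exertion windows; default 60 s.
#' @return A tibble (`t_s`, `ax_g`, `ay_g`, `az_g`) with attributes `rate_hz`
#'   and `truth`.
#' @export
synthetic_accel_stream <- function(duration_s, rate_hz,
                                   walk = NULL, moderate = NULL,
                                   noise_sd_g = 0, step_amp_g = 0.6,
                                   step_width_s = 0.3,
                                   moderate_intensity_frac = 0.18,
                                   epoch_s = 60) {
  if (duration_s <= 0) abort_config("duration_s must be positive")
  n <- floor(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  az <- rep(1, n)

  # raised-cosine step template at unit amplitude; odd length for a clean peak
  L <- round(step_width_s * rate_hz)
  if (L %% 2 == 0) L <- L + 1
  tpl0 <- (1 - cos(2 * pi * (0:(L - 1)) / (L - 1))) / 2

  step_times <- numeric(0)
  if (!is.null(walk) && nrow(walk) > 0) {
    for (i in seq_len(nrow(walk))) {
      cad <- walk$cadence_sps[i]
      st <- walk$t_start_s[i] + (seq_len(walk$n_steps[i]) - 1) / cad
      st <- st[st < duration_s - step_width_s]
      if (length(st) == 0) next
      amp <- step_amp_g * sqrt(cad)
      si <- round(st * rate_hz) + 1
      idx <- rep(si, each = L) + rep(0:(L - 1), times = length(si))
      ok <- idx >= 1 & idx <= n
      az[idx[ok]] <- az[idx[ok]] + rep(amp * tpl0, times = length(si))[ok]
      step_times <- c(step_times, (si - 1 + (L - 1) / 2) / rate_hz)
    }
  }

  # energy of walking at 1 step/s with this template: one pulse per second
  e_walk1 <- sum((step_amp_g * tpl0)^2) / rate_hz
  if (!is.null(moderate) && nrow(moderate) > 0) {
    m_amp <- sqrt(2 * moderate_intensity_frac * e_walk1)
    for (i in seq_len(nrow(moderate))) {
      w <- t >= moderate$t_start_s[i] &
        t < moderate$t_start_s[i] + moderate$duration_s[i]
      az[w] <- az[w] + m_amp * sin(2 * pi * 0.8 * (t[w] - moderate$t_start_s[i]))
    }
  }

  ax <- rnorm(n, 0, noise_sd_g)
  ay <- rnorm(n, 0, noise_sd_g)
  az <- az + rnorm(n, 0, noise_sd_g)

  exertion <- if (!is.null(walk) && nrow(walk) > 0) {
    # epoch-aligned spans of each bout: the windows the intensity series
    # will flag as high, hence where heart rate is driven up
    tibble(
      start_s = floor(walk$t_start_s / epoch_s) * epoch_s,
      end_s = ceiling((walk$t_start_s + (walk$n_steps - 1) / walk$cadence_sps +
                         step_width_s) / epoch_s) * epoch_s
    )
  } else {
    tibble(start_s = numeric(0), end_s = numeric(0))
  }

  out <- tibble(t_s = t, ax_g = ax, ay_g = ay, az_g = az)
  attr(out, "rate_hz") <- rate_hz
  attr(out, "truth") <- list(
    step_times = step_times,
    walk = if (is.null(walk)) tibble() else as_tibble(walk),
    moderate = if (is.null(moderate)) tibble() else as_tibble(moderate),
    exertion = exertion,
    e_walk1 = e_walk1
  )
  class(out) <- c("fs_accel", class(out))
  out
}

# schedule walking bouts and moderate blocks on the epoch grid, separated by
# rest gaps long enough (>= 6 epochs) that heart-rate episodes never merge
schedule_activity <- function(total_s, epoch_s, high_s, moderate_s, cadence,
                              step_width_s) {
  n_epochs <- floor(total_s / epoch_s)
  blocks <- list()

  # long exercise-like walks first (they straddle heart-rate samples),
  # then short errand bouts, some below the 40-step qualification rule.
  # Long walks fill whole epochs so every bout epoch sits clearly in the
  # high intensity band and heart-rate exertion windows match the epoch grid.
  remaining <- high_s
  min_long <- 6 * epoch_s
  while (remaining >= min_long) {
    k <- sample(6:8, 1)
    k <- min(k, floor(remaining / epoch_s))
    dur <- k * epoch_s
    n_steps <- max(40L, as.integer(floor((dur - 1.0) * cadence)))
    blocks[[length(blocks) + 1]] <- list(type = "walk", n_steps = n_steps)
    remaining <- remaining - dur
  }
  short_added <- 0
  while (remaining >= 15 / cadence) {
    n_steps <- if (short_added %% 2 == 0) {
      sample(15:39, 1)            # below the 40-step rule
    } else {
      sample(40:160, 1)
    }
    dur <- (n_steps - 1) / cadence + step_width_s
    if (dur > remaining + 30) break
    blocks[[length(blocks) + 1]] <- list(type = "walk", n_steps = n_steps)
    remaining <- remaining - dur
    short_added <- short_added + 1
  }

  remaining <- moderate_s
  while (remaining >= 5 * epoch_s) {
    k <- sample(5:12, 1)
    k <- min(k, floor(remaining / epoch_s))
    blocks[[length(blocks) + 1]] <- list(type = "moderate", epochs = k)
    remaining <- remaining - k * epoch_s
  }

  if (length(blocks) == 0) {
    return(list(walk = NULL, moderate = NULL))
  }
  blocks <- blocks[sample.int(length(blocks))]

  span_epochs <- vapply(blocks, function(b) {
    if (b$type == "walk") {
      ceiling(((b$n_steps - 1) / cadence + step_width_s + 1) / epoch_s)
    } else {
      b$epochs
    }
  }, numeric(1))

  min_gap <- 6  # epochs of rest between blocks (360 s at the default grid)
  # drop trailing blocks until the schedule fits with its rest gaps
  while (length(blocks) > 0 &&
         sum(span_epochs) + min_gap * (length(blocks) + 1) > n_epochs) {
    blocks <- blocks[-length(blocks)]
    span_epochs <- span_epochs[seq_along(blocks)]
  }
  if (length(blocks) == 0) {
    return(list(walk = NULL, moderate = NULL))
  }

  g <- length(blocks) + 1
  spare <- n_epochs - sum(span_epochs) - min_gap * g
  w <- runif(g, 0.5, 1.5)
  extra <- floor(spare * w / sum(w))
  gaps <- min_gap + extra

  walk <- list(); moderate <- list()
  at <- gaps[1]
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    t0 <- at * epoch_s + 0.5   # just inside the epoch
    if (b$type == "walk") {
      walk[[length(walk) + 1]] <- tibble(
        t_start_s = t0, n_steps = b$n_steps, cadence_sps = cadence
      )
    } else {
      moderate[[length(moderate) + 1]] <- tibble(
        t_start_s = at * epoch_s, duration_s = b$epochs * epoch_s
      )
    }
    at <- at + span_epochs[i] + gaps[i + 1]
  }
  list(
    walk = if (length(walk)) bind_rows(walk) else NULL,
    moderate = if (length(moderate)) bind_rows(moderate) else NULL
  )
}

#' Generate a participant's accelerometer stream
#'
#' Lays out a day-structured activity schedule from the participant's class
#' activity budget — long walks, short walking bouts (some under 40 steps),
#' moderate household-effort blocks, rest elsewhere — and synthesizes the
#' triaxial signal with [synthetic_accel_stream()]. Step impulses run at the
#' participant's true cadence; impulse amplitude grows with cadence so more
#' vigorous gait carries more signal power.
#'
#' @param participant One row of a [generate_cohort()] tibble.
#' @param config The [cohort_config()] used for the cohort.
#' @return An accelerometer tibble with `rate_hz` and `truth` attributes.
#' @export
generate_accel_stream <- function(participant, config) {
  stopifnot(inherits(config, "fs_cohort_config"))
  if (config$duration_days < 1 / 24) {
    abort_config("duration_days must be at least one hour (1/24)")
  }
  set.seed(participant_seed(config, participant, offset = 0L))
  total_s <- round(config$duration_days * 86400 / config$epoch_s) * config$epoch_s

  budget <- config$activity_budget
  b <- budget[budget$class == as.character(participant$frailty_class), ]
  sched <- schedule_activity(
    total_s, config$epoch_s,
    high_s = b$high_min * 60 * config$duration_days,
    moderate_s = b$moderate_min * 60 * config$duration_days,
    cadence = participant$true_cadence_sps,
    step_width_s = config$step_width_s
  )
  synthetic_accel_stream(
    duration_s = total_s, rate_hz = config$accel_rate_hz,
    walk = sched$walk, moderate = sched$moderate,
    noise_sd_g = config$accel_noise_sd_g,
    step_amp_g = config$step_amp_g, step_width_s = config$step_width_s,
    moderate_intensity_frac = config$moderate_intensity_frac,
    epoch_s = config$epoch_s
  )
}

#' Generate a participant's interval heart-rate stream
#'
#' Samples heart rate on a strict periodic grid (every `hr_interval_s`,
#' starting at recording start). During each exertion window — the
#' epoch-aligned span of a walking bout, where the intensity series runs
#' high — heart rate ramps from a partly elevated level up to
#' `resting + exertion_gain_bpm`; the first sample after the window drops to
#' the window's peak minus the participant's true HRR, and heart rate then
#' sits at resting until the next exertion. Gaussian measurement noise is
#' added to every sample and values are clamped to the physiological
#' 30-220 bpm range.
#'
#' @param participant One row of a [generate_cohort()] tibble.
#' @param accel The participant's accelerometer stream (carries the exertion
#'   ground truth).
#' @param config The [cohort_config()].
#' @return A tibble (`t_s`, `hr_bpm`) of class `fs_hr` with attribute
#'   `interval_s`. An empty accelerometer stream yields an empty heart-rate
#'   stream with a warning.
#' @export
generate_hr_stream <- function(participant, accel, config) {
  stopifnot(inherits(config, "fs_cohort_config"))
  if (nrow(accel) == 0) {
    warn("empty accelerometer stream; returning empty heart-rate stream")
    out <- tibble(t_s = numeric(0), hr_bpm = numeric(0))
    attr(out, "interval_s") <- config$hr_interval_s
    class(out) <- c("fs_hr", class(out))
    return(out)
  }
  set.seed(participant_seed(config, participant, offset = 7L))
  t_max <- max(accel$t_s)
  t <- seq(0, t_max, by = config$hr_interval_s)
  n <- length(t)

  truth <- attr(accel, "truth")
  ex <- if (!is.null(truth)) truth$exertion else NULL
  if (is.null(ex)) {
    warn("accelerometer stream has no exertion ground truth; heart rate stays at rest")
    ex <- tibble(start_s = numeric(0), end_s = numeric(0))
  }

  resting <- participant$resting_hr_bpm
  gain <- config$exertion_gain_bpm
  det <- rep(resting, n)
  if (nrow(ex) > 0) {
    ex <- arrange(ex, .data$start_s)
    for (i in seq_len(nrow(ex))) {
      inw <- which(t >= ex$start_s[i] & t < ex$end_s[i])
      if (length(inw) == 0) next
      progress <- (t[inw] - ex$start_s[i]) / (ex$end_s[i] - ex$start_s[i])
      det[inw] <- resting + gain * (0.3 + 0.7 * progress)
      peak <- inw[length(inw)]      # monotone ramp: last in-window sample
      if (peak < n && !(t[peak + 1] >= ex$start_s[i] & t[peak + 1] < ex$end_s[i])) {
        det[peak + 1] <- det[peak] - participant$true_hrr_bpm
      }
    }
  }
  hr <- clamp(det + rnorm(n, 0, config$hr_noise_sd_bpm), 30, 220)
  out <- tibble(t_s = t, hr_bpm = hr)
  attr(out, "interval_s") <- config$hr_interval_s
  class(out) <- c("fs_hr", class(out))
  out
}
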