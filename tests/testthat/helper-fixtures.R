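# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# a bare accelerometer tibble at rest (gravity on z)
rest_stream <- function(duration_s = 60, rate_hz = 50) {
  n <- duration_s * rate_hz
  out <- tibble::tibble(
    t_s = (seq_len(n) - 1) / rate_hz,
    ax_g = 0, ay_g = 0, az_g = 1
  )
  attr(out, "rate_hz") <- rate_hz
  out
}

# one clean walking bout via the package's own synthesizer, noise-free
walk_stream <- function(n_steps = 100, cadence = 1.8, duration_s = 120,
                        rate_hz = 50, t_start = 5, noise = 0) {
  synthetic_accel_stream(
    duration_s = duration_s, rate_hz = rate_hz,
    walk = tibble::tibble(t_start_s = t_start, n_steps = n_steps,
                          cadence_sps = cadence),
    noise_sd_g = noise
  )
}

# a participant assessment row with sensible defaults, overridable per field
assessment_row <- function(id = "P001", fatigue = FALSE, resistance = FALSE,
                           aerobic = FALSE, illnesses = FALSE,
                           weight_loss = FALSE, sppb = c(4, 4, 4),
                           tug = 9, speed = 1.0, frop = 8, falls = 0) {
  tibble::tibble(
    id = id,
    frail_fatigue = fatigue, frail_resistance = resistance,
    frail_aerobic = aerobic, frail_illnesses = illnesses,
    frail_weight_loss = weight_loss,
    sppb_gait = sppb[1], sppb_balance = sppb[2], sppb_chair = sppb[3],
    tug_s = tug, gait_speed_mps = speed, frop_com = frop,
    falls_12mo = falls, adl_limit = FALSE, iadl_limit = FALSE
  )
}

# all 32 combinations of the five FRAIL items
frail_grid <- function() {
  g <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  names(g) <- c("frail_fatigue", "frail_resistance", "frail_aerobic",
                "frail_illnesses", "frail_weight_loss")
  tibble::as_tibble(g)
}

# brute-force Youden oracle: enumerate every threshold between distinct
# scores (plus the all/none calls) and maximize tpr - fpr directly
youden_brute_force <- function(score, condition, direction = "higher_is_positive") {
  u <- sort(unique(score))
  cuts <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  best_j <- -Inf
  for (k in cuts) {
    call <- if (direction == "higher_is_positive") score >= k else score <= k
    tpr <- sum(call & condition) / sum(condition)
    fpr <- sum(call & !condition) / sum(!condition)
    best_j <- max(best_j, tpr - fpr)
  }
  best_j
}
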