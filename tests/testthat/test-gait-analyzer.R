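test_that("step detection recovers injected impulses and rejects flat streams", {
  a <- walk_stream(n_steps = 100, cadence = 1.8)
  steps <- detect_steps(a)
  expect_equal(nrow(steps), 100)
  # detected peaks align with injected impulse times to within one sample
  truth <- attr(a, "truth")$step_times
  expect_lte(max(abs(steps$t_s - truth)), 1 / attr(a, "rate_hz"))

  expect_equal(nrow(detect_steps(rest_stream())), 0)
  expect_equal(nrow(detect_steps(rest_stream(1)[0, ])), 0)
})

test_that("refractory interval merges too-close impulses", {
  rate <- 100
  n <- 2 * rate
  a <- tibble::tibble(t_s = (seq_len(n) - 1) / rate, ax_g = 0, ay_g = 0, az_g = 1)
  # two sharp impulses 0.1 s apart
  a$az_g[c(50, 60)] <- 1.8
  expect_equal(nrow(detect_steps(a, min_interval_s = 0.3)), 1)
  expect_equal(nrow(detect_steps(a, min_interval_s = 0.05)), 2)
})

test_that("lowering the detection threshold never loses steps", {
  a <- walk_stream(n_steps = 60, cadence = 1.6, noise = 0.02)
  hi <- nrow(detect_steps(a, min_peak_g = 1.5))
  lo <- nrow(detect_steps(a, min_peak_g = 1.2))
  expect_gte(lo, hi)
})

test_that("nonmonotone timestamps raise an input-format error", {
  a <- rest_stream(2)
  a$t_s[10] <- a$t_s[12]
  expect_error(detect_steps(a), class = "fs_input_error")
})

test_that("bout segmentation splits on gaps, conserves steps, and applies the 40-step rule", {
  mk_steps <- function(times) tibble::tibble(t_s = times, peak_g = 1.6)
  # 100 steps with a 10 s gap after step 50
  times <- c(seq(0, by = 0.5, length.out = 50),
             seq(35, by = 0.5, length.out = 50))
  bouts <- segment_bouts(mk_steps(times), max_gap_s = 3)
  expect_equal(nrow(bouts), 2)
  expect_equal(bouts$n_steps, c(50, 50))
  expect_equal(sum(bouts$n_steps), 100)  # step-count conservation
  expect_true(all(bouts$qualifies))
  expect_equal(bouts$cadence_sps, c(2, 2))

  # the 40-step boundary is sharp
  b39 <- segment_bouts(mk_steps(seq(0, by = 0.5, length.out = 39)))
  b40 <- segment_bouts(mk_steps(seq(0, by = 0.5, length.out = 40)))
  expect_false(b39$qualifies)
  expect_true(b40$qualifies)

  expect_equal(nrow(segment_bouts(mk_steps(numeric(0)))), 0)
})

test_that("gait metrics use qualifying bouts only and flag insufficient data", {
  a <- walk_stream(n_steps = 80, cadence = 2.0, duration_s = 120)
  m <- analyze_gait(a)
  expect_false(m$insufficient)
  expect_equal(m$mean_cadence_sps, 2.0, tolerance = 0.01)
  expect_equal(m$step_time_cv, 0)  # perfectly periodic steps on the grid
  expect_equal(m$qualified_step_count, 80)
  expect_gt(m$swing_power_proxy, 0)
  expect_gt(m$toe_off_proxy, 1)

  # a 30-step bout alone is insufficient gait data, not an error
  short <- analyze_gait(walk_stream(n_steps = 30, duration_s = 60))
  expect_true(short$insufficient)
  expect_true(is.na(short$mean_cadence_sps))
})

test_that("gait risk score counts impaired features deterministically", {
  healthy <- tibble::tibble(
    mean_cadence_sps = 2.0, swing_power_proxy = 0.1, toe_off_proxy = 1.8,
    step_time_cv = 0.03, qualified_step_count = 2000, insufficient = FALSE
  )
  thr <- gait_thresholds()
  expect_equal(gait_risk_score(healthy, thr)$gait_risk_score, 0L)

  impaired <- tibble::tibble(
    mean_cadence_sps = 1.0, swing_power_proxy = 0.001, toe_off_proxy = 1.1,
    step_time_cv = 0.2, qualified_step_count = 50, insufficient = FALSE
  )
  s <- gait_risk_score(impaired, thr)
  expect_equal(s$gait_risk_score, 5L)
  expect_setequal(s$features_flagged[[1]],
                  c("low_cadence", "low_swing_power", "low_toe_off",
                    "high_step_time_cv", "low_step_count"))

  missing <- dplyr::mutate(healthy, insufficient = TRUE,
                           mean_cadence_sps = NA_real_,
                           swing_power_proxy = NA_real_, toe_off_proxy = NA_real_,
                           step_time_cv = NA_real_)
  expect_true(is.na(gait_risk_score(missing, thr)$gait_risk_score))
})

test_that("cohort-relative thresholds come from the lowest quartile", {
  m <- tibble::tibble(
    mean_cadence_sps = seq(1.2, 2.0, length.out = 8),
    swing_power_proxy = 1:8 / 100, toe_off_proxy = seq(1.2, 1.9, length.out = 8),
    step_time_cv = 0.05, qualified_step_count = (1:8) * 100,
    insufficient = FALSE
  )
  thr <- gait_thresholds(m)
  expect_equal(thr$swing_power_min,
               unname(quantile(m$swing_power_proxy, 0.25)))
  expect_equal(thr$qualified_steps_min,
               unname(quantile(m$qualified_step_count, 0.25)))
})

test_that("synthetic frail cohorts score worse than robust ones on gait", {
  cfg <- cohort_config(n_participants = 12, duration_days = 1.5 / 24,
                       accel_rate_hz = 20, seed = 3)
  coh <- generate_cohort(cfg)
  # force a balanced comparison: analyze each participant's gait only
  res <- purrr::map_dfr(seq_len(nrow(coh)), function(i) {
    a <- generate_accel_stream(coh[i, ], cfg)
    analyze_gait(a)
  })
  res <- gait_risk_score(res, gait_thresholds(res))
  cls <- coh$frailty_class
  ok <- !res$insufficient
  frail_scores <- res$gait_risk_score[ok & cls != "robust"]
  robust_scores <- res$gait_risk_score[ok & cls == "robust"]
  expect_gt(length(frail_scores), 0)
  expect_gt(length(robust_scores), 0)
  expect_gt(mean(frail_scores), mean(robust_scores))
})
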