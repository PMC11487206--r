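test_that("config invariants are enforced", {
  expect_error(cohort_config(n_participants = 0), class = "fs_config_error")
  expect_error(cohort_config(frailty_mix = c(0.5, 0.4, 0.2)),
               class = "fs_config_error")
  expect_error(cohort_config(hrr_means_bpm = c(10, 18, 25)),
               class = "fs_config_error")
  expect_error(cohort_config(hr_interval_s = 0), class = "fs_config_error")
  expect_error(cohort_config(accel_rate_hz = 10), class = "fs_config_error")
  expect_s3_class(cohort_config(), "fs_cohort_config")
})

test_that("cohort generation respects the mix, is seeded, and handles degenerate mixtures", {
  cfg <- cohort_config(n_participants = 22, seed = 7)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 22)
  counts <- table(coh$frailty_class)
  # class counts within multinomial sampling error of (9, 10, 3)
  expect_true(all(abs(counts - c(9.02, 9.9, 3.08)) <= 3 * sqrt(22 * c(.41, .45, .14))))

  # byte-identical reruns for the same config
  big <- cohort_config(n_participants = 200, seed = 1)
  expect_identical(generate_cohort(big), generate_cohort(big))

  # degenerate mixture: all robust
  pure <- cohort_config(n_participants = 5, frailty_mix = c(1, 0, 0),
                        hrr_means_bpm = c(25, 18, 10), seed = 4)
  expect_true(all(generate_cohort(pure)$frailty_class == "robust"))
})

test_that("assessed FRAIL category agrees with the latent class for most participants", {
  coh <- generate_cohort(cohort_config(n_participants = 200, seed = 13))
  scored <- frail_classify(coh)
  agree <- mean(as.character(scored$frail_category) ==
                  as.character(coh$frailty_class))
  expect_gte(agree, 0.8)
})

test_that("latent structure: cadence tracks gait speed and HRR separates classes", {
  coh <- generate_cohort(cohort_config(n_participants = 200, seed = 17))
  expect_true(all(coh$true_hrr_bpm >= 0))
  expect_gt(cor(coh$true_gait_speed_mps, coh$true_cadence_sps,
                method = "spearman"), 0)
  w <- wilcox.test(coh$true_hrr_bpm[coh$frailty_class == "frail"],
                   coh$true_hrr_bpm[coh$frailty_class == "robust"],
                   alternative = "less", exact = FALSE)
  expect_lt(w$p.value, 0.01)
})

test_that("accelerometer stream carries scheduled bouts of both kinds with a gravity baseline", {
  cfg <- cohort_config(n_participants = 2, duration_days = 6 / 24,
                       accel_rate_hz = 20, seed = 19)
  coh <- generate_cohort(cfg)
  a <- generate_accel_stream(coh[1, ], cfg)
  truth <- attr(a, "truth")
  expect_gt(nrow(truth$walk), 0)
  expect_true(any(truth$walk$n_steps < 40) && any(truth$walk$n_steps >= 40))
  expect_true(all(diff(a$t_s) > 0))
  # gravity sanity: rest-period magnitude sits near 1 g
  in_walk <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(truth$exertion))) {
    in_walk <- in_walk | (a$t_s >= truth$exertion$start_s[i] &
                            a$t_s < truth$exertion$end_s[i])
  }
  mag_rest <- sqrt(a$ax_g^2 + a$ay_g^2 + a$az_g^2)[!in_walk]
  expect_lt(abs(median(mag_rest) - 1), 0.2)

  # zero budget: no walking bouts, analyzer finds no qualifying bout
  cfg0 <- cohort_config(n_participants = 1, duration_days = 1 / 24,
                        accel_rate_hz = 20,
                        activity_budget = tibble::tibble(
                          class = c("robust", "prefrail", "frail"),
                          high_min = 0, moderate_min = 0
                        ), seed = 19)
  coh0 <- generate_cohort(cfg0)
  a0 <- generate_accel_stream(coh0[1, ], cfg0)
  expect_equal(nrow(attr(a0, "truth")$walk), 0)
  expect_equal(sum(segment_bouts(detect_steps(a0))$qualifies), 0)
})

test_that("a robust participant walks at least as much as a frail one at the same seed", {
  cfg <- cohort_config(n_participants = 1, duration_days = 6 / 24,
                       accel_rate_hz = 20, seed = 29)
  base <- generate_cohort(cfg)[1, ]
  robust <- dplyr::mutate(base, frailty_class = factor("robust", levels = levels(base$frailty_class)))
  frail <- dplyr::mutate(base, frailty_class = factor("frail", levels = levels(base$frailty_class)))
  n_steps <- function(p) length(attr(generate_accel_stream(p, cfg), "truth")$step_times)
  expect_gte(n_steps(robust), n_steps(frail))
})

test_that("heart-rate streams are periodic, bounded, and noise-free recovery is exact", {
  cfg <- cohort_config(n_participants = 1, duration_days = 4 / 24,
                       accel_rate_hz = 20, hr_noise_sd_bpm = 0,
                       accel_noise_sd_g = 0, seed = 23)
  coh <- generate_cohort(cfg)
  a <- generate_accel_stream(coh[1, ], cfg)
  hr <- generate_hr_stream(coh[1, ], a, cfg)
  expect_equal(unique(diff(hr$t_s)), 300)
  expect_true(all(hr$hr_bpm >= 30 & hr$hr_bpm <= 220))

  truth <- attr(a, "truth")
  ex <- truth$exertion[truth$exertion$end_s - truth$exertion$start_s >= 300, ]
  expect_gt(nrow(ex), 0)
  # the sample after each long window drops by exactly the latent HRR
  w <- ex[1, ]
  inw <- which(hr$t_s >= w$start_s & hr$t_s < w$end_s)
  peak <- inw[length(inw)]
  expect_equal(hr$hr_bpm[peak] - hr$hr_bpm[peak + 1], coh$true_hrr_bpm[1])

  # empty accel stream gives an empty HR stream with a warning
  expect_warning(
    empty <- generate_hr_stream(coh[1, ], a[0, ], cfg),
    "empty"
  )
  expect_equal(nrow(empty), 0)
})

test_that("streams round-trip through the CSV formats with the config sidecar", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_participants = 2, duration_days = 1 / 24,
                       accel_rate_hz = 20, seed = 31)
  coh <- generate_cohort(cfg)
  a <- generate_accel_stream(coh[1, ], cfg)
  hr <- generate_hr_stream(coh[1, ], a, cfg)

  ap <- file.path(dir, "accel.csv"); write_accel_csv(a, ap)
  hp <- file.path(dir, "hr.csv"); write_hr_csv(hr, hp)
  cp <- file.path(dir, "cohort.csv"); write_cohort_csv(coh, cp, config = cfg)

  a2 <- read_accel_csv(ap, rate_hz = 20)
  expect_equal(a2$az_g, a$az_g, tolerance = 1e-6)
  h2 <- read_hr_csv(hp, interval_s = 300)
  expect_equal(h2$hr_bpm, hr$hr_bpm, tolerance = 1e-6)
  c2 <- read_cohort_csv(cp)
  expect_equal(as.character(c2$frailty_class), as.character(coh$frailty_class))
  sidecar <- file.path(dir, "cohort_config.json")
  expect_true(file.exists(sidecar))
  expect_equal(jsonlite::read_json(sidecar)$seed, 31)
})
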