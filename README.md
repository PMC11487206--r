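# frailscreen

Wearable-based frailty and falls-risk screening analytics for older-adult
cohorts.

Clinic-based frailty and falls-risk instruments — the FRAIL scale, the Short
Physical Performance Battery (SPPB), the Timed Up and Go (TUG), 4-m gait
speed, FROP-Com — need trained staff, space and a visit, and capture a single
time point. An ankle-worn sensor that logs raw triaxial acceleration
continuously, with an interval heart-rate channel, can screen for the same
constructs in free living. `frailscreen` implements that screening pipeline
end to end and asks the validation question directly: *how well does each
wearable statistic agree with each clinical reference standard when both are
collapsed into a 2×2 diagnostic test?*

The package has three layers:

1. **Synthetic cohort generator** — seeded simulation of a community-dwelling
   older-adult cohort: a robust/prefrail/frail mix (default 41/45/14%),
   class-conditional clinical assessments, and matching raw sensor streams
   (step impulses at each participant's cadence, moderate-activity blocks,
   rest; heart rate sampled every 300 s with exertion-recovery dynamics in
   which frail participants recover less).
2. **Analyzers** —
   * *gait*: step detection on the vector magnitude, walking-bout
     segmentation with the 40-step qualification rule (a continuous run of
     ≥ 40 steps counts; shorter runs do not), cadence and gait-quality
     features, and an integer 0–5 gait risk score;
   * *daily living*: epoch energy = mean squared magnitude deviation,
     normalized to the energy of walking at 1 step/second, banded into
     light (< 10%), moderate (≥ 10 to < 30%) and high (≥ 30%) intensity,
     aggregated to daily kilocalories classed low (< 521) / middle
     (521–770) / high (> 770 kcal/day);
   * *heart rate*: automated heart-rate recovery (HRR) — each maximal run of
     high-intensity epochs contributes an episode whose peak heart rate is
     compared with the next interval sample; HRR = peak − recovered, and the
     per-participant mean (as the negated *screener delta*) is the screener
     statistic.
3. **Diagnostic validation** — for every screener × reference-standard pair:
   2×2 table (sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), PPV, NPV),
   ROC over all cutoffs, the Youden-optimal cutoff
   (max J = sensitivity + specificity − 1), and the trapezoidal AUC
   (Σ Δfpr · (tpr₁ + tpr₂)/2; with one operating point this is
   (sensitivity + specificity)/2).

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on ROC curves, validation reports
and raw streams.

## Worked example

```r
library(frailscreen)

cfg <- cohort_config(n_participants = 22, duration_days = 0.25,
                     accel_rate_hz = 20, seed = 11)
study <- run_screening_study(cfg)
glance(study$report)
#> # A tibble: 1 × 5
#>   n_pairs n_evaluated mean_auc min_auc max_auc
#>     <int>       <int>    <dbl>   <dbl>   <dbl>
#> 1      16          14    0.734   0.590   0.949
```

16 pairs = 2 screeners × 8 reference variants; two cells are emitted as
not-applicable by design (the gait score against the nonfunctional FRAIL
items, the heart-rate screener against the functional items), leaving 14
evaluated rows. A slice of the formatted report:

```r
format_report(study$report)[9:11, c("screener", "standard", "optimal_cutoff",
                                    "sensitivity", "specificity", "auc")]
#>   screener           standard          optimal_cutoff sensitivity specificity   auc
#> 9 hrr_screener_delta sppb_total                 -21.6        0.93        0.86  0.86
#> 10 hrr_screener_delta sppb_gait_balance         -20.3        0.92        0.78  0.78
#> 11 hrr_screener_delta frail_all                 -22.8        1           0.86  0.95
```

A negative optimal cutoff on the heart-rate screener reads "screen positive
when the post-exertion drop is smaller than |cutoff| bpm". Per-participant
analysis is equally direct:

```r
p  <- study$cohort[1, ]
a  <- generate_accel_stream(p, cfg)
hr <- generate_hr_stream(p, a, cfg)
analyze_participant(a, hr)[, c("mean_cadence_sps", "qualified_step_count",
                               "mean_hrr_bpm", "n_episodes")]
#>   mean_cadence_sps qualified_step_count mean_hrr_bpm n_episodes
#> 1             1.36                  768        22.57          3
```

against a latent truth of cadence 1.36 steps/s and HRR 16.6 bpm for this
participant (three noisy episodes in a 6-hour recording; longer recordings
tighten the estimate).

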