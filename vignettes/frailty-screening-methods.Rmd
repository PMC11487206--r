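---
title: "Methods: wearable frailty screening, from raw streams to diagnostic validity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable frailty screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailscreen)
```

# The screening problem

Frailty and falls risk in community-dwelling older adults are conventionally
assessed with clinic instruments: the five-item FRAIL scale (0 robust, 1–2
prefrail, 3–5 frail), the SPPB (balance + gait speed + chair stand, 0–4
each, 0–12 total), the TUG, 4-m gait speed, and FROP-Com (13 risk factors,
0–60; ≤ 11 low, 12–18 moderate, ≥ 19 high falls risk). An ankle wearable
recording raw triaxial acceleration plus interval heart rate offers a
continuous, unsupervised alternative. This package treats the wearable
statistics as *index screeners* and the clinical instruments as *reference
standards*, and quantifies agreement with the standard diagnostic-test
machinery: 2×2 tables, ROC curves, Youden-optimal cutoffs, trapezoidal AUC.

A useful matching principle runs through the design: movement-related
("functional") constructs — fatigue, stair climbing, 50-m walking, gait
speed, TUG, the SPPB's gait and balance components — are what a gait
analyzer can physically sense, while non-movement ("nonfunctional")
constructs — unintentional weight loss, chronic illness burden — correlate
with cardiovascular reserve and are matched to the heart-rate analyzer. The
validation report therefore emits the gait × FRAIL-nonfunctional and
heart-rate × FRAIL-functional cells as *not applicable* by configuration,
not by inference.

# The analyzers

## Gait

Steps are local maxima of the orientation-independent vector magnitude
$\sqrt{a_x^2+a_y^2+a_z^2}$ above `min_peak_g` (default 1.2 g, i.e. 0.2 g
over gravity), thinned by a refractory interval (default 0.25 s, a
4-steps/s cadence ceiling). Consecutive steps separated by at most
`max_gap_s` (default 3 s — several missed steps at usual cadence; the
continuity of a bout is not otherwise quantifiable from an event list) form
a walking bout, and only bouts holding a **continuous run of ≥ 40 steps**
qualify: shorter runs are segmented but contribute nothing to gait metrics
or step counts. The 39/40 boundary is sharp and property-tested.

Qualifying bouts yield five features: step-count-weighted mean cadence
(steps/s); a swing-power proxy (mean squared magnitude deviation inside
bout windows, g²); a toe-off proxy (mean step peak magnitude, g); the
coefficient of variation of within-bout inter-step intervals; and the
qualified step count. The two magnitude proxies are *defined surrogates*
for unpublished biomechanical quantities: they preserve a monotone
relationship with gait vigor while being fully specified from the
accelerometer alone. The gait risk score counts impaired features (0–5).
Cutoffs mix literature-anchored absolutes (cadence < 1.4 steps/s, CV >
0.10) with cohort-relative lowest-quartile cutoffs for the device-specific
proxies and step count; all are overridable, and with fewer than four
scored participants the quartile cutoffs fall back to fixed defaults.

## Daily-living energy

Epoch energy is the mean squared deviation of the vector magnitude from the
1-g baseline over a fixed epoch (default 60 s), in g². The published device
computes an energy quantity whose exact formula is not public; the
mean-square deviation is the field's standard surrogate and is documented
here as a reconstruction. Energy is expressed relative to the energy of
walking at 1 step/second, measured from the participant's own qualifying
bouts: bout power is divided by cadence² (for a fixed gait waveform whose
impulse amplitude grows with $\sqrt{\text{cadence}}$, signal power scales
with cadence², so the rescaled value is cadence-invariant) and averaged
with step-count weights. Recordings without qualifying walking fall back to
a configured reference and record the provenance.

Intensity bands are exact: light < 10%, moderate ≥ 10 and < 30%, high
≥ 30% of the walking reference; 10.0% is moderate and 30.0% is high. Daily
kilocalories use a calibrated affine conversion
$\text{kcal} = \text{basal} + k \sum_e (\text{intensity}_e/100)\,h_e$ with
basal = 400 kcal and $k$ = 250 kcal per walking-equivalent hour, chosen
once so that a plausible active day (about 2 h of moderate household
activity plus half an hour at walking level) lands inside the middle
521–770 kcal band; the band edges themselves (521, 770, middle closed on
both ends) are fixed. The kilocalorie *classes* are exact; the conversion
is an explicit configuration, not a validated energy-expenditure model.

## Heart-rate recovery

The conventional HRR protocol (exercise to a target, rest a fixed interval,
re-measure) is impractical in free living, so exertion is found from the
data: every maximal run of high-intensity epochs is an exertion candidate.
Within a run, the maximum heart-rate sample is the episode peak (earliest
sample on ties — the deterministic choice that maximizes the recovery
window), and the **next interval sample after the peak** is the recovered
heart rate, required to arrive within one sampling interval plus 10% slack
(for jittered streams). HRR = peak − recovered; a run whose peak is the
final recorded sample is discarded. The per-participant statistic is the
arithmetic mean over episodes; its negation, the *screener delta*
(recovered − peak), is what validation consumes, so a cutoff of −14 bpm
reads "a drop smaller than 14 bpm screens positive" and higher
(less-negative) values are screen-positive. An alternative reading of the
protocol — recovery at a fixed 5-minute lag rather than the next scheduled
sample — coincides with the implemented rule under strictly periodic
sampling, which is the default; under jitter the tolerance covers the
difference.

Participants with zero episodes get an explicitly missing statistic and are
dropped pairwise from validation (with counts carried in the report), never
imputed.

# The validation engine

`contingency()` cross-tabulates screener calls against condition labels;
`diagnostics()` reports sensitivity, specificity, TPR, FPR, PPV, NPV, with
any zero-denominator cell returned as `NA` — explicitly undefined, never
coerced to 0 or 1. `roc_curve()` sweeps **midpoints between consecutive
distinct scores** plus ∓∞ anchors, so strict-versus-non-strict boundary
semantics can never change an operating point, and the (0,0) and (1,1)
anchors are always present. The Youden-optimal cutoff maximizes
J = TPR − FPR with ties broken toward higher specificity, then the lower
cutoff — a deterministic rule verified against exhaustive threshold
enumeration. AUC is the trapezoid sum over fpr-sorted points; for a
single-operating-point curve it reduces to (sensitivity + specificity)/2, a
relationship the tests exercise directly, and on dense binormal scores it
matches the closed form $\Phi(d/\sqrt2)$ to Monte Carlo precision.

The reference standards are dichotomized with standard geriatric cutpoints
(SPPB total ≤ 9; gait+balance subset ≤ 6; gait speed < 0.8 m/s; TUG
≥ 13.5 s; any FRAIL deficit, functional deficit, or nonfunctional deficit
≥ 1; FROP-Com ≥ 12, i.e. moderate-or-high risk; ≥ 1 fall in 12 months).
The exact rule text travels with every label row, and all thresholds are
free parameters so alternative choices can be explored; published summary
tables in this area typically do not state their dichotomization rules, so
these defaults are the package's own documented choice. For display the
report rounds half-up at two decimals (`format_report()`); internal values
keep full precision.

# What the generator simulates — and what it does not

The generator is first-class, tested code, and its defaults are the study
conditions the analyses assume:

* **Cohort**: n = 22, robust/prefrail/frail drawn with probabilities
  0.41/0.45/0.14; class-conditional assessments tuned so the cohort means
  sit near a typical community sample (SPPB components ≈ 3.3/3.0/2.3, gait
  speed ≈ 0.83 m/s, TUG ≈ 13.7 s, faller fraction ≈ 0.36). A single
  `assessment_noise` knob (default 0.1) occasionally perturbs the FRAIL
  deficit count by ±1, so assessed category agrees with latent class for at
  least 80% of participants — one dial for agreement experiments.
* **Latent physiology**: true HRR means 25/18/10 bpm
  (robust/prefrail/frail) with 4 bpm spread — the prefrail mean is not
  externally anchored and was fixed a priori between its neighbours;
  cadence is coupled to gait speed (`0.55 + 1.35·speed` plus small noise),
  giving the positive speed–cadence rank correlation the gait score relies
  on.
* **Accelerometer**: 1-g gravity baseline on the vertical axis; each step a
  raised-cosine impulse (width 0.3 s) whose amplitude is
  `step_amp_g·√cadence` (default 0.6 g at 1 step/s), the simplest shape a
  peak detector recovers exactly and the scaling that makes walking power
  ∝ cadence²; sinusoidal moderate blocks tuned to 18% of the walking
  reference; Gaussian per-axis noise (default 0.02 g). Long exercise-like
  walks fill whole epochs so every bout epoch is unambiguously in the high
  band and exertion windows coincide with the intensity grid; short errand
  bouts alternate below/above the 40-step rule. Activity blocks are
  separated by at least six rest epochs so heart-rate episodes never merge.
* **Heart rate**: strictly periodic sampling from t = 0 (default 300 s), a
  monotone ramp to resting + 55 bpm across each exertion window, and a
  post-window sample at exactly peak − true HRR before noise — which is
  what makes the generator/analyzer closure exact at zero noise and the
  estimator unbiased under noise. Values are clamped to 30–220 bpm.
* **Units**: acceleration in g, time in seconds from recording start, heart
  rate in bpm, fixed throughout to prevent silent unit bugs.

Unmodelled, deliberately: gyroscope/compass channels,
photoplethysmography waveforms (only interval HR values), terrain and
stairs, posture and sleep, orientation drift, device artefacts, and any
correlation between activity volume and HRR beyond the class structure.
Passing tests therefore demonstrate *internal* correctness — the analyzers
recover what the generator injected, the statistics match their oracles —
not field validity on real recordings, which would require the lab-validated
biomechanics chain this package intentionally replaces with defined proxies.

# Numerical and edge-case conventions

* Step detection: plateaus keep their first sample
  (`mag[i] ≥ mag[i−1] & mag[i] > mag[i+1]`); refractory thinning is greedy
  in time order. Empty streams yield empty event lists; nonmonotone
  timestamps are an input-format error.
* Single-step bouts have undefined cadence (`NA`); cadence is
  (n−1)/(tₗₐₛₜ−t_first) otherwise.
* No qualifying bout ⇒ an explicit `insufficient` marker, not an exception;
  downstream excludes and logs the participant.
* A constant-gravity stream has exactly zero epoch energy; an epoch
  spanning fewer than two samples is a configuration error.
* Recordings shorter than a day produce a `partial` daily summary, still
  computed; hourly energy is normalized by the day's maximum hour.
* ROC requires both classes; a single-class condition is an error naming
  the standard, which the report converts into an annotated row rather than
  a crash. A screener missing for more than half the cohort aborts the
  report.

# Problem sizes

The shipped tests and the acceptance script use 20–25 Hz sampling,
6-hour to quarter-day recordings, and cohorts of 22 (study-scale runs),
100 (parameter recovery, three seeded replicates) and 200 (distributional
checks) — sizes chosen to exercise every code path and estimator property
at comfortable runtimes. The defaults the package ships (50 Hz, 1-day
recordings) are the recommended simulation conditions for interactive use;
nothing in the implementation depends on the reduced sizes.

# Known limitations

* The gait score's five features are coarse (integer 0–5), so ROC curves
  against continuous standards have few operating points; with 22
  participants the optimal cutoff is volatile across seeds, exactly as in
  small validation studies.
* The energy formula, kilocalorie conversion and dichotomization thresholds
  are reconstructions/configurations where the published pipeline is
  silent; they are prominently parameterized rather than hidden.
* The HRR protocol believes the intensity series: exertion without ankle
  movement (e.g. cycling with a still ankle would in reality be high
  effort) is invisible to an ankle device, and the generator does not
  simulate that failure mode.
* No confidence intervals or correlated-ROC tests are produced; the
  engine reports point operating characteristics only.
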