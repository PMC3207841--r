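---
title: "Methods: periorbital temperature extraction and startle analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: periorbital temperature extraction and startle analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periotherm)
```

## The problem

The skin over the inner canthus of the eye, perfused by the angular artery
and vein, is among the warmest regions of the face and a candidate signal
source for thermography-based access technology — systems that translate a
residual physiological signal into communication for people with total
locked-in syndrome. Such a system must not fire on involuntary reactions.
The analysis implemented here asks whether an unexpected auditory startle
stimulus changes inner-canthus temperature: thermal video is tracked, a
robust per-frame temperature summary is extracted and filtered, 2-s
windows on either side of the stimulus are summarised by six measures
(range, mean, variance, skewness, Pearson kurtosis, histogram Shannon
entropy), and the measures are compared in a three-way repeated-measures
mixed ANOVA (window × side fixed, participant random). Because no raw
video of the original experiment is available, every stage is driven and
validated by a synthetic thermal-video generator with exact ground truth.

## The synthetic phantom

A frame is built in Kelvin as

$$T(r, c) = T_{bg} + (T_{face} - T_{bg})\,\mathbf{1}_{ellipse}(r, c)
  + \sum_{k=1}^{2} A_k \exp\!\left(-\frac{(r - r_k)^2 + (c - c_k)^2}
  {2\sigma^2}\right) + \varepsilon(r, c),$$

with $A_k = T_{peak} + d(t) + e(t) - T_{face}$, so the pixel at a hot-spot
centre equals exactly $T_{peak} + d(t) + e(t)$: $d(t)$ is a slow baseline
drift and $e(t)$ an optional injected stimulus effect. $\varepsilon$ is
i.i.d. Gaussian sensor noise. Motion is an integer-pixel random walk of
both hot spots; on startle trials a sudden jerk of configurable magnitude
is added at a random time within 3 s of the stimulus. Integer-pixel motion
is chosen deliberately: it makes block-matching ground truth exact, so
tracker correctness can be asserted to the pixel rather than to a
tolerance.

Key defaults (all changeable through `phantom_config()`):

* **15 Hz video, 30 s trials, stimulus uniform on [2 s, 23 s]** — the
  acquisition conditions the pipeline targets; the stimulus window keeps
  2 s of pre-stimulus and 7 s of post-stimulus context inside the trial.
* **Frame 120 × 160 px, hot-spot σ = 3 px, tracking box 11 × 15 px** — a
  geometrically scaled-down scene (the full 640 × 480 with proportionally
  larger boxes is available by overriding the geometry fields together).
  The box-to-structure proportion matters more than absolute size: the
  box must be small enough that the hot spot fills most of it, or the MSE
  surface develops a flat "moat" around the optimum that defeats any
  gradient-style search.
* **Temperatures: background 295 K, face 305.5 K, canthus peak 307.5 K** —
  room, facial skin, and the reported canthus scale.
* **Sensor noise 0.03 K/px** — typical uncooled-microbolometer NETD.
* **Drift: rms 0.05 K, timescale 10 s** — white noise low-passed at
  1/timescale and rescaled to the target rms; the simplest process with
  smooth wandering paths that a full-trial runs test rejects, emulating
  the pervasive non-stationarity of real facial temperature. The true
  drift magnitude of periorbital skin is not characterised; 0.05 K over a
  30-s trial is a free but fixed choice.
* **Jitter sd 0.5 px/frame; startle jerk 5 px; startle probability
  94/534** — small seated head motion, a visible flinch, and the observed
  fraction of stimulus trials with a visible startle.
* **Injected effect: delta 0 K (the null), onset latency 0.3 s, ramp
  1 s** — the null default matches the finding the pipeline reproduces; a
  non-zero delta ramps linearly to full size over 1 s starting 300 ms
  after the stimulus (the latency at which earlier literature claimed a
  periorbital warming). The mean of the ramp over the post window gives a
  closed-form conversion from delta to the expected post-stimulus mean
  shift (≈ 0.6 delta for a 2-s window), used by the recovery tests.
* **Participant baseline sd 0.3 K** — between-participant temperature
  variation, drawn once per participant; it dominates the between-cell
  variation, as the reported between-condition spread (~0.4 K) suggests.

### Two rendering paths

`render = "frames"` produces the full video for the tracking and
extraction stages. `render = "series"` skips rendering and directly
generates the per-side extracted series as
`peak + participant offset + drift + effect + N(0, series_noise_sd)`,
with drift and effect shared between sides and independent per-side
fluctuation. The series path is what makes study-scale simulation (tens
of thousands of trials) tractable; its fluctuation scale
(`series_noise_sd = 0.0327 K`) is calibrated so the 2 Hz-filtered
marginal variance equals 3 × 10⁻⁴ K², the reported window-variance
scale. The filter's white-noise power gain, computed by integrating
|H(f)|² over the band, is 0.2807, giving
`0.0327 = sqrt(3e-4 / 0.2807)`. The video path is validated separately
(tracking and trim-suppression checks); statistical calibration results
obtained on the series path therefore say nothing extra about tracking —
and conversely.

### Reproducibility

A single study seed determines everything. Per-participant, per-session
and per-trial substream seeds are derived deterministically from the
indices (two fixed LCG steps around an index mix, kept below 2³¹), so any
trial can be regenerated in isolation and identical seeds give
bit-identical studies.

## Tracking

Both inner-canthus boxes are tracked by block matching with the
mean-squared-error criterion; the reference block is cut once, from the
first frame, and never re-templated (re-templating accumulates drift; a
fixed reference matches the "regions set manually once per trial"
protocol). The search is a logarithmic cross search: at the current step
size the centre and the four diagonal (×-shaped) neighbours are scored;
the search moves to the best candidate, repeating at the same step until
the centre wins, then halves the step. At step 1 the full 8-neighbourhood
is hill-climbed. Two details are deliberate design choices rather than
received algorithm:

* **Repeat-before-halving.** A variant that halves after every move can
  only reach displacements whose row and column sums share a parity
  (diagonal moves change both coordinates by the same step), so many
  small displacements — for example (3, −2) — are unreachable no matter
  the data. Repeating at the current step, plus the 8-neighbourhood final
  stage, makes every displacement within range reachable, and on a
  noiseless translated phantom the search provably terminates at the
  global optimum of the (unimodal) MSE surface. The cost stays far below
  exhaustive search: ~30 block scores against 289 for a radius-8 scan.
* **Tie-breaking.** Exact score ties (common on noiseless synthetic
  scenes) are resolved by smaller |Δrow| + |Δcol|, then row-major order —
  deterministic, and favouring no motion.

An exhaustive search over a square radius (`full_search()`) with the same
tie rule is shipped as the independent oracle and is used by the tests.

Tracking **fails** — and the trial is quarantined as unusable — when the
box can no longer be placed inside the frame, or when the winning MSE
exceeds 25× the median winning MSE of the trial's first 15 frames for 5
consecutive frames. The original analysis flagged unusable trials by
inspection without a numeric rule; this rule reproduces its effect (a
region walking off the face or out of frame blows the score up by orders
of magnitude within a few frames, while noise keeps it near 2σ²).

Coordinates are 1-based `(row, col)` with inclusive box extents
throughout, the natural R convention.

## Extraction

Per frame, the region temperature is the **upper 50% trimmed mean**: the
mean of the warmest ⌈N/2⌉ pixels of the tracked box. The warm perfused
core always ranks at the top, so the statistic is determined by the same
physical pixels however the box wobbles; the cool border pixels that slip
in and out as the box jitters by a pixel or two are discarded wholesale.
On a noiseless phantom whose warmest half stays inside the jittered box
the trimmed series is *exactly* constant, and with realistic noise the
trimmed-and-filtered series retains under a few percent of the plain
mean's jitter variance when the box border crosses a temperature step.
Equal-valued pixels at the trim boundary are interchangeable — ties
cannot affect the mean. `fraction = 1` yields the plain mean, kept only
as a diagnostic.

The series is then low-pass filtered by a **second-order Butterworth at
2 Hz** (bilinear design, −3.01 dB at the cut-off, DC gain exactly 1),
applied **causally in a single pass**: "second-order" is taken literally,
so no zero-phase forward–backward pass (which would square the order and
acausally smear the stimulus onset). The startup transient is suppressed
by initialising at the steady state of the first sample — implemented by
filtering `x − x[1]` from rest and adding `x[1]` back, exact because the
DC gain is 1. Whether the original filter was causal or zero-phase is not
recorded; causal is the conservative reading and the one that cannot leak
post-stimulus signal into the pre-stimulus window.

**Windows.** The pre window covers `[t_stim − 2 s, t_stim]` and the post
window `[t_stim, t_stim + 2 s]`, both endpoint-inclusive: 31 samples each
at 15 Hz, sharing the boundary sample. The inclusive-31 convention is an
inference from the reported entropy level: 30-sample windows are capped
at log₂30 ≈ 4.907 bits, below the reported 4.91–4.92, while 31 mostly
tie-free samples average log₂31 ≈ 4.954 minus an expected tie loss of
≈ 0.03 bits — exactly the reported value. The Monte-Carlo calibration in
the test suite confirms 4.92 ± 0.01 under the null model.

## Window statistics and tests

* **Moments** use biased (1/n) central-moment estimators; kurtosis is the
  Pearson ratio m₄/m₂² (normal → 3). Short, serially correlated windows
  bias Pearson kurtosis well below 3 — the simulated null reproduces the
  reported ≈ 2.25 without any tuning. Constant windows get range and
  variance 0 and NA shape statistics, flagged `degenerate`.
* **Entropy**: histogram with 1000 equal-width bins spanning the window's
  own min and max (final bin closed), counts normalised by the sample
  size, H = −Σ p log₂ p with 0·log 0 ≡ 0; a constant window has H = 0.
  Because the bins span the observed range, H is scale- and
  shift-invariant; only the dependence structure and ties matter.
* **Normality** is screened by a chi-squared goodness-of-fit test with
  bins equiprobable under the fitted normal, bin count chosen to keep
  expected counts ≥ 5 (six bins at n = 31), statistic on k − 3 degrees of
  freedom. The binning rule is a convention (the original is unstated).
  The test assumes independent samples; on 2 Hz-filtered windows its
  rejection rate rises from ~6.5% to ~11%, which is worth knowing when
  comparing against pass rates quoted for real data.
* **Stationarity** uses the Wald–Wolfowitz runs test about the series
  median (median-equal values dropped), normal approximation, two-sided,
  at 5%. A median split is the standard construction for trend detection;
  the original names only "the runs test". Degenerate splits (fewer than
  2 values on a side) return an explicit indeterminate flag.

## The mixed ANOVA

Each of the six measures is compared in a three-factor mixed ANOVA:
window (pre/post) and side (left/right) fixed, participant random.
Trials are replicates within a (participant × window × side) cell; cell
means are taken per participant first and the classical repeated-measures
decomposition is fitted on the resulting P × 2 × 2 table
(`aov` with `Error(participant/(window*side))`). This unweighted-means
solution keeps the expected-mean-squares denominators valid when
post-exclusion trial counts differ between cells — each fixed effect is
tested against its interaction with participant. Whether the original
replicates were trials or participant means is not recorded; the
unweighted-means choice is the one that preserves the mixed-model
denominators without full REML machinery (REML is out of scope). F and p
are recomputed from the stratum sums of squares, with an explicit guard:
a numerically zero interaction mean square (an exactly reproduced effect)
reports F = ∞, p = 0 and a flag instead of NaN. No multiple-testing
correction is applied across the six measures, matching the original
per-measure reporting.

With 4 participants the window test has 1 and 3 degrees of freedom; the
200-study calibration in the acceptance suite shows the nominal 5% size
holds, and an injected 0.3 K effect (≈ 0.18 K expected post-window shift
against a 0.017 K window sd) is detected essentially always.

## Startle detection

The original study identified trials with a visible formal startle by
watching the video for sudden movement within 3 s of the stimulus. The
automated stand-in thresholds frame-to-frame motion energy (mean squared
temperature difference between consecutive frames, offset-invariant by
construction): a trial is flagged when the post-stimulus maximum within
(t_stim, t_stim + 3 s] exceeds
`median(pre) + 6 · max(MAD(pre), median(pre))`. The MAD floor is
essential under integer-pixel motion: the motion-energy distribution is a
discrete mixture of a noise floor (2σ²) and a few spike levels (~0.003 K²
for a 1-px step, ~0.01 for 2 px, ~0.05 for a 5-px jerk), on which a bare
MAD either collapses to the noise spread or sits between spike levels;
flooring it at the median makes the threshold a multiple of the trial's
typical jitter energy, separating ordinary jitter from jerks by a wide
margin. The threshold (6 robust units) is a free parameter standing in
for a human judgement; no quantitative criterion exists to match.

## What the generator does and does not emulate

The phantom reproduces the features the analysis is sensitive to: warm
elliptical canthus structure on a cooler face, integer head jitter with
occasional stimulus-locked jerks, slow non-stationary drift, sensor
noise, between-participant baselines, balanced randomly interleaved
stimulus scheduling, and an optional stimulus-locked warming. It does
**not** emulate: sub-pixel motion or rotation (tracking ground truth is
exact by construction), facial texture and anatomical asymmetry,
occlusion and specular effects, emissivity/humidity physics, ambient
coupling between the anemometer record and the scene, or the audio
stimulus itself (metadata only). Passing tests therefore certify the
pipeline's arithmetic and statistical behaviour under these idealised
conditions — not tracker robustness on real, texture-rich, sub-pixel
moving faces, which the original authors themselves note requires a more
robust tracker in clinical use.

One geometric subtlety is worth making explicit: the trim-suppression
property needs cool *structured* border pixels inside the tracking box.
On a uniform face plateau, a box far from any edge sees no border
variation for the trim to remove. The suppression checks therefore place
one canthus near the face-ellipse boundary so the box border crosses the
face/background step — the same mechanism (cool border pixels entering
the box under jitter) that motivates the trimmed mean on real faces.

## Numerical and degenerate-input conventions

* All temperature arithmetic is double precision; the 0.1 mK source
  resolution is preserved end to end (the TIFF writer's affine mapping
  round-trips at ~2 × 10⁻⁸ K).
* Frame stacks are stored as multi-page 32-bit float TIFF with values
  mapped to [0, 1] over a Kelvin range recorded in the JSON sidecar;
  configurations serialise to JSON at 17 significant digits so round
  trips are lossless.
* Degenerate inputs never crash the pipeline: constant windows, one-sided
  median splits, zero-variance fits, empty startle subsets and failed
  tracks all return explicit flags or quarantine the trial; a study run
  never aborts on a single trial.
* Problem sizes in the shipped tests are the package's own choices for a
  thorough-but-quick suite: 10⁴ windows for the entropy calibration, 100
  translation pairs for the tracker checks, 50 trials for trim
  suppression, 200 trials/5000 replicates for the runs-test pair, 200 +
  100 studies of 4 × 2 × 10 for the ANOVA size/power pair.

## Known limitations

* The cross search is correct for the phantom's smooth unimodal MSE
  surfaces; with a tracking box much larger than the warm structure the
  surface develops flat regions and partial-overlap ridges where any
  logarithmic search can alias. Box size should track structure size.
* The runs test's normal approximation is slightly conservative at
  trial length (n = 450); the chi-squared normality screen is
  anticonservative on filtered windows (see above).
* The series-level path models the *extracted* series directly; it
  carries no tracking error, so exclusion rates on that path are zero by
  construction and trial accounting at full study scale exercises only
  the bookkeeping, not the tracker.
* `startle_prob` and the detector threshold are free parameters; the
  startle-subset sizes the pipeline reports on synthetic studies are
  governed by them, not discovered.
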