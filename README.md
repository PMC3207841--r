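# periotherm

Periorbital skin-temperature analysis for thermal-video startle studies.

Infrared thermography of the inner canthi — the warm skin at the inner
corners of the eyes, overlying the angular artery and vein — is a
candidate input channel for access technology serving people with total
locked-in syndrome. Before such a system can be trusted, one must know
whether the involuntary startle response perturbs periorbital
temperature and could fire false positives. `periotherm` implements the
complete analysis pipeline for that question as tested, reusable R
components, driven by a synthetic thermal-video generator with exact
ground truth so every stage is verifiable without access to raw study
video.

## What the package computes

For each 30-s trial of 15 Hz radiometric video (temperature pixels in
Kelvin):

1. **Tracking** — both inner-canthus boxes are followed by cross-search
   block matching with the mean-squared-error criterion
   (`cross_search()`, `track_region()`), with an exhaustive-search
   oracle (`full_search()`) for verification. Trials whose regions
   cannot be tracked are flagged unusable.
2. **Extraction** — per frame, the region temperature is the upper 50%
   trimmed mean of the box pixels (mean of the warmest half,
   `trimmed_mean_upper()`), robust to cool border pixels entering the
   box as it wobbles; the series is low-pass filtered by a causal
   second-order Butterworth at 2 Hz (`lowpass()`; −3 dB at cut-off, DC
   gain 1).
3. **Windows** — 2-s pre- and post-stimulus windows (31 samples each,
   endpoint-inclusive, sharing the boundary sample at the stimulus) are
   cut relative to the stimulus time (`extract_windows()`).
4. **Statistics** — per window: range, mean, biased variance, skewness
   `m3/m2^1.5`, Pearson kurtosis `m4/m2^2`, and Shannon entropy over a
   1000-bin histogram spanning the window's min–max
   (`window_stats()`, `shannon_entropy()`); per trial: chi-squared
   normality screen (`chi2_normality()`) and Wald–Wolfowitz runs test
   for stationarity (`runs_test()`).
5. **Inference** — each measure enters a three-way repeated-measures
   mixed ANOVA, window (pre/post) × side (left/right) fixed,
   participant random, fixed effects tested against their participant
   interactions on per-cell means (`mixed_anova()`); group-mean tables
   with significance marks come from `build_report()`.
6. **Startle detection and accounting** — sudden movement within 3 s of
   the stimulus is detected from frame-difference motion energy
   (`detect_formal_startle()`), and `account_trials()` tallies
   usable/unusable and startle-subset counts.

`run_study()` orchestrates all stages over a simulated multi-participant
study (`simulate_study()` / `simulate_trial()`), quarantining failing
trials rather than aborting.

## Worked example

A scaled-down null study — 4 participants × 2 sessions × 10 trials, half
with stimulus, no injected temperature effect:

```r
library(periotherm)
cfg <- study_config(n_participants = 4, n_sessions = 2, n_trials = 10,
                    seed = 42)
res <- run_study(cfg)
print(res)
#> Of the 80 trials (40 with stimulus), 0 were unusable (0 stimulus, 0 non-stimulus).
#> Of the 40 usable stimulus trials, 9 contained a visible formal startle response.

res$anova$all_stimulus$mean
#> Mixed repeated-measures ANOVA on 'mean' (4 participants)
#>       effect df     sumsq    meansq df_denom denom_meansq statistic p.value
#>  participant  3 7.729e-01 2.576e-01       NA           NA        NA      NA
#>       window  1 4.617e-06 4.617e-06        3    2.746e-04   0.01682  0.9050
#>         side  1 8.867e-06 8.867e-06        3    9.358e-06   0.94753  0.4021
#>  window:side  1 7.682e-07 7.682e-07        3    2.147e-06   0.35771  0.5919
```

The window effect on the mean is far from significant (p = 0.90): the
stimulus leaves mean periorbital temperature unchanged under the null
model, while the participant stratum absorbs the large between-person
baseline differences. The group-mean table shows the same picture on the
measurement scale:

```r
subset(res$report$subsets$all_stimulus$table,
       measure %in% c("mean", "entropy") & factor == "window")
#>    measure factor level       mean         sd   sig
#> 5     mean window   pre 307.450707 0.22694841 FALSE
#> 6     mean window  post 307.449632 0.22459159 FALSE
#> 21 entropy window   pre   4.920827 0.05196444 FALSE
#> 22 entropy window  post   4.918712 0.04579270 FALSE
```

Pre and post means agree to a millikelvin around 307.45 K, and window
entropy sits at 4.92 bits — the ceiling log2(31) ≈ 4.95 for a 31-sample
window minus the expected tie loss. Every full-trial series is flagged
non-stationary by the runs test (`mean(res$runs$nonstationary)` is 1),
driven by the slow baseline drift in the generator. Injecting an effect
(`phantom_config(effect_delta = 0.3)`) makes the window effect highly
significant — the pipeline detects a 0.3 K post-stimulus warming
essentially always at this study size.

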