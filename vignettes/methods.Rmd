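---
title: "Models and methods: pupillometry and oscillatory power under phasic auricular stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phasicpupil` implements the analysis chain of a two-task experiment in
which short (500 ms, 30 Hz) trains of transcutaneous auricular vagus
nerve stimulation (taVNS) or sham stimulation are delivered at stimulus
onset while pupil size and MEG-like brain signals are recorded.  The two
tasks are a conflict (emotional Stroop) task — categorize a face's
emotion while ignoring an overlaid congruent or incongruent word — and a
passive pupil light reflex task (PLRT) in which a 500 ms bright flash
elicits a constriction.  Because no recordings ship with the package,
every stage is exercised against a seeded synthetic-data generator whose
effect sizes default to the published group-level values; this vignette
documents the models, the generator, and the numerical choices, and
states explicitly what passing tests do and do not show about real data.

## The synthetic-data generator

`study_design()` fixes the paradigm structure (29 subjects, six
20-trial conflict blocks and one 20-trial flash block per stimulation
condition, 500 Hz pupillometry, 1000 Hz electrophysiology,
counterbalanced stimulation order).  `effect_spec()` fixes the
generative effect sizes:

* **Behaviour.** Trial correctness follows a logistic mixed model with
  subject random intercepts and independent random slopes for
  stimulation and congruency.  The default fixed effects are the
  published log-odds values — congruency 0.92, stimulation 0.44, trial
  number 0.005 (odds ratios 2.51, 1.55, 1.005), plus small face,
  intensity and interaction terms.  Reaction times follow a linear
  mixed model with a −53.81 ms congruent-trial shift and a −0.49 ms
  per-trial practice slope.  Stimulation intensity is drawn per subject
  and condition around 1.91/1.87 mA and centered at 1.89 mA in the
  linear predictor.
* **Conflict-task pupil traces.** Each session trace is baseline
  (1000 a.u.) + slow drift + a hippus-like band-limited oscillation +
  per-trial picture-evoked constriction (raised cosine, 30 a.u. over
  1 s) + a gamma-shaped dilation peaking 1.3 s post-stimulus whose
  amplitude carries the condition effects (incongruent +7 a.u., active
  stimulation +13.5 a.u. on a 40 a.u. base), + blink artifacts +
  recorder quantization (0.1 a.u.).
* **Light-reflex traces.** `plr_template()` is flat until the onset
  latency, then an exponential-approach constriction (time constant
  0.7 s) multiplied by an exponential redilation (2.5 s), scaled so the
  minimum equals −amplitude; the peak falls at
  `latency + 0.7 * log(1 + 2.5/0.7)` ≈ latency + 0.89 s.  Defaults put
  the sham onset at 170.83 ms with a +27.09 ms delay and a 0.925
  amplitude scaling under active stimulation, matching the published
  condition means.  The onset is a slope discontinuity, which makes the
  most-negative-acceleration latency definition sharply identifiable.
* **MEG-like signals.** 1/f background plus trial-locked band-limited
  oscillations: theta (4.5–7.5 Hz) on frontal-midline channels, alpha
  (9–12.5 Hz) on occipital-midline channels.  Post-stimulus power is
  scaled by condition (theta ×1.3 under active stimulation, ×1.15 on
  incongruent trials; alpha ×0.75 under active stimulation) while the
  pre-stimulus baseline amplitude is common, so decibel baselining
  exposes the effects.  A 4 ms biphasic transient at 50× the signal SD
  follows each of the 15 pulse markers per 500 ms train, deliberately
  inside the 10 ms blanking window.

### Why the pupil noise is band-limited, not white

The two-pass cleaning procedure thresholds at
`median + 2.5 × MAD` of (1) the dilation-speed series and (2) the
deviation-from-trend series.  That rule flags a fixed upper quantile of
any *Gaussian-shaped* series regardless of its scale (about 9 % of
samples), so a generator with broadband white noise could never satisfy
the intended "clean data are not flagged" behaviour — and real pupil
traces are not white either: the pupil is a slow plant, and recorder
noise is dominated by quantization.  The generator therefore uses a
narrowband hippus-like oscillation (3–4 Hz, SD 15 a.u.) plus a slow
drift and integer-like quantization.  Such series have bounded,
light-tailed speed and deviation distributions, so the MAD thresholds
sit above the artifact-free signal and flag essentially only the blink
spikes.  Consequences to keep in mind: the measured false-flag rate
(<1 %) is a property of band-limited noise; on recordings with
substantial broadband noise the same procedure will flag a few percent
of genuine samples, as it does in practice.  Similarly, the constriction
time constant (0.7 s, peak constriction ≈ 1.05 s post-flash, within the
physiological range) keeps the reflex's own dilation speed below the
artifact threshold; with a much faster synthetic constriction the
cleaning clips the onset corner and biases extracted latencies downward
by tens of milliseconds — a real interaction worth knowing about when
applying MAD cleaning to light-reflex data.

## Pupil preprocessing

Continuous traces are cleaned (`two_pass_clean()`), epoched −2…5 s
(conflict task) or −2…7 s (PLRT) around stimulus onset
(`epoch_trials()`; the onset sample is the nearest recorded sample, so a
(−2, 5) s window at 500 Hz has 3501 samples), subjected to the strict
rejection rules (`reject_missing()`: trials with more than 50 % missing
samples; subjects with more than 50 % rejected trials in any single
condition), and normalized (`normalize_epochs()`).

Numerical choices, all config-exposed via `clean_config()`:

* *Dilation speed* is the larger of the backward and forward absolute
  difference quotients with actual timestamps; endpoints use their
  single neighbour; missing samples propagate.
* *Second pass* measures absolute deviation from a trend line formed by
  linear interpolation of first-pass gaps followed by a centered 100 ms
  moving average (window shrinks at the edges — no phase shift, no
  extrapolation); the threshold is recomputed on the deviation series
  with the same constant 2.5.
* *Interpolation* is linear and interior-only: leading/trailing missing
  runs stay missing and count toward the >50 % rule.
* *z-scoring scope* is per subject-session over all retained samples
  (the scope is not dictated by the procedure itself; per-condition
  scoring would absorb condition differences, so the pooled scope is
  the default).
* *Baseline* is the closed-open window [−200 ms, 0): the onset sample
  belongs to post-stimulus time.  *Downsampling* to 100 Hz is
  decimation after cleaning and smoothing; the retained band is far
  below the post-smoothing Nyquist frequency, so no extra anti-alias
  filter is applied.

## Light-reflex kinematics

`extract_plr()` works on the (typically trial-averaged) normalized
trace: peak constriction amplitude is the most negative post-stimulus
value; velocity and acceleration come from central differences (exact
for polynomials up to degree two, amplitude attenuation
`sinc(2*pi*f*dt)` on tones — 1.6 % at 5 Hz and 100 Hz sampling); the
constriction onset is the most negative acceleration in the first
period of the second derivative, interpreted as the interval from
stimulus onset to the peak constriction (the acceleration minimum of a
constriction necessarily precedes its amplitude minimum).  Constriction
velocities are computed on [onset, peak] including both endpoint
samples, redilation velocities on (peak, end].  Optional pre-smoothing
(`smooth_ms`) is off by default so analytic templates are recovered
exactly; on band-limited noise the unsmoothed acceleration minimum is
already robust because the onset kink dominates the curvature.

## Artifact removal and spectra

`blank_pulses()` replaces 10 ms after each pulse marker with missing
values (overlapping windows merge).  `ar_fill()` fits a Burg
autoregressive model on up to 25 ms of valid context on each side of a
gap — order `floor(context/2)` capped at 16, a choice this package fixes
rather than inherits (half the context length reconstructs mixed tones
noticeably better than shorter orders at this context) — and
cross-fades the forward and time-reversed
backward predictions with a linear ramp; one-sided prediction is used
when only one side has context, and a gap with no usable context falls
back to linear interpolation with a warning.  With the 25 ms context the
mean reconstruction NRMSE over band-limited (≤30 Hz) two-tone test
signals is ≈0.07–0.10 depending on the draw; the hard cases are tone
pairs a few hertz apart, which a 25 ms window cannot resolve (its
Rayleigh resolution is 40 Hz), so no order choice recovers them — a
40 ms context brings every draw under 0.1 if a user needs that.

`filter_chain()` applies zero-phase (forward-backward) 4th-order
Butterworth filters: high-pass 1 Hz, low-pass 60 Hz, band-stop
49–51 Hz, in that order.  `epoch_and_baseline()` cuts −2…5 s epochs,
decimates to 250 Hz (safe after the 60 Hz low-pass) and subtracts the
200 ms pre-stimulus mean, retaining the per-trial baselines for
baseline-comparison models.

`fft_power()` estimates power from a Hann-tapered 500 ms window directly
after stimulus onset, zero-padded so the FFT bins land exactly on the
2–14 Hz, 0.5 Hz grid (the window's native Rayleigh resolution is 2 Hz;
the padding interpolates the spectrum, it does not add resolution).
`morlet_tfr()` uses 5-cycle complex Morlet wavelets on a 40 ms time
grid, flagging bins within half a wavelet support of an epoch edge;
`db_baseline()` converts to decibels relative to the −500…−200 ms
window.

## Mixed models and cluster-based permutation testing

`fit_mixed()` wraps `lme4` with a documented fallback ladder (random
slopes → random intercepts; failures are flagged results, not errors;
singular fits are flagged, not fatal).  Per-predictor p-values come from
type-II likelihood-ratio chi-square tests (`lrt_table()`): each term is
tested against a model differing only in that term, with interactions
containing it excluded from both sides, refit by maximum likelihood.
Interactions are resolved by nested models
(`resolve_interaction()`: `outer/inner` coding, Satterthwaite degrees of
freedom via `lmerTest` for gaussian outcomes, Wald z for binomial, both
nesting directions).

`paired_cbpt()`/`lmm_cbpt()`/`tfr_cbpt()` implement cluster-based
permutation testing: per-point statistics (paired t, or mixed-model LRT
chi-square) are thresholded at the statistic's asymptotic
`threshold_alpha = 0.05` quantile (a config choice — the cluster-forming
threshold is not part of the method's definition), contiguous
suprathreshold runs (separately by sign for signed statistics) are
summed into cluster masses, and the observed masses are compared against
the distribution of the largest absolute cluster mass under
permutation: within-subject sign flips for paired designs (exhaustive
enumeration when 2^n ≤ n_perm, with a warning), within-subject label
shuffles for the mixed-model statistic.  `p = max(count(null ≥ |mass|)
/ n_perm, 1/n_perm)` — ties count against the observed cluster and the
floor matches the smallest attainable p (1e-4 at 10,000 permutations).
Cluster effect sizes are the paired Cohen's d of cluster-averaged
per-subject values (`d_avg`) and the largest per-point paired d
(`d_max`, with location); no ordering between the two is asserted.
Time-frequency clustering uses 8-neighbourhood adjacency in the
frequency-time plane plus declared sensor neighbours, and is restricted
to 600–5000 ms post-stimulus when comparing interpolated recordings so
that artifact-interpolated periods are never tested.

Permuting one predictor of a multi-predictor model shuffles only that
predictor's labels within subject, keeping covariates fixed; this is
approximate relative to Freedman–Lane residual permutation, and
interaction permutation (shuffling the interaction's cell labels within
subject) has no exact scheme at all — both are documented behaviours,
calibrated by simulation (family-wise error within [0.03, 0.07] at
nominal 0.05 in the test suite) rather than asserted exact.

## Cross-task delta prediction

`compute_deltas()` forms per-subject active-minus-sham difference
series; `cluster_average_delta()` reduces them to one scalar per subject
over a significant cluster's extent; `predict_across()` regresses one
task's delta profile on the other task's cluster scalars point by
point, clustering the predictor's t series under a subject-permutation
null.  With one observation per subject per point, a subject random
intercept is not identifiable (as many groups as observations), so the
per-point model is an ordinary regression; the permutation null, not
the model's asymptotics, carries the inference.

## Problem sizes and reproducibility

The test suite and the acceptance script run scaled designs chosen as
the package's own defaults for desk-scale verification: behaviour
recovery at 200 subjects × 40 trials (the headline odds ratios average
10 replicate refits; the reaction-time refit uses 120 trials per
subject), permutation calibration at 200 null replicates
× 500 permutations (n = 20), cleaning characteristics over ~300–600
generated trials, the pupil cluster test at 24 subjects × 80 trials
with 10,000 permutations, the light-reflex pipeline at 16 subjects ×
20 flashes per condition.  All randomness flows from a single
seed through per-stage derived seeds (`run_pipeline()` records them in
its manifest), so every output is bit-reproducible.

Known limitations: the generator's noise is narrowband (see above), its
trials are exchangeable within condition (no serial dependence beyond
the slow drift), the MEG model has no forward/source geometry and no
eye-movement or cardiac components, and ocular-artifact ICA is out of
scope — epochs can be passed through an external decomposition between
`epoch_and_baseline()` and the spectral stage if needed.  Passing tests
therefore demonstrate correctness of the algorithms and calibration of
the inference under the stated generative model, not performance on any
particular real recording.
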