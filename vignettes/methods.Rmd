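---
title: "Methods: wearable circadian features and LOSO classification of MCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable circadian features and LOSO classification of MCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rhythmwear` turns multi-day wrist-wearable recordings of older adults —
daytime tri-axial acceleration, nocturnal dual-channel PPG and SpO₂ —
into circadian-rhythm features and a subject-based leave-one-out (LOSO)
classifier of mild cognitive impairment. This vignette is the package's
account of the underlying methods: the models and rules, the parameters
that matter, what the synthetic cohort does and does not emulate, and
the design decisions taken where the procedure was genuinely open.

## Analysis windows and screening

Two fixed clock windows carry the whole analysis: 08:00–20:00 for
daytime activity and 00:00–06:00 for nocturnal physiology. These windows
are premised on diaries showing sleep before midnight and waking after
06:00; the synthetic diary generator respects the same constraint so the
windows always apply. Screening is rule-based and per stream: a stream
is rejected as `null_signal` when more than 50 % of samples are
identically zero or missing, as `flat_signal` when its SD falls below
1e-4 of full scale (2 g for acceleration, 100 % for SpO₂), and as
`truncated`/`outside_window` when it does not cover its window. A record
is never partially cropped: streams are either accepted (and cropped to
the window) or rejected with exactly one reason. Screening is
idempotent.

## Signal conditioning

*Acceleration* is filtered by a zero-phase (forward–backward) 4th-order
Butterworth band-pass with corners 0.2 Hz and `min(15, 0.45 × fs)` Hz.
At the 25 Hz device rate a 15 Hz corner would exceed the 12.5 Hz Nyquist
limit, so the upper corner is clipped to 11.25 Hz and the clipping is
recorded on the result. Zero phase matters because downstream features
are time-aligned across streams. The forward–backward pass uses
odd-reflection padding plus steady-state initial conditions; without
them a 0.2 Hz corner leaves multi-second edge transients that alias into
the first minutes of activity counts.

*PPG denoising* uses ensemble empirical mode decomposition. EMD is
implemented directly: cubic-spline envelopes through the signal extrema
(with up to two extrema mirrored beyond each boundary), sifting until a
Cauchy criterion < 0.02 or 15 iterations. The strict stopping threshold
(classical practice uses 0.2–0.3) measurably purifies the modes on tone
fixtures. EEMD adds `n_ensembles = 100` white-noise realisations of SD
`noise_scale = 0.2` × signal SD, decomposes each, keeps the intrinsic
modes whose periodogram-peak frequency falls in a physiological band —
cardiac 0.66–3 Hz (40–180 bpm), respiratory 0.1–0.5 Hz — and averages
the band-limited reconstructions over the ensemble. Selecting modes
within each decomposition (rather than on ensemble-averaged modes)
avoids mode-alignment artifacts: the two-tone reconstruction error drops
from ~27 % to ~5 %. On heavily corrupted signals (SNR around 0 dB) a
heavier `noise_scale` of 0.3–0.4 separates modes better; the default
stays at 0.2. Because the generator's signals are clean unless artifacts
are injected, the feature pipeline defaults to a zero-phase cardiac
band-pass and EEMD is an option (`denoise = "eemd"`); running
100-ensemble EMD over a 2.16-million-sample night is far more expensive
and adds nothing to noise-free data.

## Daytime activity features

The vertical axis is resampled to 30 Hz and rectified; per 1-s block of
30 samples, `count = round(Σ clip(max(|a| − 0.05 g, 0), 0, 2 g) / 0.01)`.
The dead-band (0.05 g), ceiling (2 g) and resolution (0.01 g·sample) are
package constants exposed as arguments — device vendors do not publish
their threshold tables, so the mapping is defined here and pinned.
PA(minute) is the sum of 60 per-second counts. Maximal runs of zero PA
*strictly longer* than 90 minutes are non-wear (91 zero minutes flag,
90 do not). Activity states use the pooled wear-minute PA distribution
of the analysis set: thresholds at the 40th/70th/90th percentiles
(linear-interpolation convention, R type 7), states assigned by
`high if PA ≥ p90, median if ≥ p70, low if ≥ p40, else sedentary`. Ties
go upward at p90, so the degenerate all-equal pool classifies every wear
minute as high; the branch order makes that explicit. Pooling across
records keeps states comparable between subjects; a per-subject
alternative would confound subject level with state occupancy. Rhythm
curves are compressed by block medians (block = 5 points, 720 → 144) —
the block is 5 *points*, which for 30-s epochs is the only reading
consistent with the 720 → 144 arithmetic — and summarised as means per
clock period, optionally after per-record min–max scaling to [0, 1]
(the normalisation that produces 0–1 period summaries is an
interpretation; min–max per record is the package's choice and is
flagged as such).

## Nocturnal physiology

Pulse peaks are local maxima above an adaptive threshold — the 60th
percentile of the signal over 60-s blocks, interpolated between block
centres (an O(n) surrogate for a rolling percentile) — with a 300 ms
refractory period and parabolic sub-sample refinement. Successive
peak-to-peak (PP) intervals outside (250, 3000) ms are gated out and
counted. rMSSD is `sqrt(mean(diff(PP)²))`, requiring ≥ 3 intervals.

Spectral indicators come from the PP tachogram resampled evenly at 4 Hz
by linear interpolation. LF (0.04–0.15 Hz) cannot be estimated from a
30-s window (fewer than two LF cycles), so LF, HF and LF/HF are computed
on a 5-min trailing buffer ending at each window, re-evaluated every
30 s: the output grid stays at 30 s while the spectral support is
adequate — standard HRV practice. Band power is periodogram integration
normalised so the total equals the signal variance (a unit-amplitude
in-band sinusoid gives 0.5), after mean removal.

Respiratory rate uses the two PPG channels: decimate to 10 Hz, whiten,
rotate to the angle maximising absolute excess kurtosis (two-source
separation), and take the component whose dominant frequency lies in
0.1–0.5 Hz; RR = 60 × f. When the two channels are proportional the
whitening is degenerate and the first channel is used directly; when no
separated component lands in the respiratory band, a band-filtered
single channel is the fallback, and windows whose respiratory band holds
under 5 % of channel power are marked missing.

Oxygen desaturation follows the ODI4 convention read as *absolute*
percentage points with a strict inequality: the baseline is the running
maximum of the preceding 120 s; an event starts when SpO₂ drops more
than 4 points below it, ends on recovery to within 2 points or after a
300 s cap. Hourly metrics are the event count (ODI), mean event duration
(0 when an hour has data but no events), and the occupancy of the three
bands ≥ 95, [90, 95), < 90 %, which partition every sample. Z-score
normalisation of indicator series is always applied with explicitly
fitted parameters and never refits on the data being transformed; in the
modelling path the fit is training-fold-only.

## Feature table

Each of the seven indicator series (HR, RR, SpO₂, rMSSD, LF, HF, LF/HF)
is reduced to 36 sliding-window medians: windows of 20 min starting
every 10 min at 00:00, …, 05:50, each window intersected with the night
so the final one is truncated to 10 min. Thirty-six full 20-min windows
do not fit in six hours (only 35 do); starting a window every 10 min and
truncating the last is the only convention that both covers the night
and yields 36 values. The oxygen group contributes, for each of ODI,
OD duration, %SpO₂ ≥ 95 and %SpO₂ 90–95, six hourly values plus the
whole-night mean: 4 × 7 = 28. Total 7 × 36 + 28 = 280 physiological
columns; mode `P+S` appends the five subjective scale features
(education years, PSQI total, sleep disturbance, daytime dysfunction,
chronic-disease count) for 285; mode `S` uses the five scale features
with exactly one row per subject. The column schema is deterministic and
order-stable. Missing cells (rejected streams, empty windows) are
imputed with training-fold column medians at modelling time, and the
imputation provenance is recorded per fold.

## Feature selection and classification

Selection runs per feature group: stratified 10-fold cross-validation at
the record level, a random forest per training fold, and permutation
importance on the held-out fold (10 permutation repeats per feature;
importance = drop in held-out accuracy), averaged over repeats and
folds. Forests are probability forests — majority-vote ties in a
classification forest are broken randomly at prediction time, which
would break seeded determinism. The five most important features per
group (ties broken by column order) form the candidate set; candidates
with importance strictly above the candidate median are retained, so
eight groups with distinct importances retain exactly 20. Record-level
selection mirrors the published sequence of selection before LOSO; a
leakage-safe variant nested inside the LOSO loop is available via the
evaluation functions' `columns` argument.

Both classifier families are gradient-boosted trees fit through the
xgboost library with a shared hyperparameter surface (number of
learners, learning rate, maximum depth): family `"gbdt"` uses classical
gradient-boosting settings (exact greedy splits, no L1/L2
regularisation), family `"xgboost"` the library's regularised defaults.
Grid search trains each grid point across all LOSO folds, pools the
held-out probabilities and computes a single AUC — per-fold AUC is
undefined on one-subject folds, which are single-class. Ties go to the
first grid point. Evaluation reports accuracy, precision, recall, F1 and
AUC in percent at the 0.5 threshold with MCI positive, the pooled ROC
points, and final-model gain importances rescaled so the top feature is
100.

Two stabilisations address pooled-LOSO pathologies. First, every
training fold drops one random subject of the class opposite the
held-out subject, so all folds train on the same class composition and
their score levels are comparable; `scale_pos_weight` additionally
balances the loss. Second, the no-signal control permutes labels at the
*record* level: subject-level permutation leaves the held-out subject's
label locally under-represented in its own feature neighbourhood in
every fold — a known pessimistic leave-one-out bias that pushes the
pooled null AUC to ~0.3 and that neither class weighting nor composition
balancing cures. Record-level permutation breaks the subject–label tie
and centres the null near 0.5; the control reports the mean over three
independent shuffles to damp Monte-Carlo noise. Users comparing a real
cohort against a permutation null should use the same record-level
scheme, and should expect subject-level permutation nulls to sit below
0.5 for structural reasons, not as evidence of anti-signal.

## Group-comparison statistics

Categorical contrasts use the 2×2 Pearson chi-square on 1 df *without*
continuity correction — the convention verified to reproduce the printed
worked statistics (5.055 for the chronic-disease table, 0.629 for sex)
to three decimals, where the corrected statistic does not. Per-period
comparisons use the two-sided Mann–Whitney test with tie-corrected
normal approximation, z signed by the first group's rank-sum deficit,
flagged at α = 0.05 per period without multiplicity adjustment (the
per-period flags are descriptive). Exact enumeration is used only as a
small-sample test oracle. The normal approximation holds its type-I
error within [0.04, 0.06] at n = 30/30 over 2000 null simulations.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
not photodiode physics. Per subject it draws scale features and
circadian parameters around group defaults; per night it synthesises
(a) a cardiac pulse train whose PP intervals are modulated by a
respiratory-coupled HF oscillation and a ~0.095 Hz LF oscillation, with
modulation depth following a smooth nocturnal curve peaking at 03:00,
plus broadband beat-to-beat jitter; (b) an additive respiratory
oscillation mixed into both PPG channels with different gains; and (c) a
1 Hz SpO₂ series with trapezoid desaturation episodes (linear fall,
hold, linear recovery) arriving as a Poisson process — trapezoids make
event boundaries analytically known for exact tests. SpO₂ is generated
directly rather than derived from PPG amplitudes because real devices
compute it in firmware. Days are a bimodal diurnal intensity template
(morning peak ~08:40, post-lunch trough at 13:00–14:00, evening rebound)
driving a gait-frequency oscillation plus 1 g gravity on the vertical
axis.

Group defaults are repository constants calibrated once so pipeline
outputs land in realistic elderly ranges — control rMSSD ~70–90 ms,
LF/HF ~0.6, ODI ~4/h, ≥ 95 % band occupancy ~90–95 % — with MCI planted
contrasts: flattened HRV peak (amplitude 0.30 vs 1.0), larger LF/HF
wobble (0.25 vs 0.05), more and deeper desaturations (5.5/h vs 4/h),
lower high-activity fraction (0.06 vs 0.10), positive morning
low-activity bias (0.35). A single-sinusoid respiratory-sinus model
cannot match printed rMSSD and HF band power simultaneously (real HRV is
broadband); the calibration privileges rMSSD and LF/HF. What the
generator does *not* emulate — movement artifacts in PPG, sleep-stage
structure, position changes, inter-night habit drift, device-specific
count mappings — bounds what passing tests show about real data: they
validate the arithmetic, the detectors and the end-to-end recoverability
of planted contrasts, not clinical performance. The published real-cohort
classification metrics are not reproducible without the original
recordings, and the package does not attempt them.

Determinism is end to end: every randomness consumer takes an explicit
seed, sub-seeds are derived by a Lehmer step (kept below 2³¹), and
identical arguments produce byte-identical streams.

## Problem sizes and numerical choices

The shipped end-to-end runs use 20 subjects per arm × 2 nights
(160 windows-per-night × 80 nights ≈ 58k indicator windows), a reduced
hyperparameter grid (learners {50, 150} × rate 0.1 × depth 3), feature
selection at 10 folds × 10 repeats × 100 trees, and 3 permutation
shuffles — sizes chosen so a full pipeline completes in about ten
minutes on one core while keeping ≥ 20 subjects/arm for the
group-contrast properties. The full grid (learners
{50, 100, 150, 200, 300} × rate {0.01, 0.05, 0.1} × depth {2, 3, 5}) is
`default_grid()`. Degenerate inputs are handled explicitly: constant
EEMD input returns zeros with a flag, zero-variance z-score fits error,
all-tied Mann–Whitney returns p = 1 with a warning, empty artifact specs
are identity, and empty cohorts are valid.

## Known limitations

Pooled-LOSO AUC remains a biased estimator under weak signal (see the
null discussion above); the chi-square reproduces printed statistics
only where the printed counts are internally consistent; EEMD mode
selection by dominant frequency can drop a mode whose energy straddles a
band edge; and the count mapping, while calibrated to behave like
commercial actigraphy counts, is not a replica of any vendor's table.
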