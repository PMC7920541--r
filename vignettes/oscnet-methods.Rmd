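---
title: "Methods: mapping action and inhibition networks from multisite LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping action and inhibition networks from multisite LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

`oscnet` analyzes multichannel local field potential (LFP) recordings from a
self-paced go/wait task: on a *go* cue the subject must respond quickly
(within 2 s) to be rewarded; on a *wait* cue it must withhold the response
for 2 s. Premature responses on wait trials operationalize impulsivity; the
two wait outcomes (patient vs. impulsive) are the decoding target. The
pipeline maps which channels ("regions" — the analysis treats channels as
labeled abstract regions) carry action-related low-frequency (delta, 1–4 Hz)
activity, which carry inhibition-related theta (4–7 Hz) activity, how
channels couple into functional networks (weighted phase-lag index, wPLI),
and whether theta-band coupling predicts wait-trial outcome.

Because the kind of in-vivo data this pipeline targets is not publicly
deposited, the package ships a first-class synthetic-data module whose
defaults encode the task statistics the analysis assumes. All tests and the
acceptance suite run on generated data scored against the generator's ground
truth.

## The synthetic world

`session_config()` defaults state the assumed world:

* 25% go / 75% wait trials, sessions of 272 trials by default;
* go response times lognormal with median 588 ms (sdlog 0.2, a typical
  rodent RT dispersion; the source statistics give only session means), with
  a 3% lapse rate so go accuracy sits near 97%;
* wait response times from a two-component truncated-normal mixture split at
  the 2 s criterion: impulsive component mean 1.263 s (sd 0.29), patient
  component mean 2.513 s (sd 0.135), patient probability 0.54 (the observed
  wait accuracy);
* self-paced trial onsets 8–12 s apart (not stated by the source; chosen so
  the default 7 s epoch never overlaps its neighbors);
* background noise is Gaussian 1/f^α (α = 1 by default), synthesized
  spectrally;
* planted effects: `planted_effect()` adds a sinusoid at a band center to
  chosen channels on chosen trial conditions, scaled in background SD units;
  `planted_coupling()` adds a shared sinusoid to a channel pair where the
  second channel lags by a fixed phase plus von Mises jitter. Both use a
  flat-top Tukey envelope (20% cosine ramps) over the planted window, so a
  "sustained" effect really is sustained at its nominal amplitude across the
  window rather than peaking at its center; the effect is partly off during
  the ramps (the first and last 10% of the window), which the recovery tests
  account for by scoring the flat top.

The coupling strength κ ∈ [0, 1] maps to the von Mises concentration
2κ/(1−κ) (0 → uniform phase, 1 → rigid lag). This mechanism was chosen
because the wPLI it induces is analytically controllable: for unit
amplitudes and lag φ, wPLI = |E sin(φ+ε)| / E|sin(φ+ε)|, which a ten-line
Monte-Carlo oracle reproduces independently of the pipeline; the test suite
checks the full estimator against that oracle and checks monotonicity of
measured wPLI in κ.

Two confounds are modeled explicitly because the analysis claims robustness
to them: whole-trial high-amplitude artifacts (per-trial channel-subset
scaling, default gain 25) exercising the rejection rule, and an optional
zero-lag common source mixed instantaneously into all channels
(`common_source_gain`) exercising wPLI's volume-conduction suppression.

What the generator does *not* emulate: spiking, cross-frequency structure,
non-stationary drift, realistic anatomy or electrode geometry, reward/motor
confounds time-locked to the response. A green recovery test therefore
establishes that the estimators detect the planted statistical structure at
realistic SNR — not that they would isolate the same structure amid real
physiological confounds.

## Preprocessing

Epochs are cut on a half-open window `[t_pre, t_post)` relative to the
stimulus (trial start) or response, with the event sample at
`round(t_event * fs)` on the zero-based sample grid; the default window
[−2, 5) s at 1 kHz gives exactly 7000 samples. Events too close to the
recording edge drop that trial with a warning rather than failing the run.

Artifact rejection is a single pass (matching the source procedure's order:
rejection before referencing): a per-trial activity score is compared to
`mean + k·SD` of the scores across trials, k = 4 by default. The source
description ("k× the SD in activity across the time dimension") is ambiguous
between an extreme-amplitude and a variance reading, so the score is
configurable: `max_abs` (default; maximum absolute amplitude after
per-channel centering) or `pooled_sd`. If the score SD is zero (identical
trials) nothing is rejected. Rejection is deliberately *not* iterated; a
second pass on the survivors would reject more (tested). Like any
`mean + k·SD` rule, it is not robust to heavy contamination: several
simultaneous large outliers inflate the score SD enough to mask one another,
so it should be trusted in the regime it was designed for — a few artifact
trials per session, in line with the single-digit-percent rejection rates
typical of this kind of data.

Median referencing subtracts the cross-channel median at every time point
(compiled kernel). It preserves pairwise channel differences and removes any
common-mode signal exactly. One consequence matters for simulation design: a
signal shared by *more than half* of the channels is treated as common mode
and largely removed, so planted networks in the test worlds always span a
minority of the array.

## Time–frequency decomposition

Morlet wavelets are applied in the frequency domain: each trace's FFT is
multiplied by a Gaussian window centered on the analysis frequency (negative
frequencies zeroed, positive doubled), giving analytic coefficients whose
modulus recovers a pure tone's amplitude with unit gain at the bin center
(tested at 5/10/40 Hz to < 5%). The cycles pair (2, 0.7) follows the EEGLAB
expansion convention: n_cycles(f) = 2·(f/f_min)^(1−0.7), i.e., 2 cycles at
the lowest frequency, growing sub-proportionally. The default grid is 139
linear frequencies from 2–70 Hz and 200 output times spanning the epoch
interior where the longest wavelet fits (3 temporal SDs from each edge) —
the 200 × 139 × 32 session matrix under the default configuration. (The
source text gives both 137 and 139 frequencies; the explicit matrix shape,
139, wins.)

Evoked power subtracts the mean baseline amplitude (window [−1, −0.75] s)
per electrode and frequency. Session maps average the analytic amplitude per
trial condition (go-correct, wait-correct, wait-incorrect), baseline-correct
the average (the "baseline of the average" reading; a per-trial option is
exposed via `evoked_power(groups=)`), then z-score over time per electrode
and frequency. Because z-scoring re-centers over time, the baseline step
matters for the unstandardized evoked maps and band summaries, not for the
z-maps.

## Statistics

Group inference is a per-bin one-sample two-sided t test across sessions
against 0 (the z-scored no-change null), with Benjamini–Hochberg FDR applied
jointly over the *entire* time × frequency × electrode matrix (independence
variant; the source names only "FDR"). Zero-variance bins get the smallest
representable p value and a flag instead of NaN. Band/window summaries use
Bonferroni over the 32 regions (or 32×5 for five-band summaries), with
adjusted values above 1 set to 1.

The dual-masked contrast reports the condition difference A−B only at bins
that survive FDR both for condition A alone and for the contrast, setting
all other bins to 0. Per the stated order, each condition map is z-scored
first and the contrast taken afterwards. The joint mask is the intersection
of the two component masks (tested by construction), and the procedure's
empirical false discovery proportion on planted data stays at or below q.

## Connectivity

wPLI is computed from the same Morlet coefficients as the power analysis
(one spectral estimator, aligned grids): for the trial-wise cross-spectrum
Z = X·conj(Y), wPLI = |E Im Z| / E |Im Z| at each pair × frequency × time,
E the mean over trials, no debiasing (the plain estimator, as printed).
Where the denominator is numerically zero (identical channels, exact zero
lag) the estimate is undefined and masked; the mask threshold is machine
epsilon scaled to mean cross-spectral power. Evoked wPLI subtracts the mean
baseline wPLI ([−0.7, −0.5] s) per pair and frequency; values may then be
negative. Condition contrasts average the per-session difference over a
band × window, test against zero, and FDR-correct over the upper triangle of
the pair matrix. Network graphs keep pairs that meet a wPLI threshold (0.1
and 0.15 by default) *and* are significant. Per-bin wPLI is reported without
temporal smoothing; a window average is what the summaries use.

Small-sample behavior worth knowing: with n trials the null wPLI fluctuates
at the ~1/√n scale, so a dozen trials put ±0.2 excursions within normal
range for a single pair; baseline correction removes the *bias* (which
cancels within condition) but not the variance. Group statistics across
sessions, not single-session values, carry the inference.

## Decoding

The outcome dataset has two rows per session — the feature averaged over
correct-wait trials and over incorrect-wait trials — with outcome as the
binary label. The regression is logistic with outcome as the response and
activity/connectivity as predictors; the source wording swaps the roles, but
only this orientation is consistent with its reported per-predictor β/p and
overall R², so it is implemented this way (documented here as the package's
reading). Pseudo-R² is McFadden's, the source not naming its variant.

Session-level designs separate easily, and Wald inference degrades
(Hauck–Donner) well before glm warns. Fits therefore fall back — flagged —
to ridge-penalized IRLS with a unit penalty on standardized slopes (a
weakly informative Gaussian prior) whenever the linear predictor exceeds 10
in magnitude or, for single-feature fits, whenever the Wald p exceeds ten
times the likelihood-ratio p (the Hauck–Donner signature: on a
session-level feature that nearly separates the outcomes, the Wald p can
sit orders of magnitude above the likelihood-ratio p); coefficients are
mapped back to the original feature scale.

The time-resolved classifier is a linear SVM (in-package, deterministic
batch subgradient descent on the L2-regularized hinge loss), run
independently at each time point on the seed region's connectivity to all
other regions: 75/25 train/test split, the regularization strength chosen by
10-fold CV inside the training split, accuracy measured on the held-out 25%,
and the whole procedure repeated over 10 seeded splits for mean ± SEM.
Features are standardized with training-fold statistics only, so factor
importance (mean |weight| over the 0.5–0.9 s window, normalized to sum 1) is
invariant to feature scaling. A matched beta-band (13–30 Hz) model serves as
the frequency-specificity control.

Behavioral sensitivity is d′ = Φ⁻¹(hits) − Φ⁻¹(false alarms), with the
scaled variant d′/4.65 (the theoretical maximum) mapping to [0, 1]; rates of
exactly 0 or 1 are clipped to 1/(2n) with a warning.

## Numerical and design choices

* FFT convolution is circular; the time grid's restriction to the epoch
  interior (3 wavelet SDs) keeps wraparound and edge effects out of every
  reported bin, and the baseline windows sit inside that interior.
* The epoch window must start at or before −1.03 s (interior margin + the
  −1 s power baseline) — shorter analysis windows in scaled runs use
  [−1.5, …) for this reason.
* Zero-variance score/feature degeneracies: keep-all (rejection), β=0/p=1
  (constant features), flagged minimal p (t maps) — all chosen to keep masks
  and downstream stages NaN-free.
* Session pair-differences that are fully masked (zero-lag degenerate) enter
  the group contrast as 0 (no evidence of difference) rather than dropping
  the session.
* Determinism: every stochastic step derives from one seed; per-session
  seeds are fixed affine functions of the master seed, SVM repeats use
  seed + repeat index. Two runs with equal seeds are bit-identical.

## Scaled acceptance worlds

The acceptance suite states its worlds once and runs them at fixed seeds:

* **Type-I control**: 20 repeats of a 20-session null world (6 channels, 20
  trials, 2–10 Hz grid). Pass requires the dual-masked contrast and the
  wPLI-contrast masks to be empty in ≥ 95% of runs. Note that BH at q=0.05
  flags ≥ 1 null pair in about 5% of runs per contrast family by
  construction, so this criterion sits near its own boundary; the seeded
  outcome is reported as-is.
* **Effect recovery**: 20 sessions × 40 trials × 24 channels; go-delta
  planted in 5 motor channels (0.3–0.5 s), wait-theta in 8 channels
  (0.5–2 s), and M1–vOFC theta coupling at κ = 0.9 on patient vs. 0 on
  impulsive wait trials. Sensitivity is scored on core planted bins
  (frequencies within 1 Hz of the planted carrier, central 80% of the
  planted window) because the Hann taper and wavelet smoothing dilute the
  window edges by construction. 24 channels (not 32) keeps the planted
  networks a minority of the array under median referencing and the run
  inside the time budget.
* **κ monotonicity**: 5 κ levels × 10 replicate 3-channel sessions,
  Spearman ρ between κ and measured wPLI > 0.9.

## Limitations

Epoch windows, not continuous data, are the analysis unit: slow dynamics
spanning trials are invisible. The wPLI estimator is blind to genuine
zero-lag coupling by design. The SVM uses a fixed small λ grid rather than a
full hyperparameter search (the stated protocol). The univariate
electrode × time regressions refit independently per bin and inherit the
usual mass-univariate caveats; FDR is the only correction applied. EDF and
HDF5 containers are not supported in this build (no reader in the target
environment); the flat binary + JSON container and events CSV are the
interchange formats.
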