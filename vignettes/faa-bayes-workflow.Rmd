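---
title: "From alpha asymmetry to corrected Bayes factors: the faabayes workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From alpha asymmetry to corrected Bayes factors: the faabayes workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faabayes)
```

## The measurement model

The package analyses a two-condition listening experiment. Each
participant hears a short standard commercial script and a longer
personalised one while EEG and pupil diameter are recorded, then reports
a composite attitude (four binary items, sum 4–8) and invests a share of
a previously won wallet (normalised to a percentage). Three
psychophysiological summaries are computed per participant and
condition:

* **FAA**, the frontal alpha asymmetry: the difference in
  baseline-normalised 10 Hz power between the right (F4) and left (F3)
  frontal electrodes, in dB. Positive values mean relatively more
  right-hemisphere alpha.
* **PAA**, the same index at P4/P3, carried along as a spatial control.
* **Pupil change**, the baseline-relative mean diameter change in mm,
  a general arousal/processing-load control.

### Spectral pipeline

Signals are tiled with contiguous 200 ms epochs: the baseline covers
−5000 to −200 ms relative to script onset (24 epochs), the task covers
script onset to script end (255 epochs for a 51 s script; a trailing
partial window is discarded). At 250 samples/s an epoch holds 50
samples, so 10 Hz is exactly the second FFT bin: the single-bin power is
leakage-free with a plain rectangular window, which is why
`alpha_power()` refuses frequencies that are not exact bins rather than
silently smearing power. Only the 10 Hz bin is used (the centre of the
8–12 Hz alpha band), not a band average. Per-epoch bin powers are
averaged across epochs *within* each segment first, and a single decibel
ratio `10·log10(P_task/P_baseline)` is then taken per channel; averaging
dB per epoch instead would not commute with the ratio and is not what
the index means. The epoch average makes the estimate independent of
script duration, which matters because the two conditions differ in
length.

`remove_evoked()` subtracts the across-epoch mean waveform (the evoked
response) from every epoch, the standard way to improve stationarity
before spectral analysis of ongoing activity. `compute_asymmetry()`
exposes this as an option that defaults to **off** for a structural
reason: the synthetic generator's alpha component is a strictly periodic
sinusoid, and any signal periodic in the epoch length is entirely
phase-locked to the epochs — the across-epoch mean *is* the signal, so
subtracting it removes the very oscillation under study. Real ongoing
alpha is not phase-locked to arbitrary epoch boundaries and tolerates
the subtraction; a perfectly periodic synthetic oscillation is the
degenerate case. The operation itself is implemented and tested
(residuals have exactly zero across-epoch mean; a noiseless periodic
cohort is annihilated, which the tests assert as the identity case).

### Pupil pipeline

Both eyes are merged per sample (mean of the valid eyes; one-eye
fallback on unilateral loss; missing only when both eyes are gone).
Baseline and task are each split at their midpoint into two half-epochs
— an odd sample goes to the initial half — and every half is
preprocessed separately: samples beyond 3 within-epoch SDs are rejected
(z computed once from the epoch's own pre-rejection statistics, no
iteration), then blinks, rejected outliers and other gaps are linearly
interpolated, with nearest-value extension at the epoch edges where a
straight line is undefined. The summary is
`mean(task) − mean(baseline)`, each side the *unweighted* mean of its
two epoch means, in mm. Millimetres, not z units, are the supported
scale — the condition-level calibration values for pupil change
(0.283 and 0.391) are mm-scale quantities; `process_pupil(scale = "z")`
exposes the within-epoch standardised alternative for sensitivity
checks without endorsing it (its change is near zero by construction
since every epoch is centred).

## The Bayes factor engines

### JZS t test

For paired or one-sample comparisons the standardised effect δ gets a
Cauchy(0, r) prior, r ∈ {0.707, 1, 1.41} (read as √2/2 and √2 in
computation). The Bayes factor integrates the noncentral-t density of
the observed statistic over the prior,

$$\mathrm{BF}_{10} = \frac{\int f_{\nu,\,\delta\sqrt{n}}(t)\,\pi(\delta)\,d\delta}{f_{\nu,0}(t)},$$

by adaptive quadrature split at δ = 0 (relative tolerance 1e−8; a
half-line whose mass is negligible relative to the other falls back to a
tiny absolute tolerance, which is the only way a quadrature of an
essentially-zero integrand can terminate cleanly). One-sided variants
truncate and renormalise the prior, giving BF+0/BF−0 for directional
hypotheses; for a symmetric prior the two one-sided factors average
exactly to the two-sided one, which the tests exploit as an invariant.

### Kendall tau-b via Savage–Dickey

The rank-correlation test places a stretched Beta(1/κ, 1/κ) prior on a
latent Pearson correlation ρ and carries it to the population Kendall
correlation by the parametric yoking τ = (2/π)·arcsin(ρ). The Jacobian
of that map cancels the endpoint divergence of the κ = 2 (arcsine-like)
prior, so the induced density on τ is bounded — a convenient numerical
property the tests verify by checking the prior integrates to one at
every width. The observed tau-b enters through the asymptotic normal
model of the standardised concordance statistic:
`z = τ̂ / sd0` with `sd0 = sqrt(2(2n+5)/(9n(n−1)))`, modelled as
N(1.5·τ·√n, 1) under population correlation τ. The Bayes factor is the
Savage–Dickey density ratio at τ = 0, i.e. the prior-weighted marginal
of the likelihood over the null likelihood. Note the noncentrality is
the large-sample form `1.5·τ·√n`, not `τ/sd0`: the two agree
asymptotically but differ at n ≈ 21, and the large-sample form is the
published construction this engine reproduces — with it, the engine
matches the reference Bayes factors of the study surface to well within
1% (e.g. τ = 0.559, n = 21, κ = 1 gives 102.99).

Ties: the observed statistic is the tie-corrected tau-b
(`kendall_tau_b()`, cross-checked in the tests against an exhaustive
pair-counting oracle), while the normal approximation uses the no-tie
null variance. With heavily tied margins (the 5-level attitude score)
the approximation is coarser; this mirrors the published method and is a
known limitation rather than a bug.

### Robustness protocol and evidence bands

Every test is run at three widths. Bands follow the conventional ladder
(anecdotal 1–3, moderate 3–10, strong 10–30, very strong 30–100,
extreme > 100, mirrored below 1; boundaries go to the stronger band;
exactly 1 is "equal evidence"). The verdict is the modal band across the
three widths — anecdotal under the default but moderate under both wider
priors counts as mostly moderate; if all three differ the default
width's band is reported, since the default is the a-priori choice.

## Multiplicity over Bayes factors

With seven correlations per condition, the package controls the false
discovery rate directly on Bayes factors through the Vovk–Sellke bound
`VS(p) = −1/(e·p·ln p)` (p < 1/e). Screens: `VS(0.05) ≈ 2.46` for H1
candidates and its reciprocal (printed as 0.406) for H0 candidates;
anything between is inconclusive and never retained. Candidates are
ranked (H1 descending, H0 ascending, ties broken by test id for
determinism) and each rank k is assigned the critical Bayes factor
`VS((k/m)·q)` — reciprocal for the H0 branch — with m = 7, q = 0.25. The
default decision rule compares *each candidate against its own rank's
critical value*, exactly as the procedure is narrated; the classical
Benjamini–Hochberg step-up walk (retain every candidate up to the
largest passing rank) is available behind
`multiplicity_config(method = "step_up")` for sensitivity analysis. The
two differ only when a high rank fails while a lower rank passes, which
the test suite demonstrates on a constructed family. Whether the
narrated per-rank rule or the step-up rule is the intended reading is
genuinely ambiguous; the per-rank rule is the default here because it is
the one described operationally.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture. Its defaults
are the study conditions: 21 participants, two conditions with 51 s and
87 s scripts, EEG at 250 samples/s, pupil at 100 samples/s, baseline
window −5000…−200 ms, 10 Hz alpha.

* **Signals** are alpha sinusoids plus additive white Gaussian noise
  (amplitude 10, noise SD 1 signal units by default — a clean post-ICA
  signal-to-noise ratio at the analysis bin). Task amplitudes encode the
  per-participant ground truth: the right channel of a pair is scaled by
  `10^(truth/20)` so the dB pipeline recovers `truth` exactly when noise
  is zero (the tests assert 1e−6 dB). No 1/f background is simulated:
  the analysis reads a single FFT bin, so spectral slope cannot affect
  correctness, only the effective noise level at 10 Hz, which the noise
  SD already controls. Because the sinusoid's period divides the epoch
  length, the synthetic alpha is phase-locked to the epochs — the reason
  the asymmetry stage defaults to no evoked-response removal (above).
  With the default noise the additive floor at the bin is ~3 orders of
  magnitude below the signal power and largely cancels in the
  task/baseline ratio, so asymmetry estimates are unbiased to well
  within their sampling spread (asserted over 200 replicates).
* **Pupil traces** are a per-participant baseline level (mean 3.5 mm,
  SD 0.4) stepping to `baseline + change` at script onset, plus a slow
  0.1 Hz sinusoidal drift (amplitude 0.05 mm) and bounded uniform sensor
  jitter (SD 0.005 mm). The jitter is uniform rather than Gaussian on
  purpose: with bounded noise, a clean sample's within-epoch z can never
  reach the 3-SD rejection threshold, so the pipeline rejects *exactly*
  the injected outliers (spikes of 8 within-epoch SDs) — a sharp,
  testable contract that Gaussian tails would break stochastically. The
  drift phase and jitter are drawn jointly under an acceptance check
  (all clean |z| ≤ 2.8) because a sinusoid segment covering an extremum
  asymmetrically can otherwise standardise past 3 in a short epoch.
  Blinks are ~120 ms binocular gaps flagged `blink`.
* **Behaviour** couples each margin to the FAA scores through a Gaussian
  copula: the rank transform of the FAA is mapped to a standard normal
  and correlated latents are drawn with Pearson ρ = sin(π·τ_target/2),
  the exact inverse of the normal-copula identity
  τ = (2/π)·arcsin(ρ). The attitude margin thresholds its latent at
  equally spaced quantiles (0.2, 0.4, 0.6, 0.8) into four binary items —
  any monotone mapping preserves the rank-correlation contract, and
  equal spacing is the least informative choice given that no response
  model is specified. The investment margin is a latent normal clamped
  to [0, 100]; its latent mean and SD are moment-matched (by
  quadrature + Nelder–Mead) so that the *clamped* variable reproduces
  the condition's calibrated mean and SD (14.762/17.346 and
  32.143/31.81) — naive truncation of a normal with those parameters
  would inflate the mean by more than one percentage point. Wallets are
  drawn uniformly over the winnings range implied by fifteen
  20,000-lire bets; the gambling game itself is not simulated, and no
  observable constrains the wallet distribution beyond positivity and
  that range.
* **Default coupling targets** are the observed correlation structure of
  the two conditions (S1: attitude 0.347, investment 0.219; S2:
  attitude −0.404, investment −0.460), so a default cohort reproduces
  the qualitative result pattern: a negative brain–behaviour coupling
  that emerges in the personalised-script condition.

What the generator does *not* emulate: 1/f EEG background and broadband
artifacts, non-phase-locked alpha dynamics, gaze-dependent pupil
foreshortening, luminance responses, item-level attitude psychometrics,
order/counterbalancing effects. Passing tests therefore certify the
*arithmetic* of every stage and the statistical behaviour of the
estimators under the stated model — not robustness to real-world EEG
artifact structure, which the upstream cleaning this pipeline assumes is
responsible for.

## Numerical choices

* Quadrature tolerances: 1e−10 (Kendall, bounded domain), 1e−8 (JZS,
  infinite domain, split at zero with an absolute-tolerance fallback for
  negligible half-lines); each result records its integration error in
  `$numerics`.
* The Vovk–Sellke inverse is monotone root finding on the log scale
  (round-trip error < 1e−9, asserted).
* Epoch tie-breaks: odd pupil windows put the extra sample in the
  initial half; trailing partial EEG epochs are discarded (zero-padding
  would destroy the exact-bin property).
* Degenerate inputs error loudly: non-bin frequencies, single-epoch
  evoked removal, all-tied tau margins, zero wallets, epochs with fewer
  than two valid samples, Bayes factors at |τ| ≥ 1 or df < 1.
* All generator randomness derives deterministically from
  `(seed, participant, condition, purpose)` sub-seeds, so any recording
  can be regenerated in isolation, bit-identically.

## Scale of the validation runs

The replicate-based checks in the test suite use problem sizes chosen to
estimate their quantities stably: copula recovery and margin calibration
at 5,000 participants (tau within ±0.03–0.05), estimator unbiasedness
over 200 single-recording replicates, and end-to-end parameter recovery
over 200 cohorts of 21 participants per arm (median Kendall BF10 above 3
under the planted τ = −0.46 coupling, below 1 under the null). The full
two-condition replica at study scale runs in a few seconds.

## Known limitations

* The Kendall engine's normal approximation degrades for |τ̂| near 1 or
  n below ~8; it refuses n < 4.
* The no-tie null variance overstates precision for heavily tied
  margins (5-level attitude scores), slightly inflating |BF| either way.
* t-test Bayes factors are validated against Monte-Carlo oracles and
  structural invariants only; no external reference values at desk
  scale exist for them, because they require raw per-participant data.
* The evidence ladder treats band boundaries as belonging to the
  stronger band; published tables are ambiguous at exactly 3, 10, 30,
  100.
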