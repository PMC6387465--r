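---
title: "Non-cerebral proxies of EEG alpha activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-cerebral proxies of EEG alpha activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Biopotentials propagate passively through conductive body tissue, so
electrodes far from the scalp — around the neck, on the wrists — may carry
attenuated copies of cerebral activity. If they do, two things should
hold: (i) the spectral *profile* of such "noEEG" channels in the alpha
range should correlate with that of scalp EEG channels, with some couples
yielding *identical* estimates of the individual alpha frequency (IAF);
and (ii) classifiers fed only noEEG spectral features should separate
eyes-closed (OC) from eyes-open (OA) states about as well as EEG-fed
classifiers, because eye closure massively modulates posterior alpha
power. `neuroproxy` implements that entire analysis chain as a tested
pipeline, exercised end-to-end on a synthetic cohort generator, because
the underlying human recordings are not publicly deposited.

## The synthetic cohort generator

Each subject is a continuous 43-channel recording (27 scalp EEG, 8 neck,
8 wrist channels) at 250 Hz with eight annotated 120-s blocks — four OC
and four OA in randomized order, mirroring the emulated protocol. The
signal model per channel is a sum of:

* an **alpha oscillator**: an amplitude-modulated sinusoid at the
  subject's IAF (drawn uniformly in 8–12 Hz and quantized to the 0.25 Hz
  analysis grid). The envelope is smooth positive noise on a 2-s grid,
  giving the spectral peak a realistic nonzero width (~0.1 Hz, under half
  an analysis bin) while keeping the PSD maximum on the carrier bin. A
  pure tone would make the gravity estimator trivially exact and hide
  bugs; a wider envelope would let background noise flip the peak to a
  neighbouring bin, which is not how a clearly expressed alpha rhythm
  behaves. The oscillator follows a posterior topography (strongest at
  O1/Oz/O2, fading frontally);
* a **theta oscillator** at IAF − 4 Hz (the centre of the IAF-anchored
  theta band) with the opposite condition modulation (OA ≥ OC), since
  non-alpha rhythms relatively increase when the eyes open;
* **1/f background noise** (exponent 1) plus white sensor noise;
* for noEEG channels, a **volume-conduction term**: the posterior source
  activity scaled by a per-channel coupling coefficient in [0, 1]
  (instantaneous scalar mixing — the premise is passive tissue
  conduction, so propagation delays are out of scope). By default the
  eight noEEG channels used as classification features are coupled at
  0.35–0.6 and the other eight are uncoupled.

### Effect sizes are generator parameters, not empirical facts

The study the pipeline emulates reports no OC/OA effect sizes, so the
defaults below are this package's own choices of a "clearly reactive"
subject, and every number should be read as a simulation parameter:

| parameter | default | meaning |
|---|---|---|
| `alpha_amp_oc` / `alpha_amp_oa` | 8 / 1.5 µV | alpha amplitude at the strongest posterior channel per condition |
| `theta_amp_oc` / `theta_amp_oa` | 1.2 / 2.5 µV | theta amplitude per condition |
| `background$scale` | 3 µV | background SD on EEG channels (noEEG channels: × 0.5) |
| `background$oa_ratio` | 1.35 | broadband OA/OC background amplitude ratio |
| `coupling` | 0.35–0.6 | source attenuation onto the coupled noEEG channels |

The broadband `oa_ratio` deserves a note: alpha and theta oscillators
alone cannot make the Delta or Beta bands discriminable, yet the analysis
expects above-chance discrimination in all four bands. A mild broadband
arousal shift (eyes open raises wideband power) is the mechanism that
carries those bands, and it is deliberately small compared with the
alpha contrast.

Artifact injection (blinks on frontal channels, EMG bursts, ECG-like
spikes on the neck) is off by default and exists to exercise the
rejection rules; ground-truth event times are returned so tests can audit
the flags. Blinks are 0.2-s raised-cosine deflections — short enough that
a 150 µV blink still exceeds the ±100 µV rule after the 1–20 Hz
band-pass, as a real blink deflection would.

What the generator does **not** emulate: electrode geometry and realistic
head conduction, line noise, non-stationary drifts in IAF, heartbeat in
the background of every channel, or inter-channel correlated noise.
Passing tests therefore demonstrate the pipeline's correctness and the
internal consistency of the analysis logic on data with the assumed
structure — not the empirical claim about human tissue conduction.

## Preprocessing

The band-pass is the stated 8th-order Butterworth pair (high-pass 1 Hz,
low-pass 20 Hz), applied zero-phase (forward–backward) so alpha bursts
stay aligned with the block labels; single-pass application is available
via `filter_spec(zero_phase = FALSE)`. Numerically, the low-pass runs
*first*: the 1 Hz high-pass has poles at |z| ≈ 0.996 and, run first on
full-scale data, injects low-frequency rounding noise that the low-pass
then passes (measured stopband floor −41 dB); in the adopted order the
40 Hz attenuation is below −100 dB.

Epoching uses 4-s windows with a 0.1-s step (3.9 s overlap). The count
per block follows the printed convention `floor((block − epoch)/step)`
with **no** `+1` term, reproducing exactly 1160 epochs per 120-s block
and 2320 per OC/OA couple. Epoch starts are `0, step, 2·step, …` within
each half-open block interval.

Two artifact rules are applied to the filtered, segmented data, each with
a *strict* inequality at its printed limit: an epoch is flagged when any
sample on any channel exceeds ±100 µV, or when the least-squares slope of
any channel across the 4-s window exceeds 10 µV/s in absolute value. A
sample at exactly 100 µV or a ramp at exactly 10 µV/s does not flag.
Flagged epochs are removed for all channels jointly (the rules define one
artifact-free dataset, not per-channel ones). ICA-based EMG/ECG removal
and regression-based eyeblink correction are published external methods
and are out of scope; a recording cleaned elsewhere can enter the
pipeline unchanged, and the amplitude/trend rules handle injected blinks.

## Spectral estimation

Each retained 4-s epoch is one Hanning-windowed periodogram,
window-power corrected (`2|FFT(wx)|²/(fs·Σw²)`, no doubling at
DC/Nyquist) so white noise integrates back to its variance; at 250 Hz the
grid spacing is exactly 0.25 Hz. Whether the original analysis re-windows
continuously (Welch on the raw blocks) or windows the extracted epochs is
ambiguous; here each retained epoch is one segment — the two coincide
when no epochs are dropped. Condition means average the four repetition
means with equal weight regardless of each repetition's surviving epoch
count (this differs from pooling epochs, and the tests pin the
distinction). The dB transform is `20·log10(PSD)` exactly as the source
analysis prints it (even though `10·log10` is conventional for power) and
is display-only: IAF, correlations and classification features all use
the linear PSD.

## IAF estimation and IAF-anchored bands

The peak estimator returns the largest-PSD bin within the 7.5–12.5 Hz
search range; the gravity estimator returns `Σ a(f)·f / Σ a(f)` over the
same bins. The combined policy uses the peak when the range holds a
unique *comparable* local maximum and the gravity otherwise — "comparable"
meaning a strict local maximum at least 25% of the range maximum, so that
noise wiggles on the flank of a dominant peak do not count as competing
alpha peaks, while genuinely split peaks do. Monotone (peakless) spectra
are flagged degenerate and routed to gravity. Equal-maximum ties also
resolve to gravity.

Bands are anchored at the IAF: Delta (0, IAF−6), Theta (IAF−6, IAF−2),
Alpha (IAF−2, IAF+2), Beta (IAF+2, IAF+16), Gamma (IAF+16, IAF+25).
Band-to-bin conversion uses half-open intervals `[f1, f2)` at 0.25 Hz
resolution intersected with the 1–20 Hz analysis range — the only
convention under which the 4-Hz Theta and Alpha bands give 16 bins per
channel and hence 144 EEG / 128 noEEG features. The published Delta and
Beta feature counts (72/64 and 360/320) imply 8 and 40 bins per channel,
which no IAF in 8–12 Hz reproduces under these band widths and the 1–20
Hz filter; the package exposes the per-band bin lists and asserts counts
only for Theta/Alpha, leaving that inconsistency documented rather than
resolved. Gamma is defined but lies wholly above the 20 Hz low-pass, so
it is never used as features.

## Correlation and the common pattern

For each subject, the alpha-range bins (21 points) of the mean-OC linear
PSD are the paired observations of a Pearson correlation for each of the
27 × 16 EEG–noEEG couples; the mean-OC condition has a single value per
bin, so the bins must be the observations (an epoch-wise mode is
available behind `couple_correlations`' arguments for exploration). The
range is the fixed 7.5–12.5 Hz window because the correlation step
precedes IAF anchoring. A couple enters the common pattern only when
R > 0 **and** p < 0.05 in every subject — a per-subject conjunction, as
specified, not a pooled test. No multiple-testing correction is applied
across the 432 couples, as a fidelity choice; `common_pattern(adjust =
"fdr")` switches it on. The IAF-difference map then averages
IAF_EEG − IAF_noEEG across subjects per retained couple and categorizes
the mean: equal (0), eeg_higher (≤ 0.25), eeg_lower (≥ −0.25),
out_of_range (|d| > 0.25). Zero-difference couples are the proxy-channel
candidates.

## SWLDA

The stepwise linear discriminant is written from scratch. Labels are
coded OC = 1, OA = 0 and regressed on the spectral features by ordinary
least squares. Each iteration adds the excluded feature whose two-sided
coefficient t-test (equivalent to the single-term partial F-test; the
source names no statistic) has the smallest p-value, if below
α_enter = 0.05; backward elimination then removes, worst first, any
included feature whose p-value exceeds α_remove = 0.1, to exhaustion,
before the next forward step — the canonical interleaving in the BCI
literature, since the verbal description is ambiguous. Ties break toward
the lowest column index; candidates that would make the design rank
deficient are skipped and logged; the model may legitimately be empty.
`max_features` is unlimited by default (the source states none) with a
`max_iterations = 100` safeguard.

Internally the forward scan maintains residuals of the labels and of all
candidate columns against the current model via incremental
Gram–Schmidt, so each scan is one matrix–vector product; features are
standardized for conditioning and the final weights are refit on the
original scale. The test suite pins the fast path to a naive brute-force
stepwise oracle (lm() refits at every step) on 130 random instances, and
asserts the convergence invariant — every included p < α_remove, no
excluded p < α_enter — by independent refits.

## Cross-validation and evaluation

Each (OC_i, OA_i) repetition couple calibrates one SWLDA model, which is
then scored on the three remaining couples *separately*; with four
repetitions this gives 4 × 3 = 12 (AUC, ACC) evaluations per subject,
band and feature set, whose means are the per-subject metrics (metric
averaging, not pooled-ROC; pooling is an easy variant through
`run_band_cv`'s per-fold output). AUC is the rank-based Mann–Whitney
form with midrank ties; ACC thresholds the 0/1-coded discriminant output
at 0.5 with no per-fold tuning, since none is described. Cohort summaries
average within subject first, then across subjects, and the EEG-vs-noEEG
comparison is a two-tailed paired t-test per band on the per-subject
averaged metrics. Identical metric vectors make the paired t statistic
0/0; that case errors rather than fabricating p = 1, and the summary
documents it.

## Problem sizes, determinism and budgets

The analysis scripts run a six-subject cohort; the acceptance script
re-derives its quantities on a five-subject cohort (the discrimination
and accuracy targets) plus one fixed-IAF subject (the recovery target).
These sizes are the package's scaled-down study conditions: one subject
costs roughly 1.5 minutes end to end on a single core, dominated by the
37,120 windowed FFTs and 32 SWLDA fits. The type-I-error calibration of
the paired test runs on zero-effect feature matrices drawn directly
(Gaussian features independent of labels) rather than on 200 fully
simulated cohorts, exercising the same fold-CV machinery at a tractable
cost. Every random quantity derives from one master seed (per-subject
streams are spawned deterministically), so complete reruns are
bit-identical; tests assert this.

## Known limitations

* The generator's volume conduction is scalar and instantaneous; no
  frequency-dependent tissue filtering.
* EDF support covers the 16-bit core format with a JSON sidecar for
  block annotations (the EDF+ annotation channel is not implemented);
  BrainVision support is read-only (INT_16 / IEEE_FLOAT_32,
  multiplexed).
* Re-referencing is not applied; signals are assumed referenced as
  recorded.
* The pipeline recomputes rather than resumes: a full run is minutes, so
  stage-level caching is limited to what the analysis scripts persist
  themselves.
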