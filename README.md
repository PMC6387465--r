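# neuroproxy

Can electrodes that are nowhere near the brain — around the neck, on the
wrists — stand in for EEG? Because body tissue conducts, cerebral
potentials propagate to non-cerebral sites, so "noEEG" channels may (i)
carry alpha-band spectral profiles that correlate with scalp EEG and
yield *identical* estimates of the individual alpha frequency (IAF), and
(ii) support eyes-closed (OC) vs eyes-open (OA) state classification on
par with EEG. `neuroproxy` implements that analysis chain as a tested R
package plus a scripted workflow, exercised end to end on a synthetic
cohort generator (the underlying human recordings are not publicly
deposited). It is aimed at researchers in neurophysiological signal
processing who want a reproducible, fully seeded reference
implementation of this pipeline.

## What the package computes

For each subject (43 channels — 27 EEG, 8 neck, 8 wrist — at 250 Hz,
eight 120-s OC/OA blocks):

1. **Preprocess** — 8th-order Butterworth band-pass 1–20 Hz (zero-phase),
   4-s epochs at 0.1-s step (`(120 − 4)/0.1 = 1160` epochs per block),
   artifact rejection by the ±100 µV amplitude rule and the 10 µV/s
   least-squares-trend rule (both strict inequalities).
2. **Spectra** — per-epoch Hanning periodograms on an exact 0.25 Hz
   grid; repetition means; condition means as the unweighted mean of the
   four repetition means.
3. **IAF and bands** — peak estimator (argmax in 7.5–12.5 Hz) with a
   gravity fallback `Σ a(f)·f / Σ a(f)` for multimodal or peakless
   spectra; IAF-anchored bands Delta (0, IAF−6), Theta (IAF−6, IAF−2),
   Alpha (IAF−2, IAF+2), Beta (IAF+2, IAF+16), Gamma (IAF+16, IAF+25);
   half-open band-to-bin conversion (a 4-Hz band ↦ 16 bins per channel,
   so the 8 noEEG channels give 128 alpha/theta features).
4. **Correlation** — Pearson R across the 21 alpha bins of the mean-OC
   spectra for all 27 × 16 EEG–noEEG couples; a couple enters the
   *common pattern* only if R > 0 and p < 0.05 in **every** subject; the
   IAF-difference map `IAF_EEG − IAF_noEEG` (averaged across subjects)
   marks zero-difference couples as proxy candidates.
5. **Classification** — from-scratch stepwise linear discriminant
   analysis (SWLDA, forward entry at p < 0.05 / backward removal at
   p > 0.1 on OLS coefficient p-values, labels OC = 1, OA = 0) on
   band-wise spectral features of 9 EEG or 8 noEEG channels;
   repetition-paired cross-validation (each (OC_i, OA_i) couple
   calibrates once, the other three couples are scored separately →
   12 evaluations per subject/band/feature set); rank-based AUC, 0.5-
   threshold accuracy, and per-band paired t-tests EEG vs noEEG.

The methods vignette (`vignettes/noneeg-proxy-methods.Rmd`) documents the
signal model, every tunable parameter, the numerical choices and the
design decisions.

## Worked example

```r
library(neuroproxy)

cfg <- sim_config(n_subjects = 1, subject_iaf = 11, seed = 104)
rec <- generate_subject(cfg, 1)
es  <- preprocess_recording(rec)
ps  <- epoch_psd(es, channels = c("Oz", "Neck4"), fmax = 30)
ocm <- condition_mean(ps, "OC")
iaf_peak(ocm, "Oz")
#> <iaf> 11.00 Hz (peak, Oz, 1 local maxima)
iaf_peak(ocm, "Neck4")
#> <iaf> 11.00 Hz (peak, Neck4, 1 local maxima)
alpha_profile_correlation(ocm, "Oz", "Neck4")
#>   eeg_channel noeeg_channel        R            p n_points
#> 1          Oz         Neck4 0.999976 1.687331e-42       21
```

The synthetic subject's 11 Hz alpha oscillator is recovered *exactly*
(same 0.25 Hz bin) from both the posterior EEG channel and the coupled
neck channel, and their alpha-range spectral profiles correlate at
R ≈ 1 — the two signatures of volume-conducted cerebral activity the
pipeline is built to detect.

## The analysis workflow

Numbered scripts under `analysis/` run the full study on a six-subject
synthetic cohort (master seed 42) and write their tables under
`results/tables/`:

```sh
Rscript analysis/01_simulate.R             # cohort -> EDF + ground truth
Rscript analysis/02_preprocess_spectra.R   # filtering, epoching, PSDs
Rscript analysis/03_iaf_bands.R            # IAF recovery + band tables
Rscript analysis/04_correlation_pattern.R  # common pattern + IAF map
Rscript analysis/05_classification.R       # SWLDA cross-validation
```

On this cohort the scripts report: IAF recovery 6/6 exact at Oz; all
216 EEG × coupled-noEEG couples (and none of the uncoupled ones) in the
common pattern, all 216 with identical IAF; and cohort-mean
cross-validated metrics

| band  | AUC EEG | AUC noEEG | ACC EEG | ACC noEEG |
|-------|--------:|----------:|--------:|----------:|
| Delta | 0.974   | 0.969     | 0.914   | 0.901     |
| Theta | 0.985   | 0.984     | 0.930   | 0.928     |
| Alpha | 0.985   | 0.985     | 0.935   | 0.935     |
| Beta  | 0.994   | 0.992     | 0.957   | 0.947     |

with paired EEG-vs-noEEG t-tests non-significant for AUC in every band —
non-cerebral features discriminate the two states as well as cerebral
ones on data with the generator's default contrast.

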