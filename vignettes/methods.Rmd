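---
title: "Methods: synthetic skin HSI cohorts, tissue indices, and the evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic skin HSI cohorts, tissue indices, and the evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`sepsishsi` implements an analysis pipeline for sepsis diagnosis and
30-day mortality prediction from hyperspectral imaging (HSI) of ICU
patients' skin: a seeded synthetic cohort generator, the deterministic
preprocessing chain, band-ratio tissue-parameter indices, deep image and
multimodal classifiers, and an evaluation harness (nested
cross-validation, logit ensembling, bootstrap confidence intervals,
recursive feature elimination, Welch/Bonferroni group statistics). No
patient data ship with the package; every analysis runs on synthetic
cohorts whose statistical structure mirrors what the clinical protocol
assumes.

# The synthetic cohort model

## Labels

Sepsis status is three-valued (`sepsis`, `no_sepsis`, `unsure`) and
30-day mortality three-valued (`survivor`, `nonsurvivor`, `unknown`).
Label counts are allocated by deterministic rounding of the configured
prevalences over a seeded random permutation, so a 508-patient cohort
reproduces the clinical accounting exactly: 71 indeterminate sepsis
labels, a 437-patient sepsis cohort at 30% prevalence, 25 patients lost
to follow-up, and subgroup mortality of 27% (sepsis), 6% (no sepsis)
and 15/71 (indeterminate) — the last value is implied by the printed
cross-tabulation (35 + 18 + 15 = 68 deaths of 483 followed, 14%)
rather than stated directly. Indeterminate labels are assigned
independently of the latent disease state, because nothing ties
indeterminacy to severity; the latent state behind an `unsure` label is
drawn from the case/control mixture at the configured prevalence.

## Latent chromophore states and spectra

Each patient carries a six-parameter latent state: oxygenated
hemoglobin fraction (`oxy_fraction`), total hemoglobin (`thb`), water
volume fraction (`water_fraction`), a Mie-like scattering baseline
(amplitude and spectral slope), and an effective optical path depth.
Reflectance follows a Beer–Lambert attenuation of the scattering
baseline:

R(λ) = amp · (λ/800)^(−slope) · exp{−d · [thb·(f·ε_HbO2(λ) + (1−f)·ε_Hb(λ)) + w·ε_H2O(λ)]}

The extinction curves are smooth analytic proxies — Gaussian bumps at
the qualitatively correct band locations (HbO2 doublet at 542/577 nm,
Hb at 556 nm with a near-infrared band at 760 nm, water rising into its
~970 nm band). They are not digitized literature spectra: the analyses
only need correct *directionality* and band separation, not radiometric
realism, and the proxies keep every quantity reproducible from code.

Control-state moments (oxy 0.72 ± 0.055, thb 1.00 ± 0.13, water
0.55 ± 0.09, amplitude 0.80 ± 0.02, slope 0.20 ± 0.05, depth
1.40 ± 0.12) were chosen once so that (i) reflectances stay inside
(0, 1] without clipping, and (ii) the band-ratio indices respond to the
intended chromophore and not to nuisance latents. The relatively high,
flat scattering baseline keeps the absorbance offset small, which makes
ratio indices cancel hemoglobin load and path depth where they should
(StO2) while a dedicated absorption-free reference window preserves
sensitivity where absolute load is the point (hemoglobin index).

Sepsis cases shift three latent axes by `effect_size` standard
deviations: oxygen saturation down, hemoglobin and water up — the
microcirculatory-dysfunction-and-edema pattern. With three independent
shifted axes the optimal discriminant has separation
`effect_size·√3`, so the latent Bayes AUROC is
`pnorm(effect_size·√3/√2)`; the default `effect_size = 1.34` gives
~0.95, the condition under which the recovery analyses are run.

## Images

Cubes are rendered at a configurable shape (desk scale 64×64×100 by
default; the acceptance analyses use 32×32×100; device scale 640×480×100
over 500–1000 nm) as a constant background (reflectance 0.30) with a
circular skin region whose pixels carry the patient spectrum under
per-pixel log-normal brightness jitter (σ = 0.03) and per-band
log-normal noise (σ = 0.03). Annotation radii follow the clinical
guideline — 100 px (palm) and 20 px (finger) at width 640 — and scale
proportionally with cube width. RGB renderings average reflectance over
600–700 / 520–580 / 500–520 nm windows.

What the generator does **not** emulate: melanin and skin-tone
variation, spatial structure within the skin region (vessels, mottling
patterns), motion artifacts, specular highlights, and any correlation
structure among the uninformative clinical features. Passing tests
therefore demonstrate that the pipeline recovers planted spectral and
tabular effects through the full protocol — not that the models would
reach any particular performance on real patients.

## Clinical features

The 45-feature schema (33 available within 1 hour of admission —
demographics, vitals, bedside scores, vasoactive doses, ventilation and
organ support, blood gas; 12 laboratory values completing the 10-hour
tier) uses plausible per-feature baseline moments. Three features are
informative by default — noradrenaline dose and lactate shifted up, pH
down in cases, by `clinical_effect_size` (defaults to `effect_size`)
standard deviations; all others are class-independent noise. Features
are independent except for the planted ones, because the source
material gives no joint distribution to emulate. Each entry is masked
missing with probability 0.016.

# Preprocessing

Calibration uses the standard flat-field formula
`(raw − dark)/(white − dark)`, clamped to `[0, 2]`, with
white-equals-dark positions set to 0 and counted. ℓ1 spectral
normalization divides each pixel's spectrum by the sum of its absolute
band values; all-zero (out-of-mask) spectra stay zero. Cropping takes
the square of side `2r+1` centered on the annotation with the inclusive
lattice mask `Δrow² + Δcol² ≤ r²`; in-mask values are carried
bit-identically, everything else is exactly zero. Rescaling to the
model input side (224 at device scale; 16 at desk scale, see below) uses
mask-normalized bilinear interpolation: data and mask are resampled
with the same geometry and in-mask outputs are divided by the
interpolated mask coverage, so boundary pixels are convex combinations
of in-mask values only and a constant disk stays constant; the mask is
re-thresholded at 0.5 and data re-zeroed outside it. Palm and finger
inputs stack along the spectral dimension (palm channels first, mask
union). Missing clinical entries are imputed with −1 *after* tier
selection, so the sentinel cannot leak across tiers.

# Tissue-parameter indices

Each index is a band-window operator on decadic absorbance
`A = −log10(max(R, 10^-4))`: the ratio of mean absorbance (or of
least-squares spectral slopes) over a numerator and denominator window,
affinely mapped to [0, 1]. The device vendor's closed-form index
formulas are not public, so the registry ships documented,
overridable approximations calibrated to the synthetic absorber
library:

| index | numerator (nm) | denominator (nm) | raw scale |
|---|---|---|---|
| StO2 | 570–590 | 740–780 | 1.0–4.0 |
| perfusion | 655–735 | 825–925 | 0.1–0.9 |
| hemoglobin | 530–590 | 620–680 | 2.5–15 |
| water | 955–980 | 880–900 | 1.2–2.4 |

Design notes, decided once against the latent model and frozen:

* **StO2** compares the hemoglobin doublet with the deoxy-Hb 760 nm
  band. The synthetic 760 nm band amplitude (0.8) is set so the two
  windows carry comparable absorbance magnitude: a ratio
  `(thb·a + o₁)/(thb·b + o₂)` is insensitive to `thb` exactly when the
  absorber-to-offset proportions match, and with that calibration the
  index correlates ~0.9 with the latent oxygen fraction and ~0 with
  hemoglobin load and path depth.
* **Hemoglobin** needs absolute load, so its denominator is an
  absorption-free reference window (620–680 nm) where absorbance is
  just the stable scattering offset.
* **Water** puts the water band in the *numerator* (955–980 nm) over
  the drier 880–900 nm window, so the index rises with tissue water.
  A fixed denominator-on-the-water-band variant would invert the
  monotonicity the index is meant to have and is therefore not the
  default.
* Scale bounds span the raw-ratio ranges the generator produces without
  clipping; they map monotonically, so group comparisons are unaffected
  by their exact values.
* Indices are computed from calibrated (non-ℓ1-normalized) reflectance:
  mean-absorbance ratios are not invariant to per-pixel rescaling
  (slope-ratio mode is, and that invariance is tested). The per-patient
  summary statistic is the in-mask **median** per channel, robust to
  the occasional extreme pixel; the aggregation is not dictated by the
  source material, so it is a documented package choice.

# Classifiers

The image model is a 14-layer-class residual CNN ("deep stem" variant):
three 3×3 stem convolutions (first at stride 2) each with batch
normalization and ReLU, a 3×3/2 max pool, four stages of one basic
residual block (stride-2 transitions downsample the identity path with
a 2×2 average pool plus 1×1 convolution), global average pooling, a
10-unit linear bottleneck with batch normalization, and a 2-logit head.
Reference widths 32/32/64 and 64/128/256/512 scale by `width_scale`
(0.25 at desk scale). The exact per-stage layout of the named reference
architecture is not specified in the source material, so the topology
is config-driven. There is no pretrained-weight hook at desk scale:
initialization is He-normal from a seeded stream.

The clinical encoder is two fully connected blocks (linear, batch
normalization, ELU, dropout; widths 50 then 30) and a 10-unit linear
head with batch normalization. The fusion model concatenates the two
batch-normalized 10-dim bottlenecks to 20 features, applies one fully
connected block (width 20, a package default — the width is unstated in
the source material) and a 2-logit head. Dropout defaults to 0.1
(also unstated, configurable).

Training minimizes softmax cross-entropy with AdamW (β1 0.9, β2 0.999,
decoupled weight decay 0.001 on weight matrices), an exponential
learning-rate schedule (0.001·0.99^epoch, applied per epoch — the decay
granularity is a package decision), 10 epochs of 500 images in batches
of 32. Batches are class-balanced: each full batch holds 16 per class,
the 20-image remainder batch 10 per class (500 = 15·32 + 20); each
class draws from a shuffled queue that reshuffles when exhausted, so
the minority class is oversampled while majority samples are not
repeated within a pass. Augmentation applies a uniform rotation in
±180° (bilinear about the center, zero fill, mask transformed
identically) and horizontal/vertical flips at probability 0.5 each.
Stochastic weight averaging replaces the final weights with the
arithmetic mean of the last two end-of-epoch snapshots, after which the
batch-normalization statistics are re-estimated in one pass over the
training data. The whole loop is hand-implemented on BLAS matrix
algebra with small C++ memory-layout kernels (im2col/col2im); gradient
correctness is verified against finite differences in the test suite.

The clinical-only model is a 100-tree random forest with class weights
inversely proportional to training class frequencies and otherwise
reference defaults (Gini splitting, bootstrap resampling, √p features
per split), exposing impurity importances renormalized to sum to 1;
it is backed by `ranger`.

# Evaluation protocol

Task cohorts drop indeterminate labels (`unsure` for sepsis, `unknown`
for mortality). Splits are patient-level, label-stratified, nested
5×5 cross-validation (stratification is a package decision that
stabilizes small-fold class counts). For each outer fold, the 5 inner
folds × 3 training seeds give 15 networks whose test-set logits are
averaged; pooled outer-fold test predictions give one ROC/AUROC per
model, with a 1000-resample bootstrap (percentile 2.5/97.5 CI;
resamples missing a class are redrawn and counted). Pooling — rather
than averaging per-fold AUROCs — matches bootstrapping "each test set"
as one set. For the random forest the ensemble averages probabilities,
as trees have no logits.

Recursive feature elimination fits the forest on each inner fold's
training set, averages impurity importances across the inner folds,
removes the least important feature (ties broken deterministically by
eliminating the later feature in canonical schema order) and repeats;
per-outer-fold rankings combine by mean rank. The feature staircase
re-evaluates the clinical model on the top-1/2/3/all feature subsets.

Group statistics compare the four per-patient index medians between
groups with two-sided Welch t tests (Welch–Satterthwaite degrees of
freedom), at the Bonferroni-corrected per-test level 0.05/4 = 0.0125.

# Desk-scale problem sizes

All shipped analyses run on one CPU core. The package's desk-scale
conditions, stated here as its own choices: cohorts of 150–300 patients
with 32×32×100 cubes (palm only), model inputs rescaled to 16×16
(the annotation crop at this cube size is 11×11, so nothing is
discarded), CNN width scale 0.25, and — in the scripted analyses and
acceptance run — one outer fold of the 5×5 scheme carrying its full
15-network ensemble rather than all five outer folds. The null-control
analysis uses 36-patient null cohorts with 3-seed ensembles at width
scale 0.125. The device-scale settings (640×480×100 cubes, 224×224
inputs, width 1.0, all outer folds) remain configuration switches.

# Numerical choices and degenerate inputs

Absorbance clamps reflectance at 10^-4; band-ratio denominators are
floored at 10^-12; ℓ1 normalization leaves all-zero spectra untouched;
calibration divides by 1 where white equals dark and reports the count;
bootstrap resamples with a single class are redrawn; Welch's test
returns t = 0, p = 1 for two degenerate equal-constant groups; the
softmax is computed with max subtraction. Every random quantity derives
from a single integer seed per entry point (cohort seed, experiment
seed, per-network seeds derived by a fixed integer hash), and runs are
bit-reproducible single-threaded.

# Known limitations

The synthetic spectra are smooth two-absorber-plus-water proxies; index
values are in arbitrary units and not comparable to any device's
output. The CNN is a faithful-but-reduced member of the named
architecture family, not a weight-compatible replica, and no pretrained
weights are used. Mortality labels carry signal only through their
association with sepsis (rates differ by group), so mortality-task
AUROCs on synthetic data are modest by construction. Conclusions about
real HSI cohorts require real data; this package demonstrates the
protocol, not clinical performance.
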