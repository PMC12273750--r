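# sepsishsi

Sepsis and 30-day mortality are hard to call early in ICU patients, yet
every hour of delay costs lives. Skin hyperspectral imaging (HSI) — a
640×480-pixel reflectance cube over 100 bands (500–1000 nm) acquired at
the bedside in seconds — carries microcirculatory information
(hemoglobin oxygenation, perfusion, tissue water) that separates septic
from non-septic critically ill patients. `sepsishsi` implements, end to
end and on synthetic data, the analysis pipeline for that problem: for
computational researchers who want a fully reproducible, tested
reference implementation of the protocol — cohort structure,
preprocessing, tissue indices, deep and multimodal classifiers, and the
statistics — without access to any patient data.

## What it computes

**Tissue-parameter indices.** On decadic absorbance
A(λ) = −log₁₀ max(R(λ), 10⁻⁴), each index is a scaled band-window
ratio, e.g.

    StO2  =  clip[ ( mean A(570–590) / mean A(740–780) − s₀ ) / (s₁ − s₀), 0, 1 ]

with analogous windows for perfusion, hemoglobin and water. Per-patient
summaries (in-mask medians) are compared between groups with two-sided
Welch t tests at the Bonferroni level 0.05/4 = 0.0125.

**Classifiers.** A residual CNN (deep 3×3 stem, four basic-block
stages with average-pool shortcut downsampling, 10-unit bottleneck)
for HSI/TPI/RGB inputs; a 50→30→10 fully connected encoder for the 45
clinical parameters (33 in the 1-hour tier); a fusion model over the
concatenated bottlenecks; a 100-tree balanced random forest for
clinical-only prediction. Deep models train with AdamW
(lr 0.001·0.99^epoch, weight decay 0.001), 10 epochs × 500 images,
class-balanced batches of 32, ±180° rotation/flip augmentation, and
stochastic weight averaging over the last two epochs — the whole
forward/backward machinery is implemented in this package on BLAS
matrix algebra.

**Evaluation.** Patient-level stratified nested 5×5 cross-validation;
per outer fold the 5 inner-fold models × 3 seeds = 15 networks are
ensembled by averaging logits; pooled test predictions give AUROC with
a 1000-resample bootstrap CI; recursive feature elimination with
inner-fold-averaged importances ranks the clinical features.

**Synthetic cohorts.** A seeded generator produces patients with latent
chromophore states (cases: lower oxygen saturation, higher hemoglobin
and water), Beer–Lambert reflectance cubes with circular skin
annotations (radii 100/20 px at width 640), RGB renderings, clinical
tables with three informative features (noradrenaline dose, lactate,
pH) and 1.6% missingness, and label prevalences matching the clinical
cohort accounting (30% sepsis, 14% mortality, 71/508 indeterminate).

## Worked example

```r
library(sepsishsi)

cfg <- cohort_config(n_patients = 150, cube_shape = c(32, 32, 100),
                     sites = "palm", seed = 20240)
latent_bayes_auroc(cfg$effect_size)
#> [1] 0.9496177

cohort <- generate_cohort(cfg)
sel <- select_task_cohort(cohort, "sepsis")
sel$n_kept; sum(sel$labels)
#> [1] 129
#> [1] 39

gs <- group_statistics(patient_index_summaries(cohort)[sel$index, ], sel$labels)
gs[, c("index", "statistic", "p_value", "significant")]
#>        index statistic      p_value significant
#> 1       sto2 -2.749301 7.219714e-03        TRUE
#> 2  perfusion -2.620742 1.031631e-02        TRUE
#> 3 hemoglobin  4.858494 8.905038e-06        TRUE
#> 4      water  2.374015 1.994575e-02       FALSE

rep <- run_experiment(cohort, task = "sepsis", modality = "hsi",
                      site = "palm", outer_folds_to_run = 1L, seed = 20240)
c(rep$auroc, rep$bootstrap$ci_low, rep$bootstrap$ci_high)
#> [1] 0.9930556 0.9619048 1.0000000
```

A 150-patient cohort with a planted latent effect (Bayes AUROC ≈ 0.95)
shows the expected pattern: of the 129 patients with a determinate
sepsis label, cases (n = 39) have significantly lower tissue oxygen
saturation and higher hemoglobin index below the 0.0125 Bonferroni
threshold (the water index points the right way but misses the
corrected threshold at this cohort size; at n = 300 all three pass),
and the 15-network HSI ensemble separates the held-out outer-fold
patients with AUROC 0.99 [0.96, 1.00].

The numbered drivers under `analysis/` run the full workflow —
`01_simulate_cohort.R` (writes ENVI cubes, annotations, tables under
`data/cohort/`), `02_preprocess.R`, `03_tissue_indices.R`,
`04_train_models.R`, `05_feature_importance.R` — each writing its
tables under `results/`.

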