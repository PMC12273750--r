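#!/usr/bin/env Rscript
## Classification experiments under the nested-CV protocol: the deep HSI
## model (one outer fold of the 5x5 scheme, 5 inner folds x 3 seeds =
## 15 ensembled networks) and the clinical random-forest model (all five
## outer folds). Writes AUROC summaries and ROC points under results/.
## The deep run takes a few minutes on one CPU at desk scale.

library(sepsishsi)

cfg <- cohort_config(n_patients = 150, cube_shape = c(32, 32, 100),
                     sites = "palm", seed = 20240)
cohort <- generate_cohort(cfg)

message("deep HSI model (palm, 15-network ensemble on outer fold 1) ...")
hsi <- run_experiment(cohort, task = "sepsis", modality = "hsi",
                      site = "palm", side = 16L, width_scale = 0.25,
                      outer_folds_to_run = 1L, seed = 20240)
message(sprintf("  HSI ensemble AUROC %.3f [%.3f, %.3f]",
                hsi$auroc, hsi$bootstrap$ci_low, hsi$bootstrap$ci_high))

message("clinical random-forest model (10h tier, full nested CV) ...")
clin <- run_experiment(cohort, task = "sepsis", modality = "clinical",
                       tier = "10h", seed = 20240)
message(sprintf("  clinical AUROC %.3f [%.3f, %.3f]",
                clin$auroc, clin$bootstrap$ci_low, clin$bootstrap$ci_high))

dir.create("results", showWarnings = FALSE)
tab <- data.frame(
  model = c("hsi_palm", "clinical_10h"),
  auroc = c(hsi$auroc, clin$auroc),
  boot_mean = c(hsi$bootstrap$mean, clin$bootstrap$mean),
  boot_sd = c(hsi$bootstrap$sd, clin$bootstrap$sd),
  ci_low = c(hsi$bootstrap$ci_low, clin$bootstrap$ci_low),
  ci_high = c(hsi$bootstrap$ci_high, clin$bootstrap$ci_high),
  n_test = c(length(hsi$labels), length(clin$labels)),
  n_models_per_fold = c(hsi$n_models_per_fold, clin$n_models_per_fold))
write.csv(tab, "results/model_auroc.csv", row.names = FALSE)
write.csv(hsi$roc, "results/roc_hsi_palm.csv", row.names = FALSE)
write.csv(clin$roc, "results/roc_clinical_10h.csv", row.names = FALSE)
message("wrote results/model_auroc.csv")
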