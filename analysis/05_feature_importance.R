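#!/usr/bin/env Rscript
## Clinical feature importance: recursive feature elimination with
## importances averaged over the inner folds (independently per outer
## fold, combined by mean rank), then the feature staircase - the
## clinical model restricted to the top-1, top-2, top-3 and all
## features. Writes the ranking and staircase tables under results/.

library(sepsishsi)

cfg <- cohort_config(n_patients = 150, cube_shape = c(16, 16, 10),
                     sites = "palm", seed = 20240)
cohort <- generate_cohort(cfg, render_images = FALSE)

fs <- feature_staircase(cohort, task = "sepsis", tier = "10h",
                        seed = 20240)
message("RFE ranking (top 10): ",
        paste(head(fs$ranking, 10), collapse = ", "))
print(fs$staircase, digits = 3)

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(rank = seq_along(fs$ranking), feature = fs$ranking),
          "results/feature_ranking.csv", row.names = FALSE)
write.csv(fs$staircase, "results/feature_staircase.csv", row.names = FALSE)
message("wrote results/feature_ranking.csv and results/feature_staircase.csv")
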