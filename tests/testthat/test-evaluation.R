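test_that("task cohorts drop indeterminate labels", {
  manifest <- data.frame(
    patient_id = sprintf("P%02d", 1:10),
    sepsis = c(rep("sepsis", 3), rep("no_sepsis", 5), "unsure", "unsure"),
    mortality = c(rep("nonsurvivor", 2), rep("survivor", 7), "unknown"))
  s <- select_task_cohort(manifest, "sepsis")
  expect_equal(s$n_kept, 8L); expect_equal(s$n_dropped, 2L)
  expect_equal(sum(s$labels), 3L)
  m <- select_task_cohort(manifest, "mortality")
  expect_equal(m$n_kept, 9L)
  ## no indeterminate labels: identity
  clean <- manifest[manifest$sepsis != "unsure", ]
  expect_equal(select_task_cohort(clean, "sepsis")$n_kept, nrow(clean))
  all_unsure <- manifest; all_unsure$sepsis <- "unsure"
  expect_error(select_task_cohort(all_unsure, "sepsis"), "no evaluable")
})

test_that("nested splits partition, stratify, and reproduce under a seed", {
  ids <- sprintf("P%03d", 1:20)
  labels <- rep(c(0L, 1L), each = 10)
  sp <- make_nested_splits(ids, labels, outer = 5, inner = 5, seed = 3)
  tests <- lapply(sp$outer, `[[`, "test")
  expect_equal(vapply(tests, length, integer(1)), rep(4L, 5))
  expect_equal(sort(unlist(tests)), 1:20)
  expect_equal(anyDuplicated(unlist(tests)), 0L)
  for (fold in sp$outer) {
    expect_length(intersect(fold$test, fold$train), 0L)
    ## class counts per outer fold within 1 of proportionality
    expect_lte(abs(sum(labels[fold$test]) - 2), 1)
    ## inner folds partition the outer training set
    vals <- lapply(fold$inner, `[[`, "val")
    expect_equal(sort(unlist(vals)), sort(fold$train))
    for (inn in fold$inner)
      expect_length(intersect(inn$train, inn$val), 0L)
  }
  sp2 <- make_nested_splits(ids, labels, outer = 5, inner = 5, seed = 3)
  expect_identical(sp, sp2)
})

test_that("logit ensembling is the arithmetic mean with an ensemble-size check", {
  l1 <- matrix(c(1, 0), 1); l2 <- matrix(c(0, 1), 1)
  expect_equal(ensemble_logits(list(l1, l2)), matrix(c(0.5, 0.5), 1))
  same <- replicate(15, matrix(c(0.3, -0.2), 1), simplify = FALSE)
  expect_equal(ensemble_logits(same, expected = 15), same[[1]])
  expect_warning(ensemble_logits(list(l1, l2), expected = 15), "expected 15")
})

test_that("AUROC equals exhaustive pairwise enumeration on 1000 random instances", {
  expect_equal(compute_auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))$auroc,
               0.75)
  expect_equal(compute_auroc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auroc, 1)
  expect_equal(compute_auroc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auroc, 0.5)
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    labels <- integer(n)
    while (length(unique(labels)) < 2) labels <- rbinom(n, 1, 0.5)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    expect_identical(compute_auroc(scores, labels)$auroc,
                     pairwise_auroc(scores, labels))
  }
  expect_error(compute_auroc(1:4, rep(1, 4)), "both classes")
})

test_that("ROC points sweep monotonically from (0,0) to (1,1)", {
  set.seed(1)
  scores <- runif(40); labels <- rbinom(40, 1, 0.4)
  roc <- compute_auroc(scores, labels)$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("bootstrap summaries are ordered, sized B, and redraw degenerate resamples", {
  set.seed(4)
  scores <- c(rnorm(30, 1), rnorm(30))
  labels <- rep(c(1L, 0L), each = 30)
  bs <- bootstrap_metric(scores, labels, B = 200)
  expect_equal(bs$B, 200)
  expect_lte(bs$ci_low, bs$mean); expect_gte(bs$ci_high, bs$mean)
  expect_gte(bs$sd, 0)
  ## perfectly separated large sample: tight interval
  sep <- c(rep(1, 50), rep(0, 50)); lab <- c(rep(1L, 50), rep(0L, 50))
  bsep <- bootstrap_metric(sep, lab, B = 100)
  expect_equal(bsep$ci_low, 1); expect_equal(bsep$ci_high, 1)
  ## property sweep: ordering always holds
  for (i in 1:100) {
    n <- sample(6:15, 1)
    l <- c(1L, 0L, rbinom(n - 2, 1, 0.5))
    b <- bootstrap_metric(runif(n), l, B = 30)
    expect_lte(b$ci_low, b$ci_high)
  }
})

test_that("bootstrap CI covers a known AUROC at nominal-ish rate", {
  ## planted score model with analytically known AUROC
  d <- 1.2
  truth <- pnorm(d / sqrt(2))
  set.seed(12)
  cover <- 0
  runs <- 120
  for (i in seq_len(runs)) {
    labels <- rep(c(1L, 0L), each = 40)
    scores <- c(rnorm(40, d), rnorm(40))
    b <- bootstrap_metric(scores, labels, B = 250)
    cover <- cover + (b$ci_low <= truth && truth <= b$ci_high)
  }
  expect_gte(cover / runs, 0.87)
  expect_lte(cover / runs, 0.995)
})

test_that("Welch test matches the reference implementation to 1e-6", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  w <- welch_test(a, b)
  ref <- t.test(a, b)   # Welch by default
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-6)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-6)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-6)
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:30, 1), 0.3, sd = runif(1, 0.5, 3))
    w <- welch_test(x, y); ref <- t.test(x, y)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-6)
  }
  ## identical groups and antisymmetry
  z <- c(1, 2, 3)
  expect_equal(welch_test(z, z)$statistic, 0)
  expect_equal(welch_test(z, z)$p_value, 1)
  w1 <- welch_test(a, b); w2 <- welch_test(b, a)
  expect_equal(w1$statistic, -w2$statistic)
  expect_equal(w1$p_value, w2$p_value)
  expect_error(welch_test(1, z), "n >= 2")
})

test_that("Bonferroni arithmetic is exact", {
  expect_identical(bonferroni_alpha(0.05, 4), 0.0125)
  expect_identical(bonferroni_alpha(0.07, 1), 0.07)
  expect_identical(bonferroni_alpha(0.05, 5), 0.01)
  expect_identical(bonferroni_alpha(0.05, 4) * 4, 0.05)
})

test_that("RFE returns a permutation, breaks ties canonically, and recovers planted signal", {
  set.seed(6)
  n <- 400
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", sprintf("%02d", 1:10))))
  y <- as.integer(X[, 4] + rnorm(n, sd = 0.4) > 0)
  inner <- lapply(1:5, function(k) sample(n, 300))
  fr <- rfe_rank_features(X, y, inner, seed = 3)
  expect_setequal(fr$ranking, colnames(X))
  expect_equal(fr$ranking[1], "f04")
  ## duplicated identical features: later canonical column eliminated first
  X2 <- X; X2[, 7] <- X2[, 4]
  colnames(X2)[7] <- "f04b"
  fr2 <- rfe_rank_features(X2, y, inner, seed = 3)
  expect_setequal(fr2$ranking, colnames(X2))
  ## rankings combine by mean rank
  comb <- combine_rankings(list(c("a", "b", "c"), c("b", "a", "c")))
  expect_equal(comb[3], "c")
})

test_that("clinical nested-CV experiment produces a complete report", {
  cfg <- cohort_config(n_patients = 80, cube_shape = c(16, 16, 10),
                       sites = "palm", seed = 21, clinical_effect_size = 2)
  co <- generate_cohort(cfg, render_images = FALSE)
  rep <- run_experiment(co, task = "sepsis", modality = "clinical",
                        tier = "10h", outer = 5, inner = 5, n_seeds = 3,
                        B = 100, seed = 21)
  expect_equal(rep$n_models_per_fold, 15L)
  expect_length(rep$scores, rep$bootstrap$B * 0 + length(rep$labels))
  sel <- select_task_cohort(co, "sepsis")
  expect_equal(length(rep$scores), sel$n_kept)  # pooled over all outer folds
  expect_gt(rep$auroc, 0.7)  # strong planted clinical signal
  expect_true(rep$bootstrap$ci_low <= rep$auroc &&
              rep$auroc <= rep$bootstrap$ci_high)
  ## determinism of the full pipeline
  rep2 <- run_experiment(co, task = "sepsis", modality = "clinical",
                         tier = "10h", outer = 5, inner = 5, n_seeds = 3,
                         B = 100, seed = 21)
  expect_identical(rep$scores, rep2$scores)
  expect_identical(rep$auroc, rep2$auroc)
  ## split hygiene on ids: every patient appears exactly once pooled
  expect_setequal(rep$ids, sel$ids)
  expect_equal(anyDuplicated(rep$ids), 0L)
})
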