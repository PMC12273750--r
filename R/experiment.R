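#' Prepare model-ready inputs for a set of patients
#'
#' Applies the preprocessing chain per modality:
#' * `"hsi"`: l1 spectral normalization, crop to the circular
#'   annotation, bilinear rescale to `side`;
#' * `"tpi"`: crop/rescale the (non-normalized) reflectance, then
#'   compute the four tissue-parameter indices;
#' * `"rgb"`: crop/rescale the RGB rendering;
#' * `"hsi_stacked"`: the `"hsi"` chain for palm and finger, stacked
#'   along the spectral dimension.
#'
#' @param samples List of patient samples (see [generate_cohort()]).
#' @param modality One of `"hsi"`, `"tpi"`, `"rgb"`, `"hsi_stacked"`.
#' @param site `"palm"` or `"finger"` (ignored for `"hsi_stacked"`).
#' @param side Model input side length.
#' @param registry Index registry for the TPI modality.
#' @return List with `images` (array `side x side x C x N`), `masks`
#'   (`side x side x N`), `ids`.
#' @export
prepare_model_inputs <- function(samples, modality = "hsi", site = "palm",
                                 side = 32L,
                                 registry = default_index_registry()) {
  one <- function(s) {
    if (modality == "hsi_stacked") {
      parts <- lapply(c("palm", "finger"), function(st) {
        im <- s$images[[st]]
        rescale_to_model_input(
          crop_to_annotation(l1_normalize(im$cube), im$annotation),
          side, modality = "hsi")
      })
      return(stack_sites(parts[[1L]], parts[[2L]]))
    }
    im <- s$images[[site]]
    if (is.null(im)) stop("site ", site, " not rendered for ", s$patient_id)
    if (modality == "hsi") {
      rescale_to_model_input(
        crop_to_annotation(l1_normalize(im$cube), im$annotation),
        side, modality = "hsi")
    } else if (modality == "tpi") {
      mi <- rescale_to_model_input(
        crop_to_annotation(im$cube, im$annotation), side, modality = "hsi")
      compute_tpi(mi, registry)
    } else if (modality == "rgb") {
      cropped <- crop_to_annotation(im$rgb, im$annotation)
      cropped$patient_id <- s$patient_id
      cropped$site <- site
      rescale_to_model_input(cropped, side, modality = "rgb")
    } else stop("unknown modality: ", modality)
  }
  cubes <- lapply(samples, one)
  C <- dim(cubes[[1L]]$data)[3L]
  n <- length(cubes)
  images <- array(0, c(side, side, C, n))
  masks <- array(FALSE, c(side, side, n))
  for (i in seq_len(n)) {
    images[, , , i] <- cubes[[i]]$data
    masks[, , i] <- cubes[[i]]$mask
  }
  list(images = images, masks = masks,
       ids = vapply(samples, `[[`, character(1), "patient_id"))
}

#' Clinical feature matrix for a set of patients
#'
#' @param samples List of patient samples.
#' @param tier `"1h"` or `"10h"`.
#' @return Matrix n x p (p = 33 or 45), missing values imputed with -1.
#' @export
prepare_clinical_matrix <- function(samples, tier = c("10h", "1h")) {
  tier <- match.arg(tier)
  t(vapply(samples, function(s) impute_clinical(s$clinical, tier),
           numeric(length(tier_features(tier)))))
}

derive_seed <- function(base, ...) {
  ## double arithmetic stays exact below 2^53 and the modulus keeps the
  ## result a valid 32-bit seed
  s <- as.numeric(base)
  for (v in c(...)) s <- (s * 131 + as.numeric(v)) %% 2000000011
  as.integer(s)
}

#' Run one classification experiment under the nested-CV protocol
#'
#' Executes the full evaluation protocol for one (task, modality, site,
#' tier) combination on a synthetic cohort: task-cohort selection,
#' label-stratified nested cross-validation, per-(inner fold, seed)
#' model training, ensembling of the inner-fold models' test
#' predictions (5 folds x 3 seeds = 15 networks by default, averaged
#' logits; averaged probabilities for the random forest), pooling of
#' the outer-fold test predictions, and AUROC with a 1000-resample
#' bootstrap confidence interval.
#'
#' @param cohort Result of [generate_cohort()].
#' @param task `"sepsis"` or `"mortality"`.
#' @param modality `"hsi"`, `"tpi"`, `"rgb"`, `"hsi_stacked"`,
#'   `"clinical"` (random forest) or `"hsi+clinical"` (fusion model).
#' @param site Measurement site for image modalities.
#' @param tier Clinical availability tier for clinical/fusion.
#' @param side Model input side length.
#' @param width_scale CNN width multiplier.
#' @param hp [training_hyperparameters()] (its seed is re-derived per
#'   fold/repetition).
#' @param outer,inner Fold counts.
#' @param n_seeds Training repetitions per inner fold.
#' @param outer_folds_to_run Integer subset of `1:outer` (NULL = all);
#'   running a subset scales the protocol down while keeping the
#'   per-fold ensemble intact.
#' @param B Bootstrap resamples.
#' @param seed Experiment seed (drives splits, training seeds,
#'   bootstrap).
#' @param clinical_features Optional subset of clinical feature names
#'   (canonical order is preserved).
#' @return Evaluation report list: pooled `scores`/`labels`, `auroc`,
#'   `roc`, `bootstrap` summary, `n_models_per_fold`, the settings, and
#'   per-fold details.
#' @export
run_experiment <- function(cohort, task = "sepsis", modality = "hsi",
                           site = "palm", tier = "10h", side = 16L,
                           width_scale = 0.25,
                           hp = training_hyperparameters(),
                           outer = 5L, inner = 5L, n_seeds = 3L,
                           outer_folds_to_run = NULL, B = 1000L,
                           seed = 1L, clinical_features = NULL) {
  sel <- select_task_cohort(cohort, task)
  samples <- cohort$samples[sel$index]
  labels <- sel$labels

  use_images <- modality %in% c("hsi", "tpi", "rgb", "hsi_stacked",
                                "hsi+clinical")
  use_clinical <- modality %in% c("clinical", "hsi+clinical")
  inputs <- NULL; clin <- NULL
  if (use_images) {
    img_modality <- if (modality == "hsi+clinical") "hsi" else modality
    inputs <- prepare_model_inputs(samples, img_modality, site, side)
  }
  if (use_clinical) {
    clin <- prepare_clinical_matrix(samples, tier)
    if (!is.null(clinical_features))
      clin <- clin[, intersect(colnames(clin), clinical_features),
                   drop = FALSE]
    clin_scaled <- scale(clin)
    clin_scaled[!is.finite(clin_scaled)] <- 0
  }

  splits <- make_nested_splits(sel$ids, labels, outer, inner, seed)
  folds <- outer_folds_to_run %||% seq_len(outer)

  pooled_scores <- numeric(0); pooled_labels <- integer(0)
  pooled_ids <- character(0)
  fold_details <- list()

  for (of in folds) {
    fold <- splits$outer[[of]]
    test <- fold$test
    members <- list()
    for (k in seq_len(inner)) {
      tr <- fold$inner[[k]]$train
      for (s in seq_len(n_seeds)) {
        sd <- derive_seed(seed, of, k, s)
        if (modality == "clinical") {
          rf <- fit_random_forest(clin[tr, , drop = FALSE], labels[tr],
                                  seed = sd)
          members[[length(members) + 1L]] <-
            cbind(0, predict_scores(rf, clin[test, , drop = FALSE])$prob)
        } else {
          hp_run <- hp; hp_run$seed <- sd
          n_feat <- if (use_clinical) ncol(clin) else NULL
          model <- if (modality == "hsi+clinical") {
            build_fusion_model(
              image_model_config(dim(inputs$images)[3L], width_scale),
              fusion_model_config(), n_features = n_feat, seed = sd)
          } else {
            build_image_model(
              image_model_config(dim(inputs$images)[3L], width_scale),
              seed = sd)
          }
          data_tr <- list(
            images = inputs$images[, , , tr, drop = FALSE],
            masks = inputs$masks[, , tr, drop = FALSE],
            clinical = if (use_clinical) clin_scaled[tr, , drop = FALSE])
          model <- train_classifier(model, data_tr, labels[tr], hp_run)
          data_te <- list(
            images = inputs$images[, , , test, drop = FALSE],
            clinical = if (use_clinical) clin_scaled[test, , drop = FALSE])
          members[[length(members) + 1L]] <-
            predict_scores(model, data_te)$logits
        }
      }
    }
    ens <- ensemble_logits(members, expected = inner * n_seeds)
    scores <- if (modality == "clinical") ens[, 2L] else {
      e <- exp(ens - apply(ens, 1L, max)); (e / rowSums(e))[, 2L]
    }
    pooled_scores <- c(pooled_scores, scores)
    pooled_labels <- c(pooled_labels, labels[test])
    pooled_ids <- c(pooled_ids, sel$ids[test])
    fold_details[[length(fold_details) + 1L]] <-
      list(fold = of, n_models = length(members),
           auroc = compute_auroc(scores, labels[test])$auroc)
  }

  roc <- compute_auroc(pooled_scores, pooled_labels)
  set.seed(derive_seed(seed, 997L))
  bs <- bootstrap_metric(pooled_scores, pooled_labels, B = B)
  list(task = task, modality = modality, site = site, tier = tier,
       side = side, width_scale = width_scale,
       n_models_per_fold = inner * n_seeds,
       folds_run = folds, fold_details = fold_details,
       ids = pooled_ids, scores = pooled_scores, labels = pooled_labels,
       auroc = roc$auroc, roc = roc$roc, bootstrap = bs, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-patient tissue index summaries for a cohort
#'
#' Crops each patient's reflectance cube to its annotation at native
#' resolution, computes the four tissue-parameter indices, and takes
#' the in-mask median per channel.
#'
#' @param cohort Result of [generate_cohort()].
#' @param site Measurement site.
#' @param registry Index registry.
#' @return data.frame: `patient_id`, `sto2`, `perfusion`, `hemoglobin`,
#'   `water`.
#' @export
patient_index_summaries <- function(cohort, site = "palm",
                                    registry = default_index_registry()) {
  rows <- lapply(cohort$samples, function(s) {
    im <- s$images[[site]]
    cropped <- crop_to_annotation(im$cube, im$annotation)
    mi <- model_input_cube(cropped$data, cropped$mask, s$patient_id,
                           site, "hsi")
    mi$wavelengths <- cropped$wavelengths
    summarize_patient_indices(compute_tpi(mi, registry))
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(patient_id = cohort$manifest$patient_id, out)
}

#' Welch/Bonferroni group statistics on the tissue indices
#'
#' Two-sided Welch's t tests comparing the per-patient index summaries
#' between groups, with the family-wise level 0.05 Bonferroni-corrected
#' across the four indices (0.0125 per test).
#'
#' @param summaries Result of [patient_index_summaries()] (the task
#'   cohort's rows).
#' @param labels Integer 0/1 group labels parallel to `summaries` rows.
#' @param alpha_overall Family-wise significance level.
#' @return data.frame with one row per index: group means, `statistic`,
#'   `df`, `p_value`, `alpha_per_test`, `significant`, `direction`
#'   (sign of case mean minus control mean).
#' @export
group_statistics <- function(summaries, labels, alpha_overall = 0.05) {
  idx_cols <- c("sto2", "perfusion", "hemoglobin", "water")
  a <- bonferroni_alpha(alpha_overall, length(idx_cols))
  rows <- lapply(idx_cols, function(cl) {
    cases <- summaries[[cl]][labels == 1L]
    controls <- summaries[[cl]][labels == 0L]
    w <- welch_test(cases, controls)
    data.frame(index = cl, mean_case = mean(cases),
               mean_control = mean(controls),
               statistic = w$statistic, df = w$df, p_value = w$p_value,
               alpha_per_test = a, significant = w$p_value < a,
               direction = sign(mean(cases) - mean(controls)))
  })
  do.call(rbind, rows)
}

#' Clinical feature-importance staircase
#'
#' Ranks the tier's clinical features by recursive feature elimination
#' (importances averaged over the inner folds, independently per outer
#' fold, combined by mean rank), then evaluates the clinical
#' random-forest model restricted to the top-1, top-2, top-3 and all
#' features under the same nested-CV/ensembling/bootstrap protocol.
#'
#' @param cohort Result of [generate_cohort()].
#' @param task Task name.
#' @param tier Clinical tier.
#' @param sizes Feature-subset sizes (NA = all).
#' @param outer,inner,n_seeds,B,seed As in [run_experiment()].
#' @return List with `ranking` (combined), `per_fold_rankings`, and
#'   `staircase` (data.frame: size, features, auroc, ci).
#' @export
feature_staircase <- function(cohort, task = "sepsis", tier = "10h",
                              sizes = c(1L, 2L, 3L, NA), outer = 5L,
                              inner = 5L, n_seeds = 3L, B = 1000L,
                              seed = 1L) {
  sel <- select_task_cohort(cohort, task)
  samples <- cohort$samples[sel$index]
  labels <- sel$labels
  clin <- prepare_clinical_matrix(samples, tier)
  splits <- make_nested_splits(sel$ids, labels, outer, inner, seed)

  per_fold <- lapply(seq_len(outer), function(of) {
    fold <- splits$outer[[of]]
    rfe_rank_features(clin, labels,
                      lapply(fold$inner, `[[`, "train"),
                      seed = derive_seed(seed, 555L, of))
  })
  ranking <- combine_rankings(per_fold)

  rows <- lapply(sizes, function(sz) {
    feats <- if (is.na(sz)) colnames(clin) else ranking[seq_len(sz)]
    rep <- run_experiment(cohort, task, "clinical", tier = tier,
                          outer = outer, inner = inner, n_seeds = n_seeds,
                          B = B, seed = seed, clinical_features = feats)
    data.frame(size = if (is.na(sz)) ncol(clin) else sz,
               features = paste(feats, collapse = "+"),
               auroc = rep$auroc, ci_low = rep$bootstrap$ci_low,
               ci_high = rep$bootstrap$ci_high)
  })
  list(ranking = ranking, per_fold_rankings = per_fold,
       staircase = do.call(rbind, rows))
}
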