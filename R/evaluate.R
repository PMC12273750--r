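#' Select the evaluable cohort for a task
#'
#' The sepsis task drops patients whose sepsis status is indeterminate
#' ("unsure"); the mortality task drops patients lost to 30-day
#' follow-up ("unknown").
#'
#' @param manifest A cohort manifest data.frame (or the result of
#'   [generate_cohort()]), with columns `patient_id`, `sepsis`,
#'   `mortality`.
#' @param task `"sepsis"` or `"mortality"`.
#' @return List with `ids`, integer `labels` (1 = sepsis / nonsurvivor),
#'   `index` (row positions in the manifest), `n_dropped`, `n_kept`.
#' @export
select_task_cohort <- function(manifest, task = c("sepsis", "mortality")) {
  task <- match.arg(task)
  if (is.list(manifest) && !is.data.frame(manifest) &&
      !is.null(manifest$manifest))
    manifest <- manifest$manifest
  if (task == "sepsis") {
    keep <- manifest$sepsis != "unsure"
    labels <- as.integer(manifest$sepsis[keep] == "sepsis")
  } else {
    keep <- manifest$mortality != "unknown"
    labels <- as.integer(manifest$mortality[keep] == "nonsurvivor")
  }
  if (!any(keep)) stop("no evaluable patients remain for task ", task)
  list(ids = manifest$patient_id[keep], labels = labels,
       index = which(keep), n_dropped = sum(!keep), n_kept = sum(keep))
}

stratified_partition <- function(idx, labels, k) {
  folds <- vector("list", k)
  for (cl in unique(labels)) {
    members <- sample(idx[labels == cl])
    assign_to <- rep(seq_len(k), length.out = length(members))
    for (f in seq_len(k))
      folds[[f]] <- c(folds[[f]], members[assign_to == f])
  }
  lapply(folds, sort)
}

#' Nested, label-stratified cross-validation splits
#'
#' Patient-level 5x5 nested scheme: the outer folds partition the
#' cohort (per-fold class counts within 1 of proportionality); within
#' each outer training set, inner folds partition it again. Deterministic
#' under `seed`.
#'
#' @param ids Patient identifiers.
#' @param labels Integer 0/1 labels parallel to `ids`.
#' @param outer,inner Fold counts (default 5 and 5).
#' @param seed Integer seed.
#' @return Object of class `nested_splits`: list `outer`, each element
#'   holding `test`, `train` (index vectors into `ids`) and `inner`, a
#'   list of `(train, val)` index pairs partitioning `train`.
#' @export
make_nested_splits <- function(ids, labels, outer = 5L, inner = 5L,
                               seed = 1L) {
  stopifnot(length(ids) == length(labels), outer >= 2L, inner >= 2L)
  set.seed(seed)
  n <- length(ids)
  outer_folds <- stratified_partition(seq_len(n), labels, outer)
  res <- lapply(outer_folds, function(test) {
    train <- setdiff(seq_len(n), test)
    inner_folds <- stratified_partition(train, labels[train], inner)
    inner_list <- lapply(inner_folds, function(val)
      list(train = setdiff(train, val), val = val))
    list(test = test, train = train, inner = inner_list)
  })
  structure(list(outer = res, ids = ids, labels = labels,
                 n_outer = outer, n_inner = inner, seed = seed),
            class = "nested_splits")
}

#' Average per-model logits
#'
#' Test-set ensembling: the predictions (logits) of the inner-fold
#' models across all repetition seeds are averaged arithmetically. A
#' deviation from the expected ensemble size (5 folds x 3 seeds = 15)
#' is reported as a warning.
#'
#' @param logits_list List of N x 2 logit matrices.
#' @param expected Expected number of models (NULL to skip the check).
#' @return Mean logit matrix.
#' @export
ensemble_logits <- function(logits_list, expected = NULL) {
  stopifnot(length(logits_list) >= 1L)
  if (!is.null(expected) && length(logits_list) != expected)
    warning("ensembling ", length(logits_list), " models, expected ",
            expected)
  Reduce(`+`, logits_list) / length(logits_list)
}

#' AUROC and ROC points
#'
#' Computes the area under the ROC curve via midranks, equal to
#' `(#(pos > neg) + 0.5 * #ties) / (n_pos * n_neg)`, plus the ROC points
#' swept over all score thresholds.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Integer 0/1 vector.
#' @return List with `auroc` and `roc` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
compute_auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("AUROC needs both classes present")
  r <- rank(scores)
  auroc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1L); fp <- cumsum(labels[ord] == 0L)
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  roc <- data.frame(threshold = c(Inf, scores[ord][keep]),
                    fpr = c(0, fp[keep] / nneg),
                    tpr = c(0, tp[keep] / npos))
  list(auroc = auroc, roc = roc)
}

#' Bootstrap summary of the AUROC
#'
#' Draws `B` resamples of size `|T|` with replacement from the test set;
#' resamples missing a class are redrawn (and counted). Reports the
#' point estimate, bootstrap mean and standard deviation, and the
#' percentile 95% confidence interval. Uses R's global random stream.
#'
#' @param scores,labels Test-set scores and 0/1 labels.
#' @param B Number of bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param metric Function `(scores, labels) -> numeric` (default AUROC).
#' @return Object of class `bootstrap_summary`: `B`, `point_estimate`,
#'   `mean`, `sd`, `ci_low`, `ci_high`, `n_redrawn`.
#' @export
bootstrap_metric <- function(scores, labels, B = 1000L, conf = 0.95,
                             metric = NULL) {
  if (is.null(metric))
    metric <- function(s, l) compute_auroc(s, l)$auroc
  n <- length(scores)
  vals <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) > 1L) break
      n_redrawn <- n_redrawn + 1L
    }
    vals[b] <- metric(scores[idx], labels[idx])
  }
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(vals, c(a, 1 - a), type = 7))
  structure(list(B = B, point_estimate = metric(scores, labels),
                 mean = mean(vals), sd = stats::sd(vals),
                 ci_low = ci[1L], ci_high = ci[2L],
                 n_redrawn = n_redrawn),
            class = "bootstrap_summary")
}

#' Two-sided Welch's t test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite
#' degrees of freedom and a two-sided p value from the t distribution.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2, nonzero
#'   variance in at least one group).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_test <- function(group_a, group_b) {
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2")
  v1 <- stats::var(group_a); v2 <- stats::var(group_b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(list(statistic = 0, df = n1 + n2 - 2, p_value = 1))
  t <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}

#' Bonferroni-corrected per-test significance level
#'
#' @param alpha_overall Family-wise level (e.g. 0.05).
#' @param m Number of tests in the family (4 index comparisons give
#'   0.0125 per test).
#' @return `alpha_overall / m`.
#' @export
bonferroni_alpha <- function(alpha_overall, m) {
  stopifnot(alpha_overall >= 0, alpha_overall <= 1, m >= 1)
  alpha_overall / m
}

#' Recursive feature elimination with inner-fold averaging
#'
#' Fits the balanced random forest on each inner fold's training set,
#' averages the impurity importances across the inner folds, removes
#' the single least-important feature, and repeats until one feature
#' remains. Ties on the minimum averaged importance are broken
#' deterministically by eliminating the feature that comes later in
#' canonical column order.
#'
#' @param features Numeric matrix/data.frame (n x p), named columns in
#'   canonical schema order.
#' @param labels Integer 0/1 labels.
#' @param inner_train_sets List of index vectors (the inner folds'
#'   training sets).
#' @param seed Integer seed (per-fit forest seeds are derived from it).
#' @return Object of class `feature_ranking`: `ranking` (most important
#'   first; a permutation of the input features), `elimination_order`
#'   and `step_importances`.
#' @export
rfe_rank_features <- function(features, labels, inner_train_sets,
                              seed = 1L) {
  features <- as.matrix(features)
  p <- ncol(features)
  stopifnot(!is.null(colnames(features)), p >= 1L)
  set.seed(seed)
  remaining <- colnames(features)
  eliminated <- character(0)
  step_importances <- list()
  while (length(remaining) > 1L) {
    imp <- rep(0, length(remaining))
    names(imp) <- remaining
    for (tr in inner_train_sets) {
      fit <- fit_random_forest(features[tr, remaining, drop = FALSE],
                               labels[tr],
                               seed = sample.int(.Machine$integer.max, 1L))
      imp <- imp + fit$importance[remaining]
    }
    imp <- imp / length(inner_train_sets)
    step_importances[[length(step_importances) + 1L]] <- imp
    ## ties: eliminate the later feature in canonical order
    worst <- max(which(imp == min(imp)))
    eliminated <- c(eliminated, remaining[worst])
    remaining <- remaining[-worst]
  }
  eliminated <- c(eliminated, remaining)
  structure(list(ranking = rev(eliminated),
                 elimination_order = eliminated,
                 step_importances = step_importances),
            class = "feature_ranking")
}

#' Combine per-outer-fold rankings by mean rank
#'
#' @param rankings List of `feature_ranking` objects (or character
#'   vectors, most important first).
#' @return Character vector of features ordered by mean rank (ties by
#'   canonical order of the first ranking).
#' @export
combine_rankings <- function(rankings) {
  vecs <- lapply(rankings, function(r)
    if (inherits(r, "feature_ranking")) r$ranking else r)
  feats <- vecs[[1L]]
  mean_rank <- rowMeans(vapply(vecs, function(v) match(feats, v),
                               numeric(length(feats))))
  feats[order(mean_rank)]
}
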