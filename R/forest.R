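#' Balanced random-forest clinical model
#'
#' 100 trees with class weights inversely proportional to the training
#' class frequencies; other settings follow common reference defaults
#' (Gini impurity splitting, bootstrap resampling, sqrt(p) features per
#' split). Exposes impurity-based feature importances renormalized to
#' sum to 1. Backed by `ranger`.
#'
#' @param features Numeric matrix or data.frame (n x p) with column
#'   names.
#' @param labels Integer 0/1 vector (1 = positive class).
#' @param num_trees Number of trees (default 100).
#' @param seed Integer seed for the forest's randomness.
#' @return Object of class `sepsishsi_rf` with elements `fit` (the
#'   ranger object), `importance` (named, sums to 1) and `num_trees`.
#' @export
fit_random_forest <- function(features, labels, num_trees = 100L, seed = 1L) {
  df <- as.data.frame(features)
  if (is.null(colnames(features)))
    colnames(df) <- paste0("f", seq_len(ncol(df)))
  y <- factor(labels, levels = c(0L, 1L))
  if (any(table(y) == 0L)) stop("both classes must be present")
  freq <- as.numeric(table(y)) / length(y)
  df$.outcome <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".outcome", data = df,
    num.trees = num_trees, probability = TRUE,
    importance = "impurity", class.weights = 1 / freq,
    seed = seed, num.threads = 1L)
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp),
                                                   length(imp))
  structure(list(fit = fit, importance = imp, num_trees = num_trees),
            class = "sepsishsi_rf")
}

#' @export
predict_scores.sepsishsi_rf <- function(model, data, ...) {
  df <- as.data.frame(data)
  if (is.null(colnames(data))) colnames(df) <- paste0("f", seq_len(ncol(df)))
  pr <- stats::predict(model$fit, data = df, num.threads = 1L)$predictions
  list(logits = NULL, prob = pr[, "1"])
}
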