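#' Cross-validation configuration
#'
#' @param k Fold count (default 10).
#' @param fold_seed Integer seed for the fold assignment; the same seed
#'   always yields the same folds.
#' @param stratified Stratify folds by group label (default TRUE).
#' @param C,gamma RBF-kernel SVM hyperparameters (both > 0). `gamma = NULL`
#'   uses the libsvm default 1 / n_features at fit time.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(k = 10L, fold_seed = 1L, stratified = TRUE,
                      C = 1, gamma = NULL) {
  if (!is_count(k) || k < 2L) stop_("k must be an integer >= 2")
  if (!is.null(C) && (!is.numeric(C) || C <= 0)) stop_("C must be positive")
  if (!is.null(gamma) && (!is.numeric(gamma) || gamma <= 0)) {
    stop_("gamma must be positive")
  }
  structure(list(k = as.integer(k), fold_seed = as.integer(fold_seed),
                 stratified = isTRUE(stratified), C = C, gamma = gamma),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Deterministically assigns each participant to one of `k` folds. With
#' stratification each fold's class proportions are within one participant
#' of exact balance.
#'
#' @param labels 0/1 group labels.
#' @param k Fold count.
#' @param fold_seed Integer seed.
#' @param stratified Stratify by label (default TRUE).
#' @return Integer vector of fold ids in 1..k, one per participant.
#' @export
stratified_folds <- function(labels, k = 10L, fold_seed = 1L,
                             stratified = TRUE) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (!is_count(k) || k < 2L) stop_("k must be an integer >= 2")
  if (k > n) stop_("k = %d exceeds participant count %d", k, n)
  local_seed(fold_seed, {
    folds <- integer(n)
    if (stratified) {
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        if (length(idx) < k) {
          stop_("class %d has %d members, fewer than k = %d folds",
                cl, length(idx), k)
        }
        folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    folds
  })
}

# Column indices of a feature matrix selected by a binary channel mask.
# For time/wavelet features a mask bit selects that channel's column; for
# FC features a pair column is kept only when BOTH endpoint channels are
# selected.
mask_columns <- function(fm, mask) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(mask)) return(seq_len(ncol(fm$values)))
  mask <- as.integer(mask)
  if (length(mask) != length(fm$channel_ids)) {
    stop_("mask length %d != channel count %d", length(mask),
          length(fm$channel_ids))
  }
  if (fm$kind == "fc") {
    keep <- which(mask[fm$pairs[, 1L]] == 1L & mask[fm$pairs[, 2L]] == 1L)
    if (!length(keep)) {
      stop_("channel mask selects no complete channel pair for FC features")
    }
    keep
  } else {
    keep <- which(mask == 1L)
    if (!length(keep)) stop_("empty channel mask selects no feature")
    keep
  }
}

# Standardize columns with training-fold statistics; zero-variance training
# columns pass through uncentered-scale 1 (constant columns carry no
# information but must not produce NaN).
fold_standardize <- function(train, test) {
  mu <- colMeans(train)
  s <- apply(train, 2L, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, s, "/"),
       test = sweep(sweep(test, 2L, mu), 2L, s, "/"))
}

#' Cross-validated SVM accuracy for a channel mask
#'
#' Trains an RBF-kernel SVM per fold on the masked feature columns
#' (standardized with training-fold statistics only) and pools the
#' out-of-fold predictions into a single confusion table.
#'
#' @param features A [feature_matrix()].
#' @param labels 0/1 group labels (1 = patient).
#' @param mask Binary channel mask, or NULL for all channels.
#' @param cv A [cv_config()].
#' @param folds Optional precomputed fold assignment (overrides
#'   `cv$fold_seed`); used to share one fold partition across many fitness
#'   evaluations within an optimization run.
#' @return List with `accuracy` (percent), `counts` (TP, TN, FP, FN) and
#'   `predictions` (pooled out-of-fold 0/1 predictions).
#' @export
cv_accuracy <- function(features, labels, mask = NULL, cv = cv_config(),
                        folds = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  labels <- as.integer(labels)
  n <- nrow(features$values)
  if (length(labels) != n) {
    stop_("label count %d != participants %d", length(labels), n)
  }
  if (length(unique(labels)) < 2L) stop_("labels contain a single class")
  cols <- mask_columns(features, mask)
  x <- features$values[, cols, drop = FALSE]
  if (is.null(folds)) {
    folds <- stratified_folds(labels, cv$k, cv$fold_seed, cv$stratified)
  }
  y <- factor(labels, levels = c(0L, 1L))
  pred <- integer(n)
  for (f in sort(unique(folds))) {
    te <- folds == f
    std <- fold_standardize(x[!te, , drop = FALSE], x[te, , drop = FALSE])
    gamma <- if (is.null(cv$gamma)) 1 / ncol(std$train) else cv$gamma
    fit <- e1071::svm(std$train, y[!te], type = "C-classification",
                      kernel = "radial", cost = cv$C, gamma = gamma,
                      scale = FALSE)
    pred[te] <- as.integer(as.character(stats::predict(fit, std$test)))
  }
  counts <- confusion_counts(labels, pred)
  list(accuracy = unname(100 * (counts["TP"] + counts["TN"]) / n),
       counts = counts, predictions = pred, folds = folds)
}

#' Confusion counts from labels and predictions
#'
#' @param labels,predictions 0/1 vectors; 1 = patient.
#' @return Named integer vector TP, TN, FP, FN.
#' @export
confusion_counts <- function(labels, predictions) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  c(TP = sum(labels == 1L & predictions == 1L),
    TN = sum(labels == 0L & predictions == 0L),
    FP = sum(labels == 0L & predictions == 1L),
    FN = sum(labels == 1L & predictions == 0L))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = (TP + TN) / total, sensitivity = TP / (TP + FN) (patient
#' recall), specificity = TN / (TN + FP) (control recall), all in percent.
#' A metric whose denominator is zero is reported as NA (undefined), not 0.
#'
#' @param counts Named vector or list with TP, TN, FP, FN.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`
#'   (percent).
#' @export
confusion_metrics <- function(counts) {
  counts <- unlist(counts)[c("TP", "TN", "FP", "FN")]
  if (anyNA(counts) || any(counts < 0)) stop_("counts must be non-negative TP/TN/FP/FN")
  tot <- sum(counts)
  ratio <- function(num, den) {
    if (den > 0) unname(100 * num / den) else NA_real_
  }
  c(accuracy = ratio(counts["TP"] + counts["TN"], tot),
    sensitivity = ratio(counts["TP"], counts["TP"] + counts["FN"]),
    specificity = ratio(counts["TN"], counts["TN"] + counts["FP"]))
}

#' Grid-search SVM hyperparameters
#'
#' Exhaustive search over a coarse logarithmic grid
#' (C in 2^(-5, -3, ..., 15), gamma in 2^(-15, -13, ..., 3)) selecting the
#' pair maximizing k-fold cross-validated accuracy; ties broken by smaller
#' C, then smaller gamma. Folds are fixed once from `cv$fold_seed`, so the
#' search is deterministic.
#'
#' @param features A [feature_matrix()].
#' @param labels 0/1 group labels.
#' @param cv A [cv_config()].
#' @param C_grid,gamma_grid Candidate values.
#' @param mask Optional channel mask to tune on.
#' @return List with `C`, `gamma`, `accuracy` (percent at the optimum).
#' @export
tune_hyperparameters <- function(features, labels, cv = cv_config(),
                                 C_grid = 2^seq(-5, 15, by = 2),
                                 gamma_grid = 2^seq(-15, 3, by = 2),
                                 mask = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop_("labels contain a single class")
  folds <- stratified_folds(labels, cv$k, cv$fold_seed, cv$stratified)
  best <- list(C = NA_real_, gamma = NA_real_, accuracy = -Inf)
  for (C in sort(C_grid)) {
    for (g in sort(gamma_grid)) {
      cvi <- cv
      cvi$C <- C; cvi$gamma <- g
      acc <- cv_accuracy(features, labels, mask, cvi, folds = folds)$accuracy
      if (acc > best$accuracy) best <- list(C = C, gamma = g, accuracy = acc)
    }
  }
  best
}
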