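#' Confusion counts at a probability threshold
#'
#' A sample is called positive iff its predicted probability is greater
#' than or equal to `threshold` (ties count as positive calls).
#'
#' @param labels true labels.
#' @param probabilities predicted probabilities in `[0, 1]`.
#' @param threshold classification threshold (default 0.5).
#' @return object of class `confusion_counts` with fields TP, FP, TN, FN.
#' @export
confusion <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) == 0) stop("empty input")
  if (length(labels) != length(probabilities)) stop("length mismatch")
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  y <- as_binary_label(labels)
  pred <- as.integer(probabilities >= threshold)
  structure(
    list(
      TP = sum(pred == 1L & y == 1L), FP = sum(pred == 1L & y == 0L),
      TN = sum(pred == 0L & y == 0L), FN = sum(pred == 0L & y == 1L)
    ),
    class = "confusion_counts"
  )
}

#' Threshold metrics from confusion counts
#'
#' Sensitivity, specificity, accuracy and the Matthews correlation
#' coefficient:
#' Sen = TP/(TP+FN), Spe = TN/(TN+FP), Acc = (TP+TN)/N,
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TN+FN)(TP+FN)(TN+FP)).
#' A metric with a zero denominator is reported as 0 and listed in the
#' `degenerate` field rather than raising an error.
#'
#' @param counts a `confusion_counts` object (or list with TP/FP/TN/FN).
#' @return list with `Sen`, `Spe`, `Acc`, `MCC` and `degenerate`
#'   (character vector naming any zero-denominator metrics).
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  n <- TP + FP + TN + FN
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  sen <- safe(TP, TP + FN, "Sen")
  spe <- safe(TN, TN + FP, "Spe")
  acc <- safe(TP + TN, n, "Acc")
  mcc_den <- sqrt(as.numeric(TP + FP) * (TN + FN) * (TP + FN) * (TN + FP))
  mcc <- if (mcc_den == 0) {
    degenerate <- c(degenerate, "MCC")
    0
  } else {
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  }
  list(Sen = sen, Spe = spe, Acc = acc, MCC = mcc, degenerate = degenerate)
}

#' Area under the ROC curve
#'
#' Computed by the midrank (Mann-Whitney) identity: the probability that a
#' random positive outranks a random negative, with ties counting one half.
#'
#' @param labels true labels (both classes must be present).
#' @param probabilities predicted scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, probabilities) {
  y <- as_binary_label(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(probabilities)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise area: thresholds are placed at each distinct score, and
#' AP = sum over thresholds of (recall increment) x precision.
#'
#' @param labels true labels (both classes must be present).
#' @param probabilities predicted scores.
#' @return AP in `(0, 1]`.
#' @export
pr_ap <- function(labels, probabilities) {
  y <- as_binary_label(labels)
  n1 <- sum(y == 1L)
  if (n1 == 0 || sum(y == 0L) == 0) {
    stop("both classes must be present to compute AP")
  }
  ord <- order(probabilities, decreasing = TRUE)
  ys <- y[ord]
  ps <- probabilities[ord]
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  # collapse tied scores: evaluate at the last index of each distinct score
  last <- which(ps != c(ps[-1], NA) | seq_along(ps) == length(ps))
  tp <- tp[last]
  fp <- fp[last]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Full metric report for a set of predictions
#'
#' @param labels true labels.
#' @param probabilities predicted probabilities.
#' @param threshold classification threshold for the count-based metrics.
#' @return list with Sen, Spe, Acc, MCC, AUC, AP and `degenerate`.
#' @export
evaluate_predictions <- function(labels, probabilities, threshold = 0.5) {
  m <- classification_metrics(confusion(labels, probabilities, threshold))
  m$AUC <- roc_auc(labels, probabilities)
  m$AP <- pr_ap(labels, probabilities)
  m
}

#' Cross-condition transfer matrix
#'
#' Applies each condition-specific trained model to the independent test
#' set of every condition and records the AUC. Entry (i, j) is the AUC of
#' the model trained on condition i evaluated on the test set of condition
#' j (rows = predictors, columns = datasets). Incompatible input lengths
#' yield `NA` with a warning rather than an error.
#'
#' @param models named list of trained `m6a_cnn` models.
#' @param testsets named list of sample data.frames with labels.
#' @return numeric matrix of AUCs with model names as rows and dataset
#'   names as columns.
#' @export
cross_condition_matrix <- function(models, testsets) {
  stopifnot(length(models) >= 1, length(testsets) >= 1)
  out <- matrix(NA_real_, length(models), length(testsets),
    dimnames = list(names(models), names(testsets)))
  enc <- lapply(testsets, enac_encode_set)
  for (i in seq_along(models)) {
    for (j in seq_along(testsets)) {
      X <- enc[[j]]
      if (dim(X)[2] != models[[i]]$input_shape[1]) {
        warning(sprintf(
          "model '%s' and test set '%s' have incompatible input lengths",
          names(models)[i], names(testsets)[j]
        ))
        next
      }
      p <- predict(models[[i]], X)
      out[i, j] <- roc_auc(testsets[[j]]$label, p)
    }
  }
  out
}

#' Stratified k-fold cross-validation over a configuration grid
#'
#' For each candidate configuration, trains on k-1 folds and evaluates on
#' the held-out fold (Sen/Spe/Acc/MCC/AUC/AP); selects the configuration
#' with the highest mean validation AUC and retrains it on all samples.
#'
#' @param samples sample data.frame with labels.
#' @param configs a [model_config()] or list of them.
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return list with `best_config`, `model` (retrained on all data) and
#'   `metrics` (one row per config x fold).
#' @export
cross_validate <- function(samples, configs = model_preset("small"), k = 5,
                           seed = 1) {
  validate_samples(samples)
  if (inherits(configs, "model_config")) configs <- list(configs)
  if (!length(configs)) stop("empty configuration grid")
  if (k < 2) stop("k must be >= 2")
  y <- as_binary_label(samples$label)
  X <- enac_encode_set(samples)
  folds <- stratified_folds(y, k, seed)
  rows <- list()
  mean_auc <- numeric(length(configs))
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    aucs <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      model <- build_model(cfg, c(dim(X)[2], 4L))
      model <- train_model(model, X[tr, , , drop = FALSE], y[tr])
      p <- predict(model, X[!tr, , , drop = FALSE])
      m <- evaluate_predictions(y[!tr], p)
      aucs[f] <- m$AUC
      rows[[length(rows) + 1L]] <- data.frame(
        config = ci, fold = f, Sen = m$Sen, Spe = m$Spe, Acc = m$Acc,
        MCC = m$MCC, AUC = m$AUC, AP = m$AP
      )
    }
    mean_auc[ci] <- mean(aucs)
  }
  best <- which.max(mean_auc)
  final <- build_model(configs[[best]], c(dim(X)[2], 4L))
  final <- train_model(final, X, y)
  list(
    best_config = configs[[best]], model = final,
    metrics = do.call(rbind, rows), mean_auc = mean_auc
  )
}
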