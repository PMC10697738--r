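#' Post-ReLU activations of the first convolutional layer
#'
#' Motif extraction analyses the first convolutional layer: each filter
#' scans the encoded sequence and its rectified activation at every
#' placement is recorded. Positions index encoded rows (valid convolution,
#' so a sequence of `T` encoded rows yields `T - kernel_rows + 1`
#' placements).
#'
#' @param model a trained `m6a_cnn` with at least one convolution block.
#' @param X encoded array from [enac_encode_set()], or a sample data.frame.
#' @return object of class `filter_activations`: list with `act`
#'   (`(n * T) x F` matrix, placement fastest within sample), `n`, `T`,
#'   `F`, `k` (kernel rows).
#' @export
first_layer_activations <- function(model, X) {
  if (!length(model$arch$blocks)) {
    stop("model has no convolutional layer")
  }
  if (is.data.frame(X)) X <- enac_encode_set(X)
  if (is.matrix(X)) X <- array(X, c(1L, dim(X)))
  blk <- model$arch$blocks[[1]]
  N <- dim(X)[1]
  T0 <- dim(X)[2]
  if (T0 != model$input_shape[1]) stop("input shape mismatch")
  A <- matrix(aperm(X, c(2, 1, 3)), ncol = 4)
  M <- matrix(0, N * blk$T_conv, blk$k * 4L)
  base <- im2col_rows(N, T0, blk$T_conv)
  for (j in seq_len(blk$k)) {
    M[, ((j - 1L) * 4L + 1L):(j * 4L)] <- A[base + (j - 1L), , drop = FALSE]
  }
  Z <- M %*% model$params[["conv1.W"]] +
    matrix(model$params[["conv1.b"]], N * blk$T_conv, blk$F, byrow = TRUE)
  Z[Z < 0] <- 0
  structure(
    list(act = Z, n = N, T = blk$T_conv, F = blk$F, k = blk$k),
    class = "filter_activations"
  )
}

#' Subsequences that activate each filter above threshold
#'
#' For every filter, the threshold is `threshold_fraction` times that
#' filter's maximum activation over the entire evaluated set; placements
#' with activation strictly above the threshold contribute the nucleotide
#' subsequence they cover. A first-layer filter spanning `k` encoded rows
#' covers `k + window - 1` nucleotides (with the default ENAC window of 2,
#' a 5-row kernel yields 6-nt subsequences). Filters that are never
#' activated yield empty lists.
#'
#' @param acts a [first_layer_activations()] object.
#' @param samples the sample data.frame the activations were computed on
#'   (sequences are needed to look up the covered nucleotides).
#' @param threshold_fraction fraction of the per-filter maximum (default
#'   0.5, i.e. half of the filter's maximum value).
#' @param window ENAC sub-window length used at encoding time (default 2).
#' @return list (one element per filter) of character vectors of activated
#'   subsequences; attribute `thresholds` holds the per-filter cutoffs.
#' @export
extract_activated_subsequences <- function(acts, samples,
                                           threshold_fraction = 0.5,
                                           window = 2) {
  stopifnot(inherits(acts, "filter_activations"))
  validate_samples(samples, require_label = FALSE)
  stopifnot(nrow(samples) == acts$n)
  sublen <- acts$k + window - 1L
  thr <- threshold_fraction * apply(acts$act, 2, max)
  out <- vector("list", acts$F)
  for (f in seq_len(acts$F)) {
    rows <- which(acts$act[, f] > thr[f])
    if (!length(rows)) {
      out[[f]] <- character(0)
      next
    }
    n_idx <- (rows - 1L) %/% acts$T + 1L
    t_idx <- (rows - 1L) %% acts$T + 1L
    out[[f]] <- substring(samples$sequence[n_idx], t_idx, t_idx + sublen - 1L)
  }
  attr(out, "thresholds") <- thr
  out
}

#' Build a position frequency matrix from activated subsequences
#'
#' Column-wise nucleotide frequencies over the aligned subsequences. An
#' empty subsequence set produces a uniform (0.25) matrix with support 0
#' and a warning.
#'
#' @param subsequences character vector of equal-length subsequences.
#' @param filter_index index of the originating filter (bookkeeping).
#' @param motif_length required only when `subsequences` is empty.
#' @param name optional motif name.
#' @return object of class `MotifPFM`: list with `freq`
#'   (`motif_length x 4`, rows summing to 1), `support`, `filter_index`,
#'   `name`.
#' @export
build_pfm <- function(subsequences, filter_index = NA_integer_,
                      motif_length = NULL, name = NULL) {
  if (!length(subsequences)) {
    if (is.null(motif_length)) {
      stop("motif_length must be given for an empty subsequence set")
    }
    warning("no activated subsequences; returning a uniform PFM with support 0")
    freq <- matrix(0.25, motif_length, 4, dimnames = list(NULL, RNA_BASES))
    return(structure(
      list(freq = freq, support = 0L, filter_index = filter_index, name = name),
      class = "MotifPFM"
    ))
  }
  lens <- nchar(subsequences)
  if (length(unique(lens)) != 1) stop("subsequences must have equal length")
  L <- lens[1]
  mat <- matrix(
    match(unlist(strsplit(subsequences, "")), RNA_BASES),
    nrow = length(subsequences), ncol = L, byrow = TRUE
  )
  freq <- t(apply(mat, 2, function(col) tabulate(col, 4) / length(col)))
  colnames(freq) <- RNA_BASES
  structure(
    list(freq = freq, support = length(subsequences),
      filter_index = filter_index, name = name),
    class = "MotifPFM"
  )
}

#' Mean number of activated placements per sequence, per filter
#'
#' The "activated amount" of a filter: the number of placements across the
#' evaluated set whose activation exceeds half (by default) of that
#' filter's maximum, divided by the number of sequences.
#'
#' @param acts a [first_layer_activations()] object.
#' @param threshold_fraction fraction of the per-filter maximum.
#' @return numeric vector (one mean count per filter).
#' @export
activated_amount <- function(acts, threshold_fraction = 0.5) {
  stopifnot(inherits(acts, "filter_activations"))
  thr <- threshold_fraction * apply(acts$act, 2, max)
  counts <- vapply(
    seq_len(acts$F),
    function(f) sum(acts$act[, f] > thr[f]),
    numeric(1)
  )
  counts / acts$n
}

#' Zero out first-layer filters (virtual pruning)
#'
#' Returns a copy of the model with the weights and bias of the selected
#' first-layer filters set to zero; the input model is never modified.
#'
#' @param model a trained `m6a_cnn`.
#' @param filters integer indices of first-layer filters, or `"all"`.
#' @return the pruned model copy.
#' @export
nullify_filters <- function(model, filters) {
  if (!length(model$arch$blocks)) stop("model has no convolutional layer")
  Fb <- model$arch$blocks[[1]]$F
  if (identical(filters, "all")) filters <- seq_len(Fb)
  filters <- as.integer(filters)
  if (any(filters < 1 | filters > Fb)) {
    stop("filter index out of range 1..", Fb)
  }
  model$params[["conv1.W"]][, filters] <- 0
  model$params[["conv1.b"]][filters] <- 0
  model
}

#' Impact score of one filter via virtual pruning
#'
#' Nullifies the filter (weights and bias set to zero) and measures the
#' mean absolute change in predicted probability over the evaluated set.
#' The operation is pure: the input model is left untouched.
#'
#' @param model trained `m6a_cnn`.
#' @param X encoded array or sample data.frame.
#' @param filter_index first-layer filter to prune.
#' @param signed if `TRUE`, return the mean signed change
#'   (pruned minus original) instead of the mean absolute change.
#' @return scalar impact score.
#' @export
impact_score <- function(model, X, filter_index, signed = FALSE) {
  if (is.data.frame(X)) X <- enac_encode_set(X)
  p0 <- predict(model, X)
  p1 <- predict(nullify_filters(model, filter_index), X)
  if (signed) mean(p1 - p0) else mean(abs(p1 - p0))
}

#' AUC drop under nullification of one filter
#'
#' Secondary pruning statistic: the decrease in test AUC when the filter is
#' zeroed.
#'
#' @param model trained `m6a_cnn`.
#' @param X encoded array or sample data.frame.
#' @param labels true labels for `X`.
#' @param filter_index first-layer filter to prune.
#' @return AUC(original) - AUC(pruned).
#' @export
filter_auc_drop <- function(model, X, labels, filter_index) {
  if (is.data.frame(X)) X <- enac_encode_set(X)
  p0 <- predict(model, X)
  p1 <- predict(nullify_filters(model, filter_index), X)
  roc_auc(labels, p0) - roc_auc(labels, p1)
}

#' Per-filter motif and contribution report
#'
#' Runs the whole model-based interpretation for every first-layer filter:
#' activated subsequences at half-maximum threshold, PFM construction,
#' activated amount, virtual-pruning impact score, and (when labels are
#' available) the AUC drop.
#'
#' @param model trained `m6a_cnn`.
#' @param samples sample data.frame (typically the independent test set).
#' @param threshold_fraction activation threshold fraction (default 0.5).
#' @param window ENAC window used at encoding time.
#' @return list with `table` (data.frame: filter_index, activated_amount,
#'   impact_score, auc_drop, support) and `pfms` (list of `MotifPFM`).
#' @export
filter_report <- function(model, samples, threshold_fraction = 0.5,
                          window = 2) {
  validate_samples(samples, require_label = FALSE)
  X <- enac_encode_set(samples, window = window)
  acts <- first_layer_activations(model, X)
  subs <- extract_activated_subsequences(acts, samples, threshold_fraction,
    window)
  sublen <- acts$k + window - 1L
  pfms <- lapply(seq_len(acts$F), function(f) {
    suppressWarnings(
      build_pfm(subs[[f]], filter_index = f, motif_length = sublen)
    )
  })
  amount <- activated_amount(acts, threshold_fraction)
  p0 <- predict(model, X)
  have_labels <- "label" %in% names(samples) && !anyNA(samples$label)
  impact <- numeric(acts$F)
  aucdrop <- rep(NA_real_, acts$F)
  auc0 <- if (have_labels) roc_auc(samples$label, p0) else NA_real_
  for (f in seq_len(acts$F)) {
    p1 <- predict(nullify_filters(model, f), X)
    impact[f] <- mean(abs(p1 - p0))
    if (have_labels) aucdrop[f] <- auc0 - roc_auc(samples$label, p1)
  }
  list(
    table = data.frame(
      filter_index = seq_len(acts$F),
      activated_amount = amount,
      impact_score = impact,
      auc_drop = aucdrop,
      support = vapply(pfms, function(p) p$support, integer(1))
    ),
    pfms = pfms
  )
}

#' Pearson correlation between two PFMs
#'
#' Pearson correlation of the flattened frequency matrices; `NA` when
#' either matrix has zero variance (e.g. a uniform PFM).
#'
#' @param a,b `MotifPFM` objects (or bare frequency matrices) of equal
#'   shape.
#' @return Pearson r, or `NA`.
#' @export
motif_pcc <- function(a, b) {
  fa <- if (inherits(a, "MotifPFM")) a$freq else a
  fb <- if (inherits(b, "MotifPFM")) b$freq else b
  if (!all(dim(fa) == dim(fb))) stop("PFMs must have equal shapes")
  va <- as.vector(fa)
  vb <- as.vector(fb)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

#' Best-offset Pearson correlation between PFMs of unequal length
#'
#' Slides the shorter PFM along the longer one (full overlap) and returns
#' the maximum correlation over offsets.
#'
#' @param a,b `MotifPFM` objects or frequency matrices.
#' @return list with `pcc` (max correlation) and `offset` (0-based shift of
#'   the shorter motif within the longer one).
#' @export
motif_best_pcc <- function(a, b) {
  fa <- if (inherits(a, "MotifPFM")) a$freq else a
  fb <- if (inherits(b, "MotifPFM")) b$freq else b
  if (nrow(fa) < nrow(fb)) {
    res <- motif_best_pcc(fb, fa)
    return(res)
  }
  short <- fb
  long <- fa
  n_off <- nrow(long) - nrow(short) + 1L
  best <- -Inf
  best_off <- NA_integer_
  for (o in seq_len(n_off)) {
    r <- motif_pcc(long[o:(o + nrow(short) - 1L), , drop = FALSE], short)
    if (!is.na(r) && r > best) {
      best <- r
      best_off <- o - 1L
    }
  }
  list(pcc = if (is.finite(best)) best else NA_real_, offset = best_off)
}

#' Hierarchically cluster filter motifs
#'
#' Agglomerative (average-linkage) clustering of PFMs under the distance
#' 1 - PCC. Zero-variance (uniform) PFMs have no defined correlation and
#' are excluded with a warning.
#'
#' @param pfms list of `MotifPFM` objects with equal shapes.
#' @param k optional number of clusters for a hard labelling.
#' @return list with `hclust` (the dendrogram), `pcc` (pairwise matrix),
#'   `labels` (cluster ids if `k` given) and `kept` (indices clustered).
#' @export
cluster_motifs <- function(pfms, k = NULL) {
  if (length(pfms) < 2) stop("need at least 2 PFMs to cluster")
  n <- length(pfms)
  pcc <- matrix(NA_real_, n, n)
  diag(pcc) <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pcc[i, j] <- pcc[j, i] <- motif_pcc(pfms[[i]], pfms[[j]])
    }
  }
  degen <- which(vapply(
    pfms, function(p) stats::sd(as.vector(p$freq)) == 0, logical(1)
  ))
  kept <- setdiff(seq_len(n), degen)
  if (length(degen)) {
    warning(length(degen), " uniform PFM(s) excluded from clustering")
  }
  if (length(kept) < 2) stop("fewer than 2 non-degenerate PFMs")
  d <- stats::as.dist(1 - pcc[kept, kept])
  hc <- stats::hclust(d, method = "average")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, pcc = pcc, labels = labels, kept = kept)
}
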