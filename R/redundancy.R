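#' Pairwise identity of two equal-length sequences
#'
#' Ungapped positionwise match fraction. For equal-length, A-centered
#' windows this is a deterministic stand-in for alignment-based identity.
#'
#' @param a,b sequences of equal length.
#' @return fraction of matching positions in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

#' Remove redundant windows by greedy identity clustering
#'
#' Greedy first-come clustering in input order: a sample is discarded iff
#' its identity (match fraction) to any already-retained sample is at least
#' `identity_threshold`. The retained samples keep their input order.
#'
#' @param samples sample data.frame (`id`, `sequence`, `label`), all
#'   sequences the same length.
#' @param identity_threshold identity at or above which a later sample is
#'   considered redundant (default 0.8).
#' @return the retained subset of `samples`.
#' @export
reduce_redundancy <- function(samples, identity_threshold = 0.8) {
  validate_samples(samples, require_label = FALSE)
  n <- nrow(samples)
  if (n <= 1) return(samples)
  lens <- nchar(samples$sequence)
  if (length(unique(lens)) != 1) {
    stop("all samples must have the same length for identity clustering")
  }
  L <- lens[1]
  # integer-code the characters once; rowMeans over logical comparisons is
  # the inner loop, so avoid repeated strsplit.
  mat <- matrix(
    match(unlist(strsplit(samples$sequence, "")), RNA_BASES),
    nrow = n, ncol = L, byrow = TRUE
  )
  kept <- 1L
  for (i in 2:n) {
    km <- mat[kept, , drop = FALSE]
    ident <- rowMeans(km == matrix(mat[i, ], nrow(km), L, byrow = TRUE))
    if (all(ident < identity_threshold)) kept <- c(kept, i)
  }
  out <- samples[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Randomly divides samples into training and independent test sets at the
#' given ratio, stratified by label so class balance is preserved. Per
#' stratum, `round(train_fraction * n)` samples go to training. A class
#' with fewer than 2 samples is kept whole in the training set with a
#' warning.
#'
#' @param samples sample data.frame with a `label` column.
#' @param train_fraction fraction assigned to training (default 0.9).
#' @param seed RNG seed; the same seed always yields the same partition.
#' @return list with `train` and `test` data.frames (disjoint, exhaustive).
#' @export
split_train_test <- function(samples, train_fraction = 0.9, seed = 1) {
  validate_samples(samples)
  if (nrow(samples) < 10) stop("need at least 10 samples to split")
  train_idx <- integer(0)
  with_rng_seed(seed, {
    for (cls in unique(samples$label)) {
      idx <- which(samples$label == cls)
      if (length(idx) < 2) {
        warning(sprintf(
          "class '%s' has < 2 samples; keeping it whole in train", cls
        ))
        train_idx <- c(train_idx, idx)
        next
      }
      n_tr <- round(train_fraction * length(idx))
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  })
  train_idx <- sort(train_idx)
  out <- list(
    train = samples[train_idx, , drop = FALSE],
    test = samples[setdiff(seq_len(nrow(samples)), train_idx), , drop = FALSE]
  )
  rownames(out$train) <- rownames(out$test) <- NULL
  out
}
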