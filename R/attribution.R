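#' In-silico mutagenesis attribution map
#'
#' Forward-propagation attribution: every position of the input sequence is
#' substituted by each of the three alternative nucleotides in turn, the
#' mutant is re-encoded (the ENAC rows touching the position change) and
#' re-scored, and the attribution is the prediction difference
#' (mutant minus original). The entry at the observed nucleotide of each
#' position is 0 by construction.
#'
#' @param model trained `m6a_cnn`.
#' @param sample a one-row sample data.frame or a sequence string.
#' @param output score the `"probability"` (default) or the pre-sigmoid
#'   `"logit"`.
#' @param window ENAC window used at encoding time.
#' @return a `4 x l` matrix (rows A, C, G, U) with attributes `method`
#'   (`"ism"`) and `sample_id`.
#' @export
ism_attribution <- function(model, sample, output = c("probability", "logit"),
                            window = 2) {
  output <- match.arg(output)
  id <- NULL
  if (is.data.frame(sample)) {
    id <- sample$id[1]
    sample <- sample$sequence[1]
  }
  s <- normalize_rna(sample)
  l <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  type <- if (output == "probability") "prob" else "logit"
  p0 <- predict(model, enac_encode_set(s, window = window), type = type)

  muts <- character(0)
  where <- integer(0)
  what <- character(0)
  for (i in seq_len(l)) {
    for (b in setdiff(RNA_BASES, chars[i])) {
      m <- chars
      m[i] <- b
      muts <- c(muts, paste0(m, collapse = ""))
      where <- c(where, i)
      what <- c(what, b)
    }
  }
  pm <- predict(model, enac_encode_set(muts, window = window), type = type)
  map <- matrix(0, 4, l, dimnames = list(RNA_BASES, NULL))
  map[cbind(match(what, RNA_BASES), where)] <- pm - p0
  attr(map, "method") <- "ism"
  attr(map, "sample_id") <- id
  map
}

#' Gradient (backward-propagation) attribution map
#'
#' Computes the derivative of the model output with respect to the encoded
#' `(L-1) x 4` input and re-projects it onto nucleotide space: the score of
#' nucleotide channel c at sequence position p is the sum of the gradients
#' of all encoded rows covering p (via the sliding-window coverage map),
#' scaled by 1/window.
#'
#' @param model trained `m6a_cnn`.
#' @param sample one-row sample data.frame or sequence string.
#' @param wrt differentiate the sigmoid `"probability"` (default) or the
#'   `"logit"`.
#' @param window ENAC window used at encoding time.
#' @return a `4 x l` matrix (rows A, C, G, U) with attributes `method`
#'   (`"gradient"`) and `sample_id`.
#' @export
gradient_attribution <- function(model, sample,
                                 wrt = c("probability", "logit"),
                                 window = 2) {
  wrt <- match.arg(wrt)
  id <- NULL
  if (is.data.frame(sample)) {
    id <- sample$id[1]
    sample <- sample$sequence[1]
  }
  X <- enac_encode_set(normalize_rna(sample), window = window)
  fw <- cnn_forward(model, X, training = FALSE, keep_cache = TRUE)
  dlogit <- if (wrt == "probability") fw$prob * (1 - fw$prob) else 1
  bw <- cnn_backward(model, fw$cache, dlogit, input_grad = TRUE)
  dE <- bw$dX[1, , ] # (L - window + 1) x 4
  T0 <- nrow(dE)
  l <- T0 + window - 1L
  map <- matrix(0, 4, l, dimnames = list(RNA_BASES, NULL))
  for (p in seq_len(l)) {
    rows <- max(1L, p - window + 1L):min(T0, p)
    map[, p] <- colSums(dE[rows, , drop = FALSE]) / window
  }
  attr(map, "method") <- "gradient"
  attr(map, "sample_id") <- id
  map
}

#' Global position profile of attribution maps
#'
#' Averages attribution maps elementwise across samples and reduces the
#' mean `4 x l` matrix to a length-`l` vector by summing absolute values
#' over the four channels, giving a global picture of which positions the
#' model attends to.
#'
#' @param maps list of `4 x l` attribution maps of identical shape.
#' @return numeric vector of length `l`.
#' @export
global_position_profile <- function(maps) {
  if (!length(maps)) stop("empty list of attribution maps")
  dims <- unique(lapply(maps, dim))
  if (length(dims) != 1) stop("attribution maps differ in shape")
  mean_map <- Reduce(`+`, maps) / length(maps)
  colSums(abs(mean_map))
}

#' Position profile of filter activations
#'
#' Model-based counterpart of [global_position_profile()]: for each
#' sequence position, the mean number (per sequence) of above-threshold
#' filter placements whose covered subsequence includes that position,
#' accumulated over all filters.
#'
#' @param acts a [first_layer_activations()] object.
#' @param seq_length nucleotide length `l` of the underlying sequences.
#' @param threshold_fraction activation threshold fraction (default 0.5).
#' @param window ENAC window used at encoding time.
#' @return numeric vector of length `seq_length`.
#' @export
activation_position_profile <- function(acts, seq_length,
                                        threshold_fraction = 0.5,
                                        window = 2) {
  stopifnot(inherits(acts, "filter_activations"))
  sublen <- acts$k + window - 1L
  thr <- threshold_fraction * apply(acts$act, 2, max)
  prof <- numeric(seq_length)
  for (f in seq_len(acts$F)) {
    rows <- which(acts$act[, f] > thr[f])
    if (!length(rows)) next
    t_idx <- (rows - 1L) %% acts$T + 1L
    for (t in t_idx) {
      span <- t:min(t + sublen - 1L, seq_length)
      prof[span] <- prof[span] + 1
    }
  }
  prof / acts$n
}

#' Cosine similarity between attribution vectors
#'
#' @param a,b numeric vectors (or matrices, which are flattened) of equal
#'   length.
#' @return cosine similarity in `[-1, 1]`; `NA` if either vector is all
#'   zero.
#' @export
attribution_similarity <- function(a, b) {
  va <- as.vector(a)
  vb <- as.vector(b)
  if (length(va) != length(vb)) stop("vectors must have equal length")
  na <- sqrt(sum(va^2))
  nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(va * vb) / (na * nb)
}
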