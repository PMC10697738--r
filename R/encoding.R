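#' ENAC encoding of a nucleotide window
#'
#' Enhanced nucleic acid composition: a window of length `window` slides
#' along the sequence with step `stride`; each placement yields the
#' nucleotide frequencies (count / window) over the fixed channel order
#' A, C, G, U. With the defaults (`window = 2`, `stride = 1`) a sequence of
#' length L becomes an (L-1) x 4 matrix whose rows each sum to 1 and whose
#' entries lie in {0, 0.5, 1}.
#'
#' @param sequence RNA string over A/C/G/U (a one-row sample data.frame is
#'   also accepted).
#' @param window sub-window length (default 2).
#' @param stride step between consecutive sub-windows (default 1).
#' @return numeric matrix with `floor((L - window) / stride) + 1` rows and
#'   columns named A, C, G, U; attribute `sample_id` if the input carried an
#'   id.
#' @examples
#' enac_encode("ACGU")
#' @export
enac_encode <- function(sequence, window = 2, stride = 1) {
  id <- NULL
  if (is.data.frame(sequence)) {
    id <- sequence$id[1]
    sequence <- sequence$sequence[1]
  }
  if (window < 1 || stride < 1) stop("window and stride must be >= 1")
  s <- normalize_rna(sequence)
  check_rna_alphabet(s, "sequence")
  L <- nchar(s)
  if (L < window) stop("sequence shorter than the encoding window")
  code <- match(strsplit(s, "")[[1]], RNA_BASES)
  n_rows <- (L - window) %/% stride + 1L
  starts <- (seq_len(n_rows) - 1L) * stride
  # one-hot cumulative counts give O(L) windowed frequencies
  onehot <- matrix(0L, L, 4)
  onehot[cbind(seq_len(L), code)] <- 1L
  cum <- rbind(0L, apply(onehot, 2, cumsum))
  freq <- (cum[starts + window + 1L, , drop = FALSE] -
    cum[starts + 1L, , drop = FALSE]) / window
  colnames(freq) <- RNA_BASES
  if (!is.null(id)) attr(freq, "sample_id") <- id
  freq
}

#' ENAC-encode a whole sample set into a 3-D array
#'
#' @param samples sample data.frame, or character vector of sequences.
#' @param window,stride as in [enac_encode()].
#' @return array of dim `c(n_samples, n_rows, 4)` with dimnames on the
#'   channel axis.
#' @export
enac_encode_set <- function(samples, window = 2, stride = 1) {
  seqs <- if (is.data.frame(samples)) samples$sequence else samples
  if (!length(seqs)) stop("no sequences to encode")
  mats <- lapply(seqs, enac_encode, window = window, stride = stride)
  nr <- unique(vapply(mats, nrow, integer(1)))
  if (length(nr) != 1) stop("sequences of mixed lengths cannot be stacked")
  X <- array(0, dim = c(length(mats), nr, 4),
    dimnames = list(NULL, NULL, RNA_BASES))
  for (i in seq_along(mats)) X[i, , ] <- mats[[i]]
  X
}

#' Nucleotide positions covered by one encoded row
#'
#' Maps a row of the ENAC matrix back to the nucleotide positions it
#' summarises (needed when projecting encoded-space gradients back onto the
#' sequence).
#'
#' @param row_index 0-based row index into the encoded matrix.
#' @param window encoding sub-window length.
#' @return integer vector of 0-based nucleotide positions
#'   `row_index, ..., row_index + window - 1`.
#' @export
enac_decode_positions <- function(row_index, window = 2) {
  if (row_index < 0) stop("row_index must be >= 0")
  seq.int(row_index, row_index + window - 1L)
}

#' Reconstruct an A-centered sequence from its ENAC matrix
#'
#' With `window = 2`, `stride = 1` the encoding is injective on A-centered
#' windows: starting from the known central base, each adjacent row pins
#' down the neighbouring nucleotide. Used as the reconstruct-and-compare
#' check of encoding injectivity.
#'
#' @param mat ENAC matrix as returned by [enac_encode()] (window 2, stride 1).
#' @param anchor_pos 0-based position of a known base (default: the center).
#' @param anchor_base the known base at `anchor_pos` (default `"A"`).
#' @return the reconstructed sequence string.
#' @export
enac_reconstruct <- function(mat, anchor_pos = nrow(mat) %/% 2,
                             anchor_base = "A") {
  L <- nrow(mat) + 1L
  out <- character(L)
  out[anchor_pos + 1L] <- anchor_base
  other_base <- function(row, known) {
    cnt <- round(row * 2)
    cnt[match(known, RNA_BASES)] <- cnt[match(known, RNA_BASES)] - 1L
    RNA_BASES[which(cnt == 1L)]
  }
  if (anchor_pos + 2L <= L) {
    for (p in seq.int(anchor_pos + 2L, L)) {
      out[p] <- other_base(mat[p - 1L, ], out[p - 1L])
    }
  }
  if (anchor_pos >= 1L) {
    for (p in seq.int(anchor_pos, 1L)) {
      out[p] <- other_base(mat[p, ], out[p + 1L])
    }
  }
  paste0(out, collapse = "")
}
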