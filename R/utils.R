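#' @keywords internal
"_PACKAGE"

# Alphabet used throughout: RNA, fixed channel order A, C, G, U.
RNA_BASES <- c("A", "C", "G", "U")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library functions never perturb user-level randomness.
with_rng_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Normalise a nucleotide string: uppercase, DNA T read as RNA U.
normalize_rna <- function(x) {
  chartr("acgtuT", "ACGUUU", toupper(x))
}

check_rna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop(sprintf(
      "%s contains characters outside {A,C,G,U} (first offender: '%s')",
      what, x[which(bad)[1]]
    ), call. = FALSE)
  }
  invisible(x)
}

#' Convert labels to binary 0/1
#'
#' Accepts `"positive"`/`"negative"`, `"pos"`/`"neg"`, logicals, or 0/1
#' numerics and returns an integer vector with 1 = positive.
#'
#' @param labels vector of class labels.
#' @return integer vector of 0s and 1s.
#' @export
as_binary_label <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0 or 1")
    return(as.integer(labels))
  }
  if (is.logical(labels)) return(as.integer(labels))
  x <- tolower(as.character(labels))
  out <- ifelse(x %in% c("positive", "pos", "1", "true"), 1L,
    ifelse(x %in% c("negative", "neg", "0", "false"), 0L, NA_integer_)
  )
  if (anyNA(out)) {
    stop("unrecognised label(s): ", paste(unique(labels[is.na(out)]), collapse = ", "))
  }
  out
}

# Validate a sample table (id, sequence, label) as produced by the dataset
# and synthetic modules.
validate_samples <- function(samples, require_label = TRUE) {
  stopifnot(is.data.frame(samples))
  need <- c("id", "sequence", if (require_label) "label")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(samples)
}

# Stratified fold assignment used by the splitter and cross-validation.
stratified_folds <- function(y, k, seed) {
  y <- as_binary_label(y)
  fold <- integer(length(y))
  with_rng_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < k) {
        stop("fewer samples than folds in one class (", length(idx), " < ", k, ")")
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}
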