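#' Read sequence windows (or transcripts) from FASTA
#'
#' Sequences are normalised to the RNA alphabet (`T` read as `U`,
#' uppercased). Class labels may be carried in the header as a `|pos` /
#' `|neg` suffix on the record id; headers without a suffix yield `NA`
#' labels (appropriate for transcript FASTA).
#'
#' @param path FASTA file.
#' @return data.frame with `id`, `sequence`, `label`.
#' @export
read_sample_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids_raw <- sub("\\s.*$", "", names(ss))
  seqs <- normalize_rna(as.character(ss))
  empty <- nchar(seqs) == 0
  if (any(empty)) {
    warning(sum(empty), " empty FASTA record(s) skipped")
    ids_raw <- ids_raw[!empty]
    seqs <- seqs[!empty]
  }
  label <- rep(NA_character_, length(ids_raw))
  has_suffix <- grepl("\\|(pos|neg)$", ids_raw)
  label[has_suffix] <- ifelse(
    sub("^.*\\|", "", ids_raw[has_suffix]) == "pos", "positive", "negative"
  )
  id <- sub("\\|(pos|neg)$", "", ids_raw)
  if (anyDuplicated(id)) warning("duplicate sequence ids in ", path)
  check_rna_alphabet(seqs, "FASTA sequence")
  data.frame(id = id, sequence = seqs, label = label, stringsAsFactors = FALSE)
}

#' Write sequence windows to FASTA
#'
#' Labels are encoded as a `|pos` / `|neg` header suffix so that a
#' write/read round trip preserves id, sequence and label.
#'
#' @param samples sample data.frame (`id`, `sequence`, `label`).
#' @param path output FASTA path.
#' @export
write_sample_fasta <- function(samples, path) {
  validate_samples(samples, require_label = FALSE)
  hdr <- samples$id
  if ("label" %in% names(samples) && !all(is.na(samples$label))) {
    suffix <- ifelse(as_binary_label(samples$label) == 1L, "|pos", "|neg")
    hdr <- paste0(hdr, suffix)
  }
  ss <- Biostrings::BStringSet(samples$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read transcripts from FASTA as a named character vector
#'
#' @param path FASTA file of transcript (mature mRNA) sequences.
#' @return named character vector, RNA alphabet.
#' @export
read_transcripts <- function(path) {
  df <- read_sample_fasta(path)
  stats::setNames(df$sequence, df$id)
}
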