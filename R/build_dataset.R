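#' Build a balanced benchmark dataset from transcripts and positive sites
#'
#' End-to-end dataset construction: extract A-centered, DRACH-filtered
#' windows around the positive sites; sample an equal number of negatives
#' at least `min_distance` nt away from every positive on the same
#' transcript; pool, remove redundant windows at the identity threshold;
#' and split 9:1 (stratified by label) into training and independent test
#' sets.
#'
#' @param transcripts named character vector of transcript sequences, or a
#'   FASTA path.
#' @param sites data.frame of sites (only rows labelled positive are used),
#'   or a TSV path in the [read_sites()] dialect.
#' @param flank flank length per side (default 100: 201-nt windows).
#' @param min_distance negative-to-positive distance constraint (default 200).
#' @param identity_threshold redundancy-removal identity cutoff (default 0.8).
#' @param train_fraction training fraction of the final split (default 0.9).
#' @param seed RNG seed driving negative sampling and the split.
#' @return list with `train`, `test` (sample data.frames), `rejections`
#'   (window rejection log) and `negatives` (the sampled negative sites).
#' @export
build_dataset <- function(transcripts, sites, flank = 100, min_distance = 200,
                          identity_threshold = 0.8, train_fraction = 0.9,
                          seed = 1) {
  if (is.character(transcripts) && length(transcripts) == 1 &&
    file.exists(transcripts)) {
    transcripts <- read_transcripts(transcripts)
  }
  if (is.character(sites)) sites <- read_sites(sites)
  transcripts <- vapply(transcripts, normalize_rna, character(1))

  pos_sites <- sites[as_binary_label(sites$label) == 1L, , drop = FALSE]
  pos <- extract_windows(transcripts, pos_sites, flank)
  n_pos <- nrow(pos$samples)
  if (n_pos == 0) stop("no positive window survived extraction")

  neg_sites <- sample_negatives(
    transcripts, pos_sites,
    min_distance = min_distance,
    n_target = n_pos, seed = seed, flank = flank
  )
  neg <- extract_windows(transcripts, neg_sites, flank)

  pooled <- rbind(pos$samples, neg$samples)
  pooled <- reduce_redundancy(pooled, identity_threshold)
  split <- split_train_test(pooled, train_fraction, seed = seed)

  list(
    train = split$train,
    test = split$test,
    rejections = rbind(pos$rejections, neg$rejections),
    negatives = neg_sites
  )
}
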