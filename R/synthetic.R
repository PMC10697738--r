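#' One-hot (or matrix) motif PFM
#'
#' @param x a consensus string (one-hot PFM) or a `length x 4` frequency
#'   matrix with columns A, C, G, U.
#' @param name motif name (defaults to the consensus string when given one).
#' @return a `MotifPFM`.
#' @export
motif_pfm <- function(x, name = NULL) {
  if (is.character(x)) {
    s <- normalize_rna(x)
    check_rna_alphabet(s, "motif")
    code <- match(strsplit(s, "")[[1]], RNA_BASES)
    freq <- matrix(0, length(code), 4, dimnames = list(NULL, RNA_BASES))
    freq[cbind(seq_along(code), code)] <- 1
    if (is.null(name)) name <- s
  } else {
    freq <- as.matrix(x)
    stopifnot(ncol(freq) == 4)
    if (any(abs(rowSums(freq) - 1) > 1e-8)) stop("PFM rows must sum to 1")
    colnames(freq) <- RNA_BASES
  }
  structure(
    list(freq = freq, support = NA_integer_, filter_index = NA_integer_,
      name = name),
    class = "MotifPFM"
  )
}

#' Specify a planted motif for simulation
#'
#' @param motif consensus string or `MotifPFM`.
#' @param offset where the motif is inserted relative to the window:
#'   `"5p"` (uniform over the 5' flank, never overlapping the central
#'   DRACH 5-mer; the default), `"3p"` (uniform over the 3' flank), a
#'   single 1-based start position, or a length-2 vector giving a uniform
#'   range of 1-based start positions.
#' @param insertion_rate probability that a positive sample receives the
#'   motif.
#' @return a `planted_motif` spec.
#' @export
planted_motif <- function(motif, offset = "5p", insertion_rate = 0.9) {
  pfm <- if (inherits(motif, "MotifPFM")) motif else motif_pfm(motif)
  stopifnot(insertion_rate >= 0, insertion_rate <= 1)
  structure(
    list(pfm = pfm, offset = offset, insertion_rate = insertion_rate),
    class = "planted_motif"
  )
}

#' Simulation specification for planted-motif benchmark sets
#'
#' Describes a balanced set of A-centered DRACH-context windows in which
#' the two classes share the same central 5-mer distribution (uniform over
#' the 18 DRACH 5-mers) and differ only by motifs planted in the flanks of
#' the positive class. Any signal a model learns is therefore attributable
#' to the planted flanking motifs, which is what makes motif-recovery tests
#' meaningful.
#'
#' @param n_pos,n_neg class sizes.
#' @param length odd window length (>= 11).
#' @param background_probs background nucleotide probabilities (A, C, G, U),
#'   summing to 1.
#' @param planted_motifs list of [planted_motif()] specs (positives only).
#' @param seed RNG seed.
#' @return a `sim_spec`.
#' @export
sim_spec <- function(n_pos, n_neg, length = 201,
                     background_probs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                     planted_motifs = list(), seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1, length >= 11, length %% 2 == 1)
  if (abs(sum(background_probs) - 1) > 1e-8) {
    stop("background_probs must sum to 1")
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
      length = as.integer(length), background_probs = background_probs,
      planted_motifs = planted_motifs, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# Resolve the valid 1-based start range for a planted motif so that it
# never overlaps the central DRACH 5-mer [center-2, center+2].
motif_start_range <- function(offset, motif_len, L) {
  center <- (L + 1L) %/% 2L
  rng <- if (identical(offset, "5p")) {
    c(1L, center - 2L - motif_len)
  } else if (identical(offset, "3p")) {
    c(center + 3L, L - motif_len + 1L)
  } else if (is.numeric(offset) && length(offset) == 1) {
    c(as.integer(offset), as.integer(offset))
  } else if (is.numeric(offset) && length(offset) == 2) {
    as.integer(offset)
  } else {
    stop("unrecognised offset specification")
  }
  if (rng[1] < 1L || rng[2] < rng[1] || rng[2] > L - motif_len + 1L) {
    stop("motif does not fit in the available flank")
  }
  ends <- c(rng[1] + motif_len - 1L, rng[2] + motif_len - 1L)
  if (max(rng[2], ends[2]) >= center - 2L && min(rng[1]) <= center + 2L) {
    # any placement in the range overlapping the central 5-mer is invalid
    if (!(ends[2] < center - 2L || rng[1] > center + 2L)) {
      stop("offset range overlaps the central DRACH 5-mer")
    }
  }
  rng
}

#' Generate a balanced planted-motif dataset
#'
#' Both classes are background sequence with a uniformly drawn DRACH 5-mer
#' at the center; positives additionally receive each planted motif with
#' its insertion rate at a start position drawn from its offset
#' distribution. Fully seeded and reproducible.
#'
#' @param spec a [sim_spec()].
#' @return list with `samples` (data.frame id/sequence/label), `truth`
#'   (data.frame id/motif/start/end, one row per actual insertion, 1-based
#'   coordinates) and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  L <- spec$length
  center <- (L + 1L) %/% 2L
  kmers <- drach_kmers()
  ranges <- lapply(spec$planted_motifs, function(pm) {
    motif_start_range(pm$offset, nrow(pm$pfm$freq), L)
  })
  n <- spec$n_pos + spec$n_neg
  labels <- rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg))
  ids <- sprintf("%s_%04d", ifelse(labels == "positive", "pos", "neg"),
    c(seq_len(spec$n_pos), seq_len(spec$n_neg)))
  seqs <- character(n)
  truth <- list()
  with_rng_seed(spec$seed, {
    for (i in seq_len(n)) {
      chars <- sample(RNA_BASES, L, replace = TRUE,
        prob = spec$background_probs)
      chars[(center - 2L):(center + 2L)] <-
        strsplit(sample(kmers, 1), "")[[1]]
      if (labels[i] == "positive") {
        for (mi in seq_along(spec$planted_motifs)) {
          pm <- spec$planted_motifs[[mi]]
          if (stats::runif(1) > pm$insertion_rate) next
          rng <- ranges[[mi]]
          start <- if (rng[1] == rng[2]) rng[1] else
            sample(rng[1]:rng[2], 1)
          mlen <- nrow(pm$pfm$freq)
          inst <- vapply(seq_len(mlen), function(r) {
            sample(RNA_BASES, 1, prob = pm$pfm$freq[r, ])
          }, character(1))
          chars[start:(start + mlen - 1L)] <- inst
          truth[[length(truth) + 1L]] <- data.frame(
            id = ids[i],
            motif = if (!is.null(pm$pfm$name)) pm$pfm$name else
              sprintf("motif_%d", mi),
            start = start, end = start + mlen - 1L,
            stringsAsFactors = FALSE
          )
        }
      }
      seqs[i] <- paste0(chars, collapse = "")
    }
  })
  list(
    samples = data.frame(id = ids, sequence = seqs, label = labels,
      stringsAsFactors = FALSE),
    truth = if (length(truth)) do.call(rbind, truth) else
      data.frame(id = character(), motif = character(), start = integer(),
        end = integer()),
    spec = spec
  )
}

#' Generate synthetic transcripts with planted positive sites
#'
#' Random background transcripts carrying planted positive m6A sites at
#' DRACH contexts, spaced far enough apart that every planted site is
#' recoverable as an A-centered window. The site list uses the 0-based
#' BED-like TSV dialect of [read_sites()], so the output exercises the
#' dataset-construction pipeline end to end.
#'
#' @param n number of transcripts.
#' @param length_range transcript length range (uniform draw).
#' @param sites_per_transcript planted positive sites per transcript.
#' @param flank flank the downstream pipeline will use (sites are kept at
#'   least `flank` away from the transcript ends).
#' @param spacing minimum distance between planted sites (default 500 nt).
#' @param seed RNG seed.
#' @return list with `transcripts` (named character vector) and `sites`
#'   (data.frame transcript_id/position/label/source).
#' @export
generate_transcripts <- function(n = 20, length_range = c(1500, 3000),
                                 sites_per_transcript = 2, flank = 100,
                                 spacing = 500, seed = 1) {
  stopifnot(length_range[1] >= 2 * flank + 1)
  kmers <- drach_kmers()
  transcripts <- character(n)
  names(transcripts) <- sprintf("tx%02d", seq_len(n))
  sites <- list()
  with_rng_seed(seed, {
    for (i in seq_len(n)) {
      len <- sample(length_range[1]:length_range[2], 1)
      chars <- sample(RNA_BASES, len, replace = TRUE)
      # spaced uniform placement: sorted offsets plus cumulative spacing
      lo <- flank
      hi <- len - flank - 1L
      k <- sites_per_transcript
      room <- (hi - lo) - (k - 1L) * spacing
      if (room < 0) {
        stop("cannot place ", k, " sites ", spacing,
          " nt apart in a transcript of length ", len)
      }
      placed <- lo + sort(sample.int(room + 1L, k, replace = FALSE) - 1L) +
        (seq_len(k) - 1L) * spacing # 0-based centers
      for (p in sort(placed)) {
        km <- strsplit(sample(kmers, 1), "")[[1]]
        chars[(p - 1L):(p + 3L)] <- km # 1-based window p-1..p+3
        sites[[length(sites) + 1L]] <- data.frame(
          transcript_id = names(transcripts)[i], position = p,
          label = "positive", source = "planted", stringsAsFactors = FALSE
        )
      }
      transcripts[i] <- paste0(chars, collapse = "")
    }
  })
  list(transcripts = transcripts, sites = do.call(rbind, sites))
}
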