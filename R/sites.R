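#' Read a BED-like TSV of candidate modification sites
#'
#' The expected dialect is a tab-separated file with a header naming at
#' least `transcript_id`, `position` and `label`. Positions are 0-based
#' offsets of the central adenosine within the supplied transcript sequence
#' (genome-to-transcript mapping is out of scope; callers provide mature
#' mRNA). An optional `source` column carries free-text provenance.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `transcript_id`, `position` (integer),
#'   `label`, `source`.
#' @export
read_sites <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("transcript_id", "position", "label")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("sites file is missing required column(s): ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(raw) == 0) {
    return(data.frame(
      transcript_id = character(), position = integer(),
      label = character(), source = character(),
      stringsAsFactors = FALSE
    ))
  }
  pos <- suppressWarnings(as.integer(raw$position))
  bad <- which(is.na(pos) | suppressWarnings(as.numeric(raw$position)) != pos)
  if (length(bad)) {
    # +1 for the header line so reported numbers match the file
    stop(sprintf(
      "non-integer position(s) at line(s): %s",
      paste(bad + 1L, collapse = ", ")
    ), call. = FALSE)
  }
  data.frame(
    transcript_id = raw$transcript_id,
    position = pos,
    label = tolower(raw$label),
    source = if ("source" %in% names(raw)) raw$source else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write a sites table as a BED-like TSV
#'
#' @param sites data.frame as returned by [read_sites()].
#' @param path output path.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Extract a fixed-length A-centered window around one site
#'
#' Returns a `(2 * flank + 1)`-nt window centered on the site, after the
#' standard filters: the window must lie fully within the transcript, the
#' central base must be `A`, and the central 5-mer must match DRACH. Sites
#' failing any filter are rejected, not padded; the rejection carries a
#' reason code (`out_of_bounds`, `center_not_A`, `not_drach`).
#'
#' @param transcript transcript sequence (RNA or DNA alphabet).
#' @param position 0-based offset of the central adenosine.
#' @param flank number of nucleotides on each side (default 100, i.e. a
#'   201-nt window).
#' @param label class label attached to the resulting sample.
#' @param id sample identifier.
#' @return a one-row sample data.frame (`id`, `sequence`, `label`), or an
#'   object of class `"window_rejection"` with a `reason` field.
#' @export
extract_window <- function(transcript, position, flank = 100, label = NA,
                           id = NULL) {
  if (flank < 2) stop("flank must be >= 2 so the central DRACH 5-mer fits")
  tx <- normalize_rna(transcript)
  len <- nchar(tx)
  if (is.null(id)) id <- sprintf("site_%d", position)
  reject <- function(reason) {
    structure(list(id = id, position = position, reason = reason),
      class = "window_rejection"
    )
  }
  if (position < flank || position + flank > len - 1L) {
    return(reject("out_of_bounds"))
  }
  # substr is 1-based; position is the 0-based center
  center <- substr(tx, position + 1L, position + 1L)
  if (center != "A") {
    return(reject("center_not_A"))
  }
  five <- substr(tx, position - 1L, position + 3L)
  if (!is_drach(five)) {
    return(reject("not_drach"))
  }
  seqw <- substr(tx, position - flank + 1L, position + flank + 1L)
  check_rna_alphabet(seqw, "window")
  data.frame(
    id = id, sequence = seqw, label = as.character(label),
    stringsAsFactors = FALSE
  )
}

#' Extract windows for a whole sites table
#'
#' Vectorised driver over [extract_window()] that collects accepted samples
#' and a rejection log.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param sites data.frame as returned by [read_sites()].
#' @param flank flank length per side.
#' @return list with `samples` (data.frame id/sequence/label) and
#'   `rejections` (data.frame transcript_id/position/reason).
#' @export
extract_windows <- function(transcripts, sites, flank = 100) {
  stopifnot(!is.null(names(transcripts)))
  samples <- list()
  rej <- list()
  for (i in seq_len(nrow(sites))) {
    txid <- sites$transcript_id[i]
    if (!txid %in% names(transcripts)) {
      rej[[length(rej) + 1L]] <- data.frame(
        transcript_id = txid, position = sites$position[i],
        reason = "unknown_transcript", stringsAsFactors = FALSE
      )
      next
    }
    res <- extract_window(
      transcripts[[txid]], sites$position[i], flank,
      label = sites$label[i],
      id = sprintf("%s_%d", txid, sites$position[i])
    )
    if (inherits(res, "window_rejection")) {
      rej[[length(rej) + 1L]] <- data.frame(
        transcript_id = txid, position = sites$position[i],
        reason = res$reason, stringsAsFactors = FALSE
      )
    } else {
      samples[[length(samples) + 1L]] <- res
    }
  }
  list(
    samples = if (length(samples)) do.call(rbind, samples) else
      data.frame(id = character(), sequence = character(), label = character()),
    rejections = if (length(rej)) do.call(rbind, rej) else
      data.frame(
        transcript_id = character(), position = integer(),
        reason = character()
      )
  )
}

#' Sample distance-constrained DRACH negatives
#'
#' Implements the two-step negative sampling used for balanced benchmark
#' construction: first enumerate every adenosine that (i) does not coincide
#' with a known positive, (ii) lies at least `min_distance` nt from every
#' positive site on the same transcript, and (iii) sits in a DRACH 5-mer
#' context; then subsample uniformly to `n_target`.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param positives data.frame of positive sites (`transcript_id`,
#'   `position`, 0-based).
#' @param min_distance minimum distance (nt) from any positive on the same
#'   transcript; default 200 so that 201-nt negative windows cannot overlap
#'   positive windows.
#' @param n_target number of negatives to return (typically the positive
#'   count, for a balanced set).
#' @param seed RNG seed for the uniform subsample.
#' @param flank if non-`NULL`, additionally require that a window of this
#'   flank fits within the transcript (avoids sampling negatives that would
#'   be rejected at extraction).
#' @return data.frame of negative sites (`transcript_id`, `position`,
#'   `label = "negative"`, `source`). Warns if fewer than `n_target`
#'   candidates exist.
#' @export
sample_negatives <- function(transcripts, positives, min_distance = 200,
                             n_target, seed = 1, flank = NULL) {
  if (length(transcripts) == 0) stop("empty transcript set")
  stopifnot(!is.null(names(transcripts)))
  cand <- list()
  for (txid in names(transcripts)) {
    tx <- normalize_rna(transcripts[[txid]])
    len <- nchar(tx)
    chars <- strsplit(tx, "")[[1]]
    pos_a <- which(chars == "A") - 1L # 0-based
    # central 5-mer must fit
    pos_a <- pos_a[pos_a >= 2L & pos_a <= len - 3L]
    if (!is.null(flank)) {
      pos_a <- pos_a[pos_a >= flank & pos_a <= len - flank - 1L]
    }
    if (!length(pos_a)) next
    fives <- substring(tx, pos_a - 1L, pos_a + 3L)
    pos_a <- pos_a[is_drach(fives)]
    ppos <- positives$position[positives$transcript_id == txid]
    if (length(ppos)) {
      keep <- vapply(
        pos_a,
        function(p) min(abs(p - ppos)) >= min_distance,
        logical(1)
      )
      pos_a <- pos_a[keep]
    }
    if (length(pos_a)) {
      cand[[txid]] <- data.frame(
        transcript_id = txid, position = pos_a,
        stringsAsFactors = FALSE
      )
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(transcript_id = character(), position = integer())
  rownames(cand) <- NULL
  if (nrow(cand) < n_target) {
    warning(sprintf(
      "only %d eligible negative candidates for n_target = %d; returning all",
      nrow(cand), n_target
    ))
    pick <- seq_len(nrow(cand))
  } else {
    pick <- with_rng_seed(seed, sample(nrow(cand), n_target))
  }
  out <- cand[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) {
    out$label <- "negative"
    out$source <- "sampled"
  } else {
    out$label <- character(0)
    out$source <- character(0)
  }
  out
}
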