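#' Export PFMs in MEME minimal motif format
#'
#' Writes a TOMTOM-compatible minimal MEME file over the RNA alphabet
#' (ACGU), one letter-probability block per motif with `nsites` set to the
#' motif's support. An empty list yields a header-only file.
#'
#' @param pfms list of `MotifPFM` objects (rows must sum to 1).
#' @param path output file path.
#' @param background background letter frequencies (A, C, G, U).
#' @return `path`, invisibly.
#' @export
export_meme <- function(pfms, path, background = rep(0.25, 4)) {
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGU", "",
    "strands: +", "",
    "Background letter frequencies",
    paste(
      c(rbind(RNA_BASES, formatC(background, format = "f", digits = 6))),
      collapse = " "
    ),
    ""
  )
  for (p in pfms) {
    freq <- if (inherits(p, "MotifPFM")) p$freq else p
    if (any(abs(rowSums(freq) - 1) > 1e-6)) {
      stop("PFM rows must sum to 1 for MEME export")
    }
    nm <- if (inherits(p, "MotifPFM") && !is.null(p$name)) p$name else
      sprintf("filter_%s", if (inherits(p, "MotifPFM")) p$filter_index else "x")
    support <- if (inherits(p, "MotifPFM")) p$support else nrow(freq)
    lines <- c(
      lines,
      paste("MOTIF", nm),
      sprintf(
        "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
        nrow(freq), max(support, 1L)
      ),
      apply(freq, 1, function(r) {
        paste(formatC(r, format = "f", digits = 6), collapse = " ")
      }),
      ""
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal MEME motif file
#'
#' Parses files written by [export_meme()] (and other minimal-format MEME
#' files over a 4-letter alphabet) back into `MotifPFM` objects; used for
#' round-trip checks and for importing reference motifs.
#'
#' @param path MEME file path.
#' @return list of `MotifPFM` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF")) {
      nm <- trimws(sub("^MOTIF", "", lines[i]))
      i <- i + 1
      while (i <= length(lines) &&
        !startsWith(lines[i], "letter-probability matrix")) {
        i <- i + 1
      }
      hdr <- lines[i]
      w <- as.integer(sub(".*w= *(\\d+).*", "\\1", hdr))
      nsites <- if (grepl("nsites=", hdr)) {
        as.integer(sub(".*nsites= *(\\d+).*", "\\1", hdr))
      } else NA_integer_
      block <- lines[(i + 1):(i + w)]
      freq <- do.call(rbind, lapply(block, function(x) {
        as.numeric(strsplit(trimws(x), "\\s+")[[1]])
      }))
      colnames(freq) <- RNA_BASES
      out[[length(out) + 1L]] <- structure(
        list(freq = freq, support = nsites, filter_index = NA_integer_,
          name = nm),
        class = "MotifPFM"
      )
      i <- i + w + 1
    } else {
      i <- i + 1
    }
  }
  out
}
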