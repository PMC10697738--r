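#' Test 5-mers against the DRACH consensus
#'
#' m6A deposition is strongly constrained to the degenerate 5-mer context
#' DRACH, where D is A, G or U, R is A or G, the central base is the
#' methylated adenosine, the fourth base is C and H is A, C or U. Candidate
#' sites whose central 5-mer fails this consensus are excluded from both the
#' positive and the negative class during dataset construction.
#'
#' @param window5 character vector of 5-mers over the RNA alphabet
#'   (`T` is accepted as a synonym of `U`).
#' @return logical vector, `TRUE` where the 5-mer matches DRACH.
#' @examples
#' is_drach(c("GGACU", "UUACG", "AAACA"))
#' @export
is_drach <- function(window5) {
  w <- normalize_rna(window5)
  if (any(nchar(w) != 5)) stop("is_drach() expects 5-mers, got other lengths")
  check_rna_alphabet(w, "5-mer")
  d <- substr(w, 1, 1)
  r <- substr(w, 2, 2)
  a <- substr(w, 3, 3)
  c4 <- substr(w, 4, 4)
  h <- substr(w, 5, 5)
  d %in% c("A", "G", "U") & r %in% c("A", "G") & a == "A" & c4 == "C" &
    h %in% c("A", "C", "U")
}

#' Enumerate all DRACH 5-mers
#'
#' @return character vector of the 18 5-mers matching the DRACH consensus.
#' @export
drach_kmers <- function() {
  g <- expand.grid(
    D = c("A", "G", "U"), R = c("A", "G"), A = "A", C = "C",
    H = c("A", "C", "U"), stringsAsFactors = FALSE
  )
  sort(apply(g, 1, paste0, collapse = ""))
}
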