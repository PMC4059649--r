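## Native six-frame ORF scanner. This replaces an external ORF predictor in
## the coding filter: a TU is discarded when any reading frame on either
## strand encodes an ATG-initiated peptide longer than the threshold.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest ATG-initiated ORF across all six reading frames
#'
#' Scans both strands of a nucleotide sequence in all three frames and
#' returns the length, in amino acids, of the longest open reading frame:
#' the codons from an \code{ATG} up to (but excluding) the first in-frame
#' stop codon, the initiator Met included. ORFs reaching the end of the
#' sequence without an in-frame stop are counted up to the last complete
#' codon (open-ended ORFs count — the conservative reading for a coding
#' filter). Codons containing \code{N} never match \code{ATG} or a stop.
#'
#' @param sequence a single nucleotide string (or \code{DNAString}) over
#'   \code{A,C,G,T,N}; case-insensitive.
#' @return integer amino-acid length; 0 if no \code{ATG} occurs in any frame.
#' @examples
#' longestOrfAa("ATGTAA")                     # 1: Met then stop
#' longestOrfAa("CCCCCC")                     # 0: no start codon
#' longestOrfAa("ATGAAAAAA")                  # 3: open-ended ORF
#' @export
longestOrfAa <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (length(s) != 1L) stop("sequence must be a single string")
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters other than A, C, G, T, N")
  n <- nchar(s)
  if (n < 3L) return(0L)
  rc <- as.character(reverseComplement(DNAStringSet(s))[[1L]])
  best <- 0L
  for (str in c(s, rc)) {
    for (f in 0:2) {
      k <- (n - f) %/% 3L
      if (k < 1L) next
      starts <- f + 1L + 3L * (seq_len(k) - 1L)
      codons <- substring(str, starts, starts + 2L)
      best <- max(best, .longest_orf_in_frame(codons))
    }
  }
  best
}

## one linear pass over a codon vector
.longest_orf_in_frame <- function(codons) {
  best <- 0L
  orf_start <- NA_integer_
  k <- length(codons)
  is_start <- codons == "ATG"
  is_stop <- codons %in% STOP_CODONS
  for (i in seq_len(k)) {
    if (is.na(orf_start)) {
      if (is_start[i]) orf_start <- i
    } else if (is_stop[i]) {
      best <- max(best, i - orf_start)
      orf_start <- NA_integer_
    }
  }
  if (!is.na(orf_start)) best <- max(best, k - orf_start + 1L)
  best
}
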