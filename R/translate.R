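#' Translate a DNA sequence in all six reading frames
#'
#' Frames +1..+3 start at positions 1..3 of the forward strand; frames
#' -1..-3 start at positions 1..3 of the reverse complement. Trailing
#' partial codons are dropped. Codons containing `N` translate to `X`.
#'
#' @param dna a [Biostrings::DNAString], or a character scalar over
#'   `{A,C,G,T,N}`.
#' @return A named character vector of six peptides, names
#'   `"+1","+2","+3","-1","-2","-3"`. An empty input yields six empty
#'   peptides.
#' @examples
#' six_frame_translate("ATGAAA")
#' @export
six_frame_translate <- function(dna) {
  if (is.character(dna)) dna <- Biostrings::DNAString(dna)
  stopifnot(methods::is(dna, "DNAString"))
  fwd <- dna
  rev <- Biostrings::reverseComplement(dna)
  out <- character(6)
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (f in 1:3) {
    out[f]     <- .translate_frame(fwd, f)
    out[f + 3] <- .translate_frame(rev, f)
  }
  out
}

# translate one frame, dropping the trailing partial codon
.translate_frame <- function(dna, frame) {
  n <- length(dna)
  n_codons <- (n - frame + 1L) %/% 3L
  if (n_codons <= 0L) return("")
  s <- Biostrings::subseq(dna, frame, frame + 3L * n_codons - 1L)
  as.character(Biostrings::translate(s, if.fuzzy.codon = "X"))
}
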