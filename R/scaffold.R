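#' Order and orient contigs along a related reference genome
#'
#' Reference-guided scaffolding by homology anchors: windows sampled
#' along each contig are located in the reference (exact or
#' near-exact matches on either strand). A contig is assigned to the
#' reference chromosome holding the majority of its anchors, ordered
#' by the median anchor position, and oriented by the majority anchor
#' strand. Contigs with no located anchors are listed as unplaced,
#' never dropped.
#'
#' @param contigs named [Biostrings::DNAStringSet] to place.
#' @param reference named [Biostrings::DNAStringSet] of reference
#'   chromosomes.
#' @param anchor_size anchor window length in bp.
#' @param anchor_step spacing between anchor windows in bp.
#' @param max_mismatch mismatches tolerated per anchor match.
#' @return data.frame with one row per contig: `contig`, `chrom` (`NA`
#'   when unplaced), `order` (1-based rank along the chromosome, `NA`
#'   when unplaced), `strand` (`+`/`-`/`NA`), `median_pos`,
#'   `n_anchors`.
#' @export
reference_guided_scaffold <- function(contigs, reference,
                                      anchor_size = 200,
                                      anchor_step = 500,
                                      max_mismatch = 2) {
  stopifnot(length(contigs) > 0, length(reference) > 0,
            !is.null(names(contigs)), !is.null(names(reference)))
  rows <- list()
  for (ctg in names(contigs)) {
    seq <- contigs[[ctg]]
    starts <- seq(1L, max(1L, length(seq) - anchor_size + 1L),
                  by = anchor_step)
    chroms <- character(0); pos <- numeric(0); strands <- character(0)
    for (s in starts) {
      w <- Biostrings::subseq(seq, s,
                              min(length(seq), s + anchor_size - 1L))
      if (length(w) < anchor_size %/% 2) next
      loc <- .locate_anchor(w, reference, max_mismatch)
      if (is.null(loc)) next
      chroms <- c(chroms, loc$chrom)
      pos <- c(pos, loc$pos)
      strands <- c(strands, loc$strand)
    }
    if (length(chroms) == 0) {
      rows[[ctg]] <- data.frame(contig = ctg, chrom = NA_character_,
                                strand = NA_character_,
                                median_pos = NA_real_, n_anchors = 0L,
                                stringsAsFactors = FALSE)
      next
    }
    chrom <- names(which.max(table(chroms)))
    on_chrom <- chroms == chrom
    rows[[ctg]] <- data.frame(
      contig = ctg, chrom = chrom,
      strand = names(which.max(table(strands[on_chrom]))),
      median_pos = stats::median(pos[on_chrom]),
      n_anchors = sum(on_chrom), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$order <- NA_integer_
  for (chrom in unique(stats::na.omit(out$chrom))) {
    idx <- which(!is.na(out$chrom) & out$chrom == chrom)
    out$order[idx][order(out$median_pos[idx])] <- seq_along(idx)
  }
  rownames(out) <- NULL
  out[, c("contig", "chrom", "order", "strand", "median_pos",
          "n_anchors")]
}

# best unique-ish placement of one anchor window in the reference;
# forward strand searched first, reverse complement second
.locate_anchor <- function(window, reference, max_mismatch) {
  rc <- Biostrings::reverseComplement(window)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") window else rc
    for (chrom in names(reference)) {
      m <- Biostrings::matchPattern(pat, reference[[chrom]],
                                    max.mismatch = max_mismatch)
      if (length(m) == 1)
        return(list(chrom = chrom, pos = IRanges::start(m)[1],
                    strand = strand))
      if (length(m) > 1) return(NULL)  # repetitive anchor: ambiguous
    }
  }
  NULL
}
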