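#' Thresholds for the three gene-validation methods
#'
#' Defaults mirror the standard rules: a gene is transcript-validated
#' when a uniquely mapped transcript covers at least 60% of its
#' genomic span; FPKM-validated when its expression exceeds 1 FPKM
#' (strict) in at least one condition; peptide-validated when at least
#' one unique, unambiguously mapped peptide with q-value below 0.01
#' (strict) matches its protein.
#'
#' @param transcript_overlap_min minimum covered fraction (inclusive).
#' @param fpkm_min FPKM threshold (exclusive: validation requires
#'   `fpkm > fpkm_min`).
#' @param peptide_q_max q-value ceiling (exclusive: requires
#'   `q < peptide_q_max`).
#' @return object of class `validation_thresholds`.
#' @export
validation_thresholds <- function(transcript_overlap_min = 0.60,
                                  fpkm_min = 1.0,
                                  peptide_q_max = 0.01) {
  stopifnot(transcript_overlap_min > 0, transcript_overlap_min <= 1,
            fpkm_min > 0, peptide_q_max > 0, peptide_q_max <= 1)
  structure(list(transcript_overlap_min = transcript_overlap_min,
                 fpkm_min = fpkm_min, peptide_q_max = peptide_q_max),
            class = "validation_thresholds")
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `fpkm = count * 1e9 / (gene_length * library_total)`.
#'
#' @param count mapped fragment count for the gene.
#' @param gene_length gene length in bp (> 0).
#' @param library_total total mapped fragments in the library (> 0).
#' @return numeric FPKM (vectorized).
#' @examples
#' compute_fpkm(10, 1000, 1e6)  # 10
#' @export
compute_fpkm <- function(count, gene_length, library_total) {
  stopifnot(all(gene_length > 0), all(library_total > 0),
            all(count >= 0))
  count * 1e9 / (gene_length * library_total)
}

#' FPKM validation of one gene
#'
#' TRUE iff the gene's FPKM strictly exceeds the threshold in at least
#' one condition. Library totals are the per-condition sums of mapped
#' fragments over all genes in the count table.
#'
#' @param gene_id gene to test.
#' @param counts data.frame with columns `gene`, `condition`, `count`,
#'   `gene_length`.
#' @param thresholds a [validation_thresholds()].
#' @return logical flag.
#' @export
fpkm_validate <- function(gene_id, counts,
                          thresholds = validation_thresholds()) {
  lib <- tapply(counts$count, counts$condition, sum)
  rec <- counts[counts$gene == gene_id, , drop = FALSE]
  if (nrow(rec) == 0) return(FALSE)
  tot <- as.numeric(lib[as.character(rec$condition)])
  rec <- rec[tot > 0, , drop = FALSE]  # empty library: FPKM is 0
  tot <- tot[tot > 0]
  if (nrow(rec) == 0) return(FALSE)
  f <- compute_fpkm(rec$count, rec$gene_length, tot)
  any(f > thresholds$fpkm_min)
}

#' Transcript-overlap validation of one gene
#'
#' TRUE iff some transcript that maps uniquely to the gene's locus
#' (`n_loci == 1`) covers at least the threshold fraction of the
#' gene's genomic span (inclusive at the boundary).
#'
#' @param gene_id gene to test.
#' @param alignments data.frame with columns `gene`, `transcript`,
#'   `covered_fraction`, `n_loci`.
#' @param thresholds a [validation_thresholds()].
#' @return logical flag.
#' @export
transcript_overlap_validate <- function(gene_id, alignments,
                                        thresholds = validation_thresholds()) {
  rec <- alignments[alignments$gene == gene_id, , drop = FALSE]
  if (nrow(rec) == 0) return(FALSE)
  any(rec$n_loci == 1 &
        rec$covered_fraction >= thresholds$transcript_overlap_min)
}

#' Peptide validation of one gene
#'
#' TRUE iff some peptide with q-value strictly below the threshold is
#' an exact substring of exactly one protein in the proteome, and that
#' protein is the gene's product. Peptides matching two or more
#' proteins are ambiguous and validate nothing.
#'
#' @param gene_id gene to test; its protein must be `proteome[[gene_id]]`.
#' @param peptides data.frame with columns `peptide`, `q_value`.
#' @param proteome named [Biostrings::AAStringSet] of predicted
#'   proteins (names are gene ids).
#' @param thresholds a [validation_thresholds()].
#' @return logical flag.
#' @export
peptide_validate <- function(gene_id, peptides, proteome,
                             thresholds = validation_thresholds()) {
  gene_id %in% .unambiguous_peptide_genes(peptides, proteome,
                                          thresholds)
}

# gene ids validated by at least one unique sub-threshold peptide;
# computed once per table (each peptide is located in the whole
# proteome, then ambiguous ones are discarded)
.unambiguous_peptide_genes <- function(peptides, proteome, thresholds) {
  pass <- peptides[peptides$q_value < thresholds$peptide_q_max, ,
                   drop = FALSE]
  hit <- character(0)
  for (pep in unique(pass$peptide)) {
    n <- Biostrings::vcountPattern(pep, proteome)
    if (sum(n > 0) == 1) hit <- c(hit, names(proteome)[n > 0])
  }
  unique(hit)
}

#' Assemble the per-gene evidence set
#'
#' Applies the three validation methods to every gene and returns one
#' row per gene with the three evidence flags plus bookkeeping flags
#' used by the Venn selectors.
#'
#' @param gene_ids character vector of annotated gene ids.
#' @param alignments,counts,peptides evidence tables (see
#'   [transcript_overlap_validate()], [fpkm_validate()],
#'   [peptide_validate()]).
#' @param proteome named [Biostrings::AAStringSet].
#' @param thresholds a [validation_thresholds()].
#' @param dubious,repeat_flag,non_reference logical vectors parallel
#'   to `gene_ids` (default all `FALSE`).
#' @return data.frame of class `evidence_set` with columns `gene_id`,
#'   `transcriptome_flag`, `fpkm_flag`, `protein_flag`,
#'   `dubious_flag`, `repeat_flag`, `non_reference_flag`.
#' @export
evidence_set <- function(gene_ids, alignments, counts, peptides,
                         proteome,
                         thresholds = validation_thresholds(),
                         dubious = FALSE, repeat_flag = FALSE,
                         non_reference = FALSE) {
  stopifnot(!anyDuplicated(gene_ids))
  n <- length(gene_ids)
  peptide_ok <- .unambiguous_peptide_genes(peptides, proteome,
                                           thresholds)
  out <- data.frame(
    gene_id = gene_ids,
    transcriptome_flag = vapply(gene_ids, transcript_overlap_validate,
                                logical(1), alignments = alignments,
                                thresholds = thresholds),
    fpkm_flag = vapply(gene_ids, fpkm_validate, logical(1),
                       counts = counts, thresholds = thresholds),
    protein_flag = gene_ids %in% peptide_ok,
    dubious_flag = rep_len(dubious, n),
    repeat_flag = rep_len(repeat_flag, n),
    non_reference_flag = rep_len(non_reference, n),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("evidence_set", "data.frame")
  out
}

#' Partition genes by their combination of evidence
#'
#' Counts genes in each of the eight combinations of the three
#' evidence flags (transcriptome, FPKM, protein), over a selected
#' subset: `"all"` genes, `"nondubious"`, `"non_reference"`, or
#' `"non_reference_norepeat"` (non-reference genes excluding
#' repeat-flagged ones). A logical vector selector is also accepted.
#' The eight cells always sum to the subset size.
#'
#' @param evidence an [evidence_set()].
#' @param selector subset name or logical vector.
#' @return list with `counts` (named integer vector over combinations
#'   such as `"T+F+P"`, `"T only"`, ...), `total`, and `no_evidence`.
#' @export
venn_partition <- function(evidence, selector = "all") {
  if (is.character(selector)) {
    sel <- switch(selector,
      all = rep(TRUE, nrow(evidence)),
      nondubious = !evidence$dubious_flag,
      non_reference = evidence$non_reference_flag,
      non_reference_norepeat =
        evidence$non_reference_flag & !evidence$repeat_flag,
      stop("unknown selector '", selector, "'"))
  } else {
    sel <- rep_len(as.logical(selector), nrow(evidence))
  }
  e <- evidence[sel, , drop = FALSE]
  combos <- c("none", "T", "F", "P", "T+F", "T+P", "F+P", "T+F+P")
  key <- function(t, f, p) {
    lab <- c(if (t) "T", if (f) "F", if (p) "P")
    if (length(lab) == 0) "none" else paste(lab, collapse = "+")
  }
  counts <- stats::setNames(integer(length(combos)), combos)
  for (i in seq_len(nrow(e))) {
    k <- key(e$transcriptome_flag[i], e$fpkm_flag[i], e$protein_flag[i])
    counts[k] <- counts[k] + 1L
  }
  list(counts = counts, total = nrow(e),
       no_evidence = unname(counts["none"]))
}
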