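# Independent oracles used to cross-check the implementation.
# These deliberately use different algorithms/code paths than the
# package internals.

# Textbook Smith-Waterman with affine gaps (gap of length L costs
# open + L * ext), plain double loop over the full DP matrices.
sw_oracle <- function(query, subject, scheme) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  if (n == 0 || m == 0) return(0)
  mat <- scheme$substitution_matrix
  open <- scheme$gap_open; ext <- scheme$gap_extend
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in subject (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1], H[i, j - 1] - open) - ext
      F[i, j] <- max(F[i - 1, j], H[i - 1, j] - open) - ext
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[q[i - 1], s[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# best raw score over all six frames of all contigs, via the DP oracle
six_frame_search_oracle <- function(query, genome, scheme) {
  best <- 0
  for (ctg in names(genome)) {
    frames <- strainpan::six_frame_translate(genome[[ctg]])
    for (pep in frames) {
      if (nchar(pep) == 0) next
      best <- max(best, sw_oracle(query, pep, scheme))
    }
  }
  best
}

# codon-by-codon translation via the standard genetic code table
translate_oracle <- function(dna) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(dna) %/% 3
  if (n == 0) return("")
  codons <- substring(dna, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- ifelse(grepl("N", codons), "X", unname(code[codons]))
  paste(aa, collapse = "")
}

# two-sided Fisher exact log10 p by full enumeration of the
# hypergeometric support, using stats::dhyper in log space
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(0)
  x <- max(0, c1 - r2):min(r1, c1)
  lp <- stats::dhyper(x, r1, r2, c1, log = TRUE)
  obs <- lp[x == a]
  keep <- lp <= obs + log(1 + 1e-7)
  mx <- max(lp[keep])
  min(0, (mx + log(sum(exp(lp[keep] - mx)))) / log(10))
}

# N50 by exhaustive threshold scan over candidate lengths
n50_scan_oracle <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  min(lengths)
}

# direct replay of the Novelty Metric formula from a hit table
novelty_replay_oracle <- function(hits, q, g, ref) {
  h <- hits[hits$query_id == q, ]
  bit <- function(gg) {
    v <- h$bit_score[h$genome_id == gg]
    if (length(v) == 0) 0 else max(v)
  }
  mx <- if (nrow(h) == 0) 0 else max(h$bit_score)
  if (mx <= 0) return(NA_real_)
  (bit(g) - bit(ref)) / mx
}

# protein sequence of a planted gene (terminal stop removed)
truth_protein <- function(truth, gene_id) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(truth$gene_seqs[[gene_id]])))
  sub("\\*$", "", aa)
}

truth_proteins <- function(truth, gene_ids) {
  Biostrings::AAStringSet(vapply(gene_ids, truth_protein,
                                 character(1), truth = truth))
}

random_peptide <- function(n) {
  paste(sample(setdiff(strainpan:::.AA_ALPHABET, c("X", "*")), n,
               replace = TRUE), collapse = "")
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
        collapse = "")
}
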