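#' Generate two noisy annotator tracks from planted truth
#'
#' Emulates two independent annotation pipelines for one strain: each
#' track perturbs a random fraction of the true gene models. A
#' perturbed model is either 5'-shifted by whole codons (losing the
#' start codon), 3'-truncated by whole codons (losing the stop), or
#' dropped entirely. Perturbations are whole-codon so frame-consistent
#' annotator errors remain distinguishable from pseudogenization.
#' Dubious labels are carried into both tracks; pseudogene loci are
#' emitted as putative genes (discovering the disruption is the
#' merge's job).
#'
#' @param truth a `synthetic_truth` (see [generate_strain_panel()]).
#' @param error_rate per-gene perturbation probability (per track).
#' @param seed integer seed for the perturbation draw.
#' @param strain strain to annotate (default the focal strain).
#' @param types perturbation types to draw from; e.g. `"drop"` alone
#'   gives a drop-only annotator.
#' @return list with `track_a`, `track_b` ([annotation_set()]s) and
#'   `perturbations` (data.frame: `track`, `gene_id`, `type`,
#'   `codons` shifted/truncated) for measuring correction recall.
#' @export
generate_annotator_calls <- function(truth, error_rate, seed,
                                     strain = truth$focal_strain,
                                     types = c("shift", "truncate",
                                               "drop")) {
  stopifnot(inherits(truth, "synthetic_truth"),
            error_rate >= 0, error_rate <= 1)
  .with_seed(seed, {
    pl <- truth$placements
    pl <- pl[pl$strain == strain, , drop = FALSE]
    make_track <- function(label) {
      models <- list(); perts <- list()
      for (i in seq_len(nrow(pl))) {
        row <- pl[i, ]
        status <- if (row$class == "dubious") "dubious" else "valid_coding"
        m <- gene_models(row$gene_id, row$contig, row$start, row$end,
                         row$strand, status = status, source = label)
        if (stats::runif(1) < error_rate) {
          type <- if (length(types) == 1) types else sample(types, 1)
          codons <- sample(2:6, 1)
          if (type == "drop") {
            perts[[length(perts) + 1L]] <- data.frame(
              track = label, gene_id = row$gene_id, type = type,
              codons = NA_integer_, stringsAsFactors = FALSE)
            next
          }
          if (type == "shift") {          # 5' end moved inward
            if (row$strand == "+") m$start <- m$start + 3L * codons
            else m$end <- m$end - 3L * codons
          } else {                        # 3' end moved inward
            if (row$strand == "+") m$end <- m$end - 3L * codons
            else m$start <- m$start + 3L * codons
          }
          perts[[length(perts) + 1L]] <- data.frame(
            track = label, gene_id = row$gene_id, type = type,
            codons = codons, stringsAsFactors = FALSE)
        }
        models[[length(models) + 1L]] <- m
      }
      models <- if (length(models)) do.call(rbind, models)
        else gene_models(character(0), character(0), integer(0),
                         integer(0), character(0))
      list(set = annotation_set(strain, models, label),
           perts = if (length(perts)) do.call(rbind, perts)
                   else data.frame(track = character(),
                                   gene_id = character(),
                                   type = character(),
                                   codons = integer(),
                                   stringsAsFactors = FALSE))
    }
    a <- make_track("trackA")
    b <- make_track("trackB")
    list(track_a = a$set, track_b = b$set,
         perturbations = rbind(a$perts, b$perts))
  })
}

#' Generate expression and peptide evidence from planted truth
#'
#' Emits the three evidence tables for one strain's genes. Truly
#' expressed genes receive: a uniquely mapping transcript covering at
#' least 60% of the gene; per-condition counts giving FPKM > 1 in at
#' least one condition; and 1--2 unique peptides at q < 0.01.
#' Non-expressed genes receive none of the three. Peptides drawn from
#' the planted shared blocks are emitted as well; they match two
#' proteins and so exercise the uniqueness filter without validating
#' anything.
#'
#' @param truth a `synthetic_truth`.
#' @param seed integer seed.
#' @param strain strain (default focal).
#' @param n_conditions number of expression conditions.
#' @return list with `alignments`, `counts`, `peptides` (data.frames
#'   in the formats consumed by [evidence_set()]) and `proteome`
#'   (named [Biostrings::AAStringSet] of the strain's predicted
#'   proteins).
#' @export
generate_expression_evidence <- function(truth, seed,
                                         strain = truth$focal_strain,
                                         n_conditions = 4L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  .with_seed(seed, {
    pl <- truth$placements
    pl <- pl[pl$strain == strain, , drop = FALSE]
    coding <- pl[pl$class %in% c("core", "novel", "dubious"), ,
                 drop = FALSE]
    prot <- vapply(coding$gene_id, function(g) {
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(truth$gene_seqs[[g]]),
        if.fuzzy.codon = "X"))
      sub("\\*$", "", aa)
    }, character(1))
    proteome <- Biostrings::AAStringSet(prot)

    expressed <- coding$gene_id[coding$expressed]
    conditions <- sprintf("cond%d", seq_len(n_conditions))

    aln <- data.frame(gene = character(), transcript = character(),
                      covered_fraction = numeric(), n_loci = integer(),
                      stringsAsFactors = FALSE)
    for (g in expressed) {
      aln <- rbind(aln, data.frame(
        gene = g, transcript = paste0("tx_", g),
        covered_fraction = stats::runif(1, 0.7, 1.0), n_loci = 1L,
        stringsAsFactors = FALSE))
    }

    counts <- expand.grid(gene = coding$gene_id,
                          condition = conditions,
                          stringsAsFactors = FALSE)
    glen <- stats::setNames(coding$end - coding$start + 1L,
                            coding$gene_id)
    counts$gene_length <- as.integer(glen[counts$gene])
    counts$count <- ifelse(counts$gene %in% expressed,
                           stats::rpois(nrow(counts), 30) + 1L, 0L)
    counts <- counts[, c("gene", "condition", "count", "gene_length")]

    peptides <- data.frame(peptide = character(),
                           protein_ids = character(),
                           q_value = numeric(), stringsAsFactors = FALSE)
    for (g in expressed) {
      p <- prot[[g]]
      for (r in seq_len(sample(1:2, 1))) {
        if (nchar(p) < 12) next
        at <- sample(nchar(p) - 10, 1)
        pep <- substr(p, at, at + 9)
        matches <- names(prot)[vapply(prot, function(x)
          grepl(pep, x, fixed = TRUE), logical(1))]
        peptides <- rbind(peptides, data.frame(
          peptide = pep, protein_ids = paste(matches, collapse = ";"),
          q_value = stats::runif(1, 0, 0.009),
          stringsAsFactors = FALSE))
      }
    }
    for (pair in truth$shared_pairs) {
      if (!all(pair %in% names(prot))) next
      # an 11-residue peptide inside the shared block of both genes
      p1 <- prot[[pair[1]]]; p2 <- prot[[pair[2]]]
      pep <- .longest_shared_window(p1, p2, 11)
      if (is.na(pep)) next
      peptides <- rbind(peptides, data.frame(
        peptide = pep, protein_ids = paste(pair, collapse = ";"),
        q_value = stats::runif(1, 0, 0.009), stringsAsFactors = FALSE))
    }
    list(alignments = aln, counts = counts, peptides = peptides,
         proteome = proteome)
  })
}

# first length-k window of a that also occurs in b (NA if none)
.longest_shared_window <- function(a, b, k) {
  if (nchar(a) < k) return(NA_character_)
  for (s in seq_len(nchar(a) - k + 1)) {
    w <- substr(a, s, s + k - 1)
    if (grepl(w, b, fixed = TRUE)) return(w)
  }
  NA_character_
}
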