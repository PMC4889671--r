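#' Parameters for gene-geography analyses
#'
#' @param subtelomere_span bp from a chromosome end within which a
#'   gene counts as subtelomeric (default 50 kbp; the boundary is
#'   inclusive, so a gene exactly 50 kbp from the nearest end is
#'   subtelomeric).
#' @param cluster_max_gap maximum gap in bp between consecutive
#'   cluster members.
#' @param cluster_min_size minimum genes per cluster (>= 2).
#' @param missing_bit_floor bit-score floor below which a reference
#'   gene counts as missing from a target genome; `NULL` derives it
#'   from the search scheme's raw floor.
#' @param synteny_flank number of neighboring genes on each side used
#'   to judge synteny.
#' @return object of class `geography_params`.
#' @export
geography_params <- function(subtelomere_span = 50000,
                             cluster_max_gap = 20000,
                             cluster_min_size = 2,
                             missing_bit_floor = NULL,
                             synteny_flank = 2) {
  stopifnot(subtelomere_span > 0, cluster_max_gap > 0,
            cluster_min_size >= 2, synteny_flank > 0)
  structure(list(subtelomere_span = subtelomere_span,
                 cluster_max_gap = cluster_max_gap,
                 cluster_min_size = cluster_min_size,
                 missing_bit_floor = missing_bit_floor,
                 synteny_flank = synteny_flank),
            class = "geography_params")
}

.missing_floor <- function(params, scheme) {
  if (!is.null(params$missing_bit_floor)) return(params$missing_bit_floor)
  raw_to_bitscore(scheme$raw_floor, scheme)
}

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L sum to at
#' least half the total. Invariant under permutation; scales linearly
#' under uniform scaling of the lengths.
#'
#' @param lengths positive numeric vector.
#' @return the N50 value.
#' @examples
#' n50(c(10, 5, 3, 2))  # 10
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Classify gene models as subtelomeric
#'
#' A gene is subtelomeric when its nearest distance to a chromosome
#' end, `min(start - 1, contig_length - end)`, is at most the span
#' (boundary inclusive).
#'
#' @param models gene-model data.frame (see [gene_models()]).
#' @param contig_lengths named vector of contig lengths.
#' @param params a [geography_params()].
#' @return logical vector parallel to the model rows.
#' @export
subtelomeric_classify <- function(models, contig_lengths,
                                  params = geography_params()) {
  len <- as.numeric(contig_lengths[models$contig])
  if (anyNA(len)) stop("model on contig without a known length")
  d <- pmin(models$start - 1, len - models$end)
  d <= params$subtelomere_span
}

#' Genes of a reference annotation missing from a target genome
#'
#' A reference gene is missing iff its best translated-search bit
#' score against the target genome falls below the floor. Raising the
#' floor can only grow the missing set.
#'
#' @param ref_set [annotation_set()] of the reference genome (only
#'   `valid_coding` and `dubious` models are searched).
#' @param ref_genome,target_genome named [Biostrings::DNAStringSet].
#' @param scheme a [scoring_scheme()].
#' @param params a [geography_params()].
#' @return data.frame with `gene_id` and `best_bit` for each missing
#'   gene (zero rows when nothing is missing).
#' @export
detect_missing_genes <- function(ref_set, ref_genome, target_genome,
                                 scheme = scoring_scheme(),
                                 params = geography_params()) {
  floor_bits <- .missing_floor(params, scheme)
  prot <- annotation_proteins(ref_set, ref_genome)
  frames <- genome_frames(target_genome)
  out <- data.frame(gene_id = character(), best_bit = numeric(),
                    stringsAsFactors = FALSE)
  for (g in names(prot)) {
    hit <- best_genome_hit(prot[[g]], target_genome, scheme,
                           raw_floor = 0, frames = frames)
    bits <- if (is.null(hit)) 0 else hit$bit_score
    if (bits < floor_bits)
      out <- rbind(out, data.frame(gene_id = g, best_bit = bits,
                                   stringsAsFactors = FALSE))
  }
  out
}

#' Predicted proteins of an annotation set
#'
#' Translates every `valid_coding` (and `dubious`) gene model,
#' dropping the terminal stop.
#'
#' @param set an [annotation_set()].
#' @param genome named [Biostrings::DNAStringSet].
#' @return named character vector of protein sequences.
#' @export
annotation_proteins <- function(set, genome) {
  m <- set$models
  m <- m[m$type != "tRNA" & m$status %in% c("valid_coding", "dubious"), ,
         drop = FALSE]
  out <- character(nrow(m))
  names(out) <- m$id
  for (i in seq_len(nrow(m))) {
    s <- .model_seq(as.list(m[i, ]), genome)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(s), if.fuzzy.codon = "X"))
    out[i] <- sub("\\*$", "", aa)
  }
  out
}

#' Nonsyntenic homolog pairs between two annotated genomes
#'
#' A pair (a, b) is reported when the two proteins are mutual best
#' hits between the two gene sets (by local-alignment raw score, ties
#' broken toward the lexicographically smaller id) and their
#' neighborhoods disagree: the flanking gene-id sets (up to
#' `synteny_flank` genes each side, order-insensitive) share no
#' common id.
#'
#' @param set_a,set_b [annotation_set()] objects.
#' @param genome_a,genome_b their assemblies.
#' @param scheme a [scoring_scheme()].
#' @param params a [geography_params()].
#' @return data.frame with columns `gene_a`, `gene_b`, `raw_score`.
#' @export
find_nonsyntenic_homologs <- function(set_a, set_b, genome_a, genome_b,
                                      scheme = scoring_scheme(),
                                      params = geography_params()) {
  pa <- annotation_proteins(set_a, genome_a)
  pb <- annotation_proteins(set_b, genome_b)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      raw_score = numeric(), stringsAsFactors = FALSE)
  if (length(pa) == 0 || length(pb) == 0) return(empty)
  sc <- matrix(0, length(pa), length(pb),
               dimnames = list(names(pa), names(pb)))
  for (i in names(pa)) for (j in names(pb))
    sc[i, j] <- local_align(pa[[i]], pb[[j]], scheme)$raw_score
  best_b_of_a <- colnames(sc)[apply(sc, 1, which.max)]
  best_a_of_b <- rownames(sc)[apply(sc, 2, which.max)]
  names(best_b_of_a) <- rownames(sc)
  names(best_a_of_b) <- colnames(sc)
  out <- empty
  for (a in names(best_b_of_a)) {
    b <- best_b_of_a[[a]]
    if (!identical(best_a_of_b[[b]], a)) next       # not reciprocal
    if (sc[a, b] < scheme$raw_floor) next           # noise pair
    fa <- .flank_ids(set_a$models, a, params$synteny_flank)
    fb <- .flank_ids(set_b$models, b, params$synteny_flank)
    if (length(intersect(fa, fb)) == 0)
      out <- rbind(out, data.frame(gene_a = a, gene_b = b,
                                   raw_score = sc[a, b],
                                   stringsAsFactors = FALSE))
  }
  out
}

# ids of up to k coordinate-neighbors on each side of gene `id`
.flank_ids <- function(models, id, k) {
  m <- models[models$type != "tRNA", , drop = FALSE]
  m <- m[order(m$contig, m$start), , drop = FALSE]
  i <- which(m$id == id)
  if (length(i) != 1) stop("gene '", id, "' not found once")
  same <- which(m$contig == m$contig[i])
  pos <- match(i, same)
  take <- same[setdiff(seq(max(1, pos - k), min(length(same), pos + k)),
                       pos)]
  m$id[take]
}

#' Clusters of flagged genes along the chromosomes
#'
#' Maximal runs of flagged genes on one contig with inter-gene gaps at
#' most `cluster_max_gap` and at least `cluster_min_size` members.
#' Each call carries a subtelomeric flag judged at the midpoint of the
#' cluster span.
#'
#' @param flagged_ids ids of the genes of interest (e.g. novel genes).
#' @param models gene-model data.frame holding their coordinates.
#' @param contig_lengths named vector of contig lengths.
#' @param params a [geography_params()].
#' @return data.frame with one row per cluster: `contig`, `members`
#'   (comma-joined ids in coordinate order), `n`, `start`, `end`,
#'   `span`, `subtelomeric`.
#' @export
detect_gene_clusters <- function(flagged_ids, models, contig_lengths,
                                 params = geography_params()) {
  m <- models[models$id %in% flagged_ids, , drop = FALSE]
  m <- m[order(m$contig, m$start), , drop = FALSE]
  out <- data.frame(contig = character(), members = character(),
                    n = integer(), start = integer(), end = integer(),
                    span = integer(), subtelomeric = logical(),
                    stringsAsFactors = FALSE)
  if (nrow(m) == 0) return(out)
  run <- list(m[1, ])
  flush <- function(run, out) {
    if (length(run) < params$cluster_min_size) return(out)
    r <- do.call(rbind, run)
    mid <- floor((min(r$start) + max(r$end)) / 2)
    sub <- subtelomeric_classify(
      data.frame(contig = r$contig[1], start = mid, end = mid),
      contig_lengths, params)
    rbind(out, data.frame(
      contig = r$contig[1], members = paste(r$id, collapse = ","),
      n = nrow(r), start = min(r$start), end = max(r$end),
      span = max(r$end) - min(r$start) + 1L, subtelomeric = sub,
      stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(m))[-1]) {
    prev <- run[[length(run)]]
    gap <- m$start[i] - prev$end
    if (m$contig[i] == prev$contig && gap <= params$cluster_max_gap) {
      run[[length(run) + 1L]] <- m[i, ]
    } else {
      out <- flush(run, out)
      run <- list(m[i, ])
    }
  }
  flush(run, out)
}
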