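#' Configuration of a synthetic strain panel
#'
#' Defines the geometry and composition of a planted strain panel: a
#' reference strain carrying only core genes, plus derived strains
#' carrying planted novel genes (with a configurable subtelomeric
#' bias), gene clusters, pseudogenes, and dubious ORFs, together with
#' two noisy annotator tracks and expression/peptide evidence.
#'
#' Defaults use a desk-scale geometry (two 20 kb chromosomes, 5 kb
#' subtelomere span, 50--100-codon genes) chosen so that full
#' translated search over the whole panel runs in seconds while
#' preserving the structural features under study: both subtelomeric
#' and interior placements are possible, clusters fit inside one
#' subtelomere, and novel genes are sequence-unrelated to core genes
#' so their best cross-hits sit at the noise floor.
#'
#' @param seed integer seed; identical seed and config give
#'   byte-identical output.
#' @param n_strains total strains including the reference (>= 2; the
#'   second strain is the focal derived strain carrying every planted
#'   feature).
#' @param n_chromosomes,chromosome_length panel geometry (bp).
#' @param subtelomere_span bp from each chromosome end that counts as
#'   subtelomeric for placement; `chromosome_length` must be at least
#'   twice this span.
#' @param n_core_genes genes shared by every strain.
#' @param n_novel_genes genes absent from the reference strain.
#' @param novel_subtelomeric_fraction probability that a novel gene
#'   (or cluster) is placed subtelomerically.
#' @param n_clusters,cluster_size planted clusters of coordinate-
#'   adjacent novel genes; cluster members are drawn from
#'   `n_novel_genes` (so `n_clusters * cluster_size <=
#'   n_novel_genes`).
#' @param n_pseudogenes planted disrupted genes (early in-frame stop,
#'   no in-frame rescue ATG) on the focal strain.
#' @param n_dubious planted structurally valid ORFs labeled dubious
#'   on the focal strain.
#' @param annotator_error_rate per-gene perturbation probability for
#'   [generate_annotator_calls()].
#' @param expression_fraction fraction of valid, nondubious focal
#'   genes that are truly expressed.
#' @param n_shared_peptide_pairs pairs of core genes sharing an
#'   11-codon block, used to emit ambiguous peptides.
#' @param gene_codons integer range (min, max) of codons per gene
#'   (excluding stop).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_strains = 4L,
                             n_chromosomes = 2L,
                             chromosome_length = 20000L,
                             subtelomere_span = 5000L,
                             n_core_genes = 30L, n_novel_genes = 8L,
                             novel_subtelomeric_fraction = 0.8,
                             n_clusters = 1L, cluster_size = 3L,
                             n_pseudogenes = 3L, n_dubious = 3L,
                             annotator_error_rate = 0.2,
                             expression_fraction = 0.7,
                             n_shared_peptide_pairs = 2L,
                             gene_codons = c(50L, 100L)) {
  cfg <- list(seed = as.integer(seed), n_strains = as.integer(n_strains),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              subtelomere_span = as.integer(subtelomere_span),
              n_core_genes = as.integer(n_core_genes),
              n_novel_genes = as.integer(n_novel_genes),
              novel_subtelomeric_fraction = novel_subtelomeric_fraction,
              n_clusters = as.integer(n_clusters),
              cluster_size = as.integer(cluster_size),
              n_pseudogenes = as.integer(n_pseudogenes),
              n_dubious = as.integer(n_dubious),
              annotator_error_rate = annotator_error_rate,
              expression_fraction = expression_fraction,
              n_shared_peptide_pairs = as.integer(n_shared_peptide_pairs),
              gene_codons = as.integer(gene_codons))
  counts <- cfg[c("n_strains", "n_chromosomes", "chromosome_length",
                  "n_core_genes", "n_novel_genes", "n_clusters",
                  "cluster_size", "n_pseudogenes", "n_dubious")]
  stopifnot(all(unlist(counts) >= 0), cfg$n_strains >= 2,
            cfg$n_chromosomes >= 1)
  props <- cfg[c("novel_subtelomeric_fraction", "annotator_error_rate",
                 "expression_fraction")]
  stopifnot(all(unlist(props) >= 0), all(unlist(props) <= 1))
  if (cfg$chromosome_length < 2 * cfg$subtelomere_span)
    stop("chromosome_length must be at least twice subtelomere_span")
  if (cfg$n_clusters * cfg$cluster_size > cfg$n_novel_genes)
    stop("clusters require n_clusters * cluster_size <= n_novel_genes")
  structure(cfg, class = "synthetic_config")
}

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv())
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.BASES <- c("A", "C", "G", "T")
.SENSE_CODONS <- setdiff(
  apply(expand.grid(.BASES, .BASES, .BASES), 1, paste, collapse = ""),
  .STOPS)

.random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# random ORF: ATG + sense codons + stop. `no_atg` also excludes
# internal in-frame ATG codons (used for pseudogene bodies so no
# in-frame rescue start exists).
.random_orf <- function(n_codons, no_atg = FALSE) {
  pool <- if (no_atg) setdiff(.SENSE_CODONS, "ATG") else .SENSE_CODONS
  body <- sample(pool, n_codons - 1L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(.STOPS, 1))
}

#' Generate a synthetic strain panel with planted truth
#'
#' Builds one genome per strain. The reference strain carries only
#' the core genes; each derived strain carries the core genes plus a
#' subset of the planted novel genes (the focal strain carries all of
#' them, together with the planted pseudogenes and dubious ORFs;
#' other derived strains carry each novel gene or cluster with
#' probability 1/2). Background DNA is i.i.d. uniform over A/C/G/T;
#' genes are random codon sequences between ATG and a stop, so all
#' planted genes except pseudogenes are valid ORFs and novel genes
#' are unrelated to core genes. Pseudogenes carry an early in-frame
#' stop and no in-frame ATG downstream, so they cannot be rescued by
#' boundary correction.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_panel` with elements `panel`
#'   (named list of [Biostrings::DNAStringSet] genomes) and `truth`
#'   (class `synthetic_truth`: `placements` data.frame with one row
#'   per strain/gene placement, `gene_info` per-gene metadata,
#'   `gene_seqs` oriented gene sequences, `strains`,
#'   `reference_strain`, `focal_strain`, and the `config`).
#' @export
generate_strain_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(config$seed, .generate_strain_panel(config))
}

.generate_strain_panel <- function(cfg) {
  strains <- c("ref", paste0("strain", LETTERS[seq_len(cfg$n_strains - 1)]))
  reference <- strains[1]; focal <- strains[2]

  ## --- per-gene metadata -------------------------------------------------
  ids <- c(sprintf("core%03d", seq_len(cfg$n_core_genes)),
           sprintf("novel%03d", seq_len(cfg$n_novel_genes)),
           sprintf("pseudo%03d", seq_len(cfg$n_pseudogenes)),
           sprintf("dub%03d", seq_len(cfg$n_dubious)))
  class_of <- c(rep("core", cfg$n_core_genes),
                rep("novel", cfg$n_novel_genes),
                rep("pseudogene", cfg$n_pseudogenes),
                rep("dubious", cfg$n_dubious))
  names(class_of) <- ids
  n_genes <- length(ids)
  codons <- sample(seq(cfg$gene_codons[1], cfg$gene_codons[2]),
                   n_genes, replace = TRUE)
  # pseudogenes get long bodies with a mid-gene disruption and no
  # in-frame ATG after it, so no boundary repair within a correction
  # window of a few hundred bp can restore a valid ORF
  codons[class_of == "pseudogene"] <-
    pmax(codons[class_of == "pseudogene"], 240L)
  seqs <- character(n_genes)
  for (i in seq_len(n_genes)) {
    if (class_of[i] == "pseudogene") {
      s <- .random_orf(codons[i], no_atg = TRUE)
      mid <- codons[i] %/% 2L
      substr(s, 3L * mid + 1L, 3L * mid + 3L) <- sample(.STOPS, 1)
      seqs[i] <- s
    } else {
      seqs[i] <- .random_orf(codons[i])
    }
  }
  names(seqs) <- ids

  # shared 11-codon blocks between pairs of core genes (ambiguous
  # peptide source); copied in frame into the middle of both genes
  shared_pairs <- list()
  if (cfg$n_shared_peptide_pairs > 0 && cfg$n_core_genes >= 2) {
    n_pairs <- min(cfg$n_shared_peptide_pairs, cfg$n_core_genes %/% 2)
    picks <- sample(which(class_of == "core"), 2 * n_pairs)
    for (p in seq_len(n_pairs)) {
      i <- picks[2 * p - 1]; j <- picks[2 * p]
      block <- paste(sample(.SENSE_CODONS, 11, replace = TRUE),
                     collapse = "")
      at <- function(s) 3 * (nchar(s) %/% 6) + 1  # mid, in frame
      substr(seqs[i], at(seqs[i]), at(seqs[i]) + 32) <- block
      substr(seqs[j], at(seqs[j]), at(seqs[j]) + 32) <- block
      shared_pairs[[p]] <- c(ids[i], ids[j])
    }
  }

  ## --- placement plan ----------------------------------------------------
  # zone: subtel_left / subtel_right / interior, per gene; clusters
  # share one zone and stay adjacent
  zone <- character(n_genes); names(zone) <- ids
  chrom <- integer(n_genes); names(chrom) <- ids
  cluster_id <- rep(NA_integer_, n_genes); names(cluster_id) <- ids
  pick_zone <- function(p_subtel) {
    if (stats::runif(1) < p_subtel)
      sample(c("subtel_left", "subtel_right"), 1)
    else "interior"
  }
  is_core <- class_of == "core"
  for (i in which(is_core)) {
    zone[i] <- pick_zone(0.2)
    chrom[i] <- sample(cfg$n_chromosomes, 1)
  }
  novel_idx <- which(class_of == "novel")
  k <- 0L
  if (cfg$n_clusters > 0) {
    for (cl in seq_len(cfg$n_clusters)) {
      members <- novel_idx[k + seq_len(cfg$cluster_size)]
      k <- k + cfg$cluster_size
      z <- pick_zone(cfg$novel_subtelomeric_fraction)
      ch <- sample(cfg$n_chromosomes, 1)
      zone[members] <- z; chrom[members] <- ch
      cluster_id[members] <- cl
    }
  }
  for (i in novel_idx[seq_along(novel_idx) > k]) {
    zone[i] <- pick_zone(cfg$novel_subtelomeric_fraction)
    chrom[i] <- sample(cfg$n_chromosomes, 1)
  }
  for (i in which(class_of %in% c("pseudogene", "dubious"))) {
    zone[i] <- pick_zone(0.3)
    chrom[i] <- sample(cfg$n_chromosomes, 1)
  }
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  names(strand) <- ids

  ## --- strain membership -------------------------------------------------
  carried <- matrix(FALSE, n_genes, length(strains),
                    dimnames = list(ids, strains))
  carried[is_core, ] <- TRUE
  carried[class_of %in% c("pseudogene", "dubious"), focal] <- TRUE
  carried[class_of == "novel", focal] <- TRUE
  others <- setdiff(strains, c(reference, focal))
  for (st in others) {
    # clusters travel as a unit
    for (cl in unique(stats::na.omit(cluster_id)))
      carried[!is.na(cluster_id) & cluster_id == cl, st] <-
        stats::runif(1) < 0.5
    singles <- class_of == "novel" & is.na(cluster_id)
    carried[singles, st] <- stats::runif(sum(singles)) < 0.5
  }

  ## --- expression truth --------------------------------------------------
  expressible <- carried[, focal] & class_of %in% c("core", "novel")
  expressed <- rep(FALSE, n_genes); names(expressed) <- ids
  expressed[expressible] <-
    stats::runif(sum(expressible)) < cfg$expression_fraction

  ## --- build genomes -----------------------------------------------------
  placements <- list()
  panel <- list()
  for (st in strains) {
    chroms <- character(cfg$n_chromosomes)
    for (ch in seq_len(cfg$n_chromosomes)) {
      here <- which(carried[, st] & chrom == ch)
      # cluster members adjacent (grouped by cluster id), remaining
      # genes in random order
      key <- ifelse(is.na(cluster_id[here]), 1e6, cluster_id[here])
      here <- here[order(key, sample(length(here)))]
      built <- .build_chromosome(st, ch, here, ids, seqs, strand, zone,
                                 cluster_id, cfg)
      chroms[ch] <- built$seq
      if (nrow(built$placed) > 0) {
        built$placed$class <- class_of[built$placed$gene_id]
        built$placed$cluster_id <- cluster_id[built$placed$gene_id]
        built$placed$expressed <- if (st == focal)
          expressed[built$placed$gene_id] else FALSE
        placements[[length(placements) + 1L]] <- built$placed
      }
    }
    names(chroms) <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
    panel[[st]] <- Biostrings::DNAStringSet(chroms)
  }
  placements <- do.call(rbind, placements)
  rownames(placements) <- NULL

  gene_info <- data.frame(
    gene_id = ids, class = class_of, zone = zone,
    chromosome = sprintf("chr%02d", chrom), strand = strand,
    length = nchar(seqs), cluster_id = cluster_id,
    expressed = expressed, stringsAsFactors = FALSE)
  truth <- structure(
    list(placements = placements, gene_info = gene_info,
         gene_seqs = seqs, shared_pairs = shared_pairs,
         strains = strains, reference_strain = reference,
         focal_strain = focal, config = cfg),
    class = "synthetic_truth")
  structure(list(panel = panel, truth = truth),
            class = "synthetic_panel")
}

# assemble one chromosome from its gene list; returns the sequence
# and the realized placements
.build_chromosome <- function(strain, ch, here, ids, seqs, strand,
                              zone, cluster_id, cfg) {
  L <- cfg$chromosome_length
  span <- cfg$subtelomere_span
  spacer <- function() sample(100:250, 1)
  cluster_gap <- function() sample(150:300, 1)

  build_block <- function(idx) {
    # returns list(seq, offsets df) with 1-based offsets inside block
    pieces <- character(0); pos <- 0L
    rows <- list()
    prev_cluster <- NA_integer_
    for (i in idx) {
      gap <- if (!is.na(cluster_id[i]) && !is.na(prev_cluster) &&
                 cluster_id[i] == prev_cluster) cluster_gap() else spacer()
      sp <- .random_dna(gap)
      g <- seqs[i]
      if (strand[i] == "-")
        g <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(g)))
      pieces <- c(pieces, sp, g)
      start <- pos + gap + 1L
      end <- start + nchar(seqs[i]) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        strain = strain, gene_id = ids[i],
        contig = sprintf("chr%02d", ch), start = start, end = end,
        strand = strand[i], location_class = NA_character_,
        stringsAsFactors = FALSE)
      pos <- end
      prev_cluster <- cluster_id[i]
    }
    list(seq = paste(pieces, collapse = ""),
         placed = if (length(rows)) do.call(rbind, rows)
                  else data.frame())
  }
  shift_block <- function(block, offset) {
    if (nrow(block$placed) > 0) {
      block$placed$start <- block$placed$start + offset
      block$placed$end <- block$placed$end + offset
    }
    block
  }

  left <- build_block(here[zone[here] == "subtel_left"])
  mid <- build_block(here[zone[here] == "interior"])
  right <- build_block(here[zone[here] == "subtel_right"])
  llen <- nchar(left$seq); mlen <- nchar(mid$seq)
  rlen <- nchar(right$seq)
  if (llen > span || rlen > span)
    stop("synthetic config infeasible: subtelomeric genes exceed the ",
         "subtelomere span on chr", ch)
  margin <- 500L
  mid_start <- max(span + margin + 1L, (L - mlen) %/% 2L)
  if (mid_start + mlen - 1L > L - span - margin || mid_start <= llen)
    stop("synthetic config infeasible: genes do not fit on chr", ch)
  fill1 <- mid_start - 1L - llen
  fill2 <- L - (mid_start + mlen - 1L) - rlen
  if (fill2 < 0)
    stop("synthetic config infeasible: genes do not fit on chr", ch)
  seq <- paste0(left$seq, .random_dna(fill1), mid$seq,
                .random_dna(fill2), right$seq)
  stopifnot(nchar(seq) == L)
  mid <- shift_block(mid, llen + fill1)
  right <- shift_block(right, llen + fill1 + mlen + fill2)
  placed <- rbind(left$placed, mid$placed, right$placed)
  if (nrow(placed) > 0) {
    d <- pmin(placed$start - 1L, L - placed$end)
    placed$location_class <- ifelse(d <= span, "subtelomeric",
                                    "interior")
  }
  list(seq = seq, placed = placed)
}
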