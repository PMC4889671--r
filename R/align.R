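.AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                  "F","P","S","T","W","Y","V","X","*")

.check_peptide <- function(x, what = "peptide") {
  bad <- setdiff(unique(strsplit(x, "")[[1]]), .AA_ALPHABET)
  if (length(bad) > 0)
    stop("invalid ", what, " symbol(s): ", paste(bad, collapse = ", "))
  invisible(x)
}

#' Local alignment of two peptides under affine gaps
#'
#' Maximal Smith--Waterman local-alignment score of `query` against
#' `subject` under the scheme's substitution matrix and affine gap
#' costs (a gap of length L costs `gap_open + L * gap_extend`). The
#' score is never negative; an empty query or subject scores 0.
#'
#' @param query,subject peptide strings over the 20 amino acids plus
#'   `X` (scores 0 against everything) and `*`.
#' @param scheme a [scoring_scheme()].
#' @return A list with `raw_score`, and `query_range`/`subject_range`
#'   (1-based inclusive `c(start, end)` of the optimal local alignment,
#'   `NA` when the score is 0).
#' @examples
#' local_align("MKT", "MKT")$raw_score  # 5 + 5 + 5
#' @export
local_align <- function(query, subject, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  query <- as.character(query); subject <- as.character(subject)
  .check_peptide(query, "query"); .check_peptide(subject, "subject")
  if (nchar(query) == 0L || nchar(subject) == 0L)
    return(list(raw_score = 0, query_range = c(NA, NA),
                subject_range = c(NA, NA)))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = scheme$substitution_matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  s <- Biostrings::score(pa)
  if (s <= 0)
    return(list(raw_score = 0, query_range = c(NA, NA),
                subject_range = c(NA, NA)))
  p <- Biostrings::pattern(pa); sj <- Biostrings::subject(pa)
  list(raw_score = s,
       query_range = c(IRanges::start(p), IRanges::end(p)),
       subject_range = c(IRanges::start(sj), IRanges::end(sj)))
}

#' Best translated-search hit of a protein against a genome
#'
#' Aligns `query` against all six reading frames of every contig and
#' returns the maximum-bit-score hit, or `NULL` when the best raw score
#' falls below the scheme's `raw_floor` (absent hits count as bit score
#' 0 downstream). Subject coordinates are 1-based inclusive nucleotide
#' positions on the forward strand; `frame` is in `{+1,+2,+3,-1,-2,-3}`.
#'
#' @param query a peptide string or [Biostrings::AAString]; when named
#'   (or `query_id` given) the id is carried into the hit.
#' @param genome a named [Biostrings::DNAStringSet] of contigs.
#' @param scheme a [scoring_scheme()].
#' @param query_id,genome_id identifiers stored in the hit record.
#' @param raw_floor override of the scheme's raw-score floor.
#' @return A one-row data.frame with columns `query_id`, `genome_id`,
#'   `contig_id`, `subject_start`, `subject_end`, `frame`, `raw_score`,
#'   `bit_score`, or `NULL` if no hit reaches the floor.
#' @export
best_genome_hit <- function(query, genome, scheme = scoring_scheme(),
                            query_id = NA_character_,
                            genome_id = NA_character_,
                            raw_floor = scheme$raw_floor,
                            frames = NULL) {
  stopifnot(length(genome) > 0)
  if (is.null(names(genome)))
    stop("genome contigs must be named")
  query <- as.character(query)
  .check_peptide(query, "query")
  if (is.null(frames)) frames <- genome_frames(genome)
  # score-only pass over all contigs and frames, then one full
  # alignment on the winner to recover coordinates
  best <- NULL
  for (contig in names(genome)) {
    clen <- length(genome[[contig]])
    for (fname in names(frames[[contig]])) {
      pep <- frames[[contig]][[fname]]
      if (nchar(pep) == 0L) next
      s <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(query), Biostrings::AAString(pep),
        type = "local",
        substitutionMatrix = scheme$substitution_matrix,
        gapOpening = scheme$gap_open,
        gapExtension = scheme$gap_extend, scoreOnly = TRUE)
      if (s <= 0) next
      if (is.null(best) || s > best$raw_score)
        best <- list(contig = contig, fname = fname, raw_score = s,
                     clen = clen)
    }
  }
  if (is.null(best) || best$raw_score < raw_floor) return(NULL)
  al <- local_align(query, frames[[best$contig]][[best$fname]], scheme)
  nt <- .frame_to_genomic(al$subject_range, best$fname, best$clen)
  best$frame <- .frame_int(best$fname)
  best$start <- nt[1]; best$end <- nt[2]
  best$raw_score <- al$raw_score
  data.frame(query_id = query_id, genome_id = genome_id,
             contig_id = best$contig,
             subject_start = best$start, subject_end = best$end,
             frame = best$frame, raw_score = best$raw_score,
             bit_score = raw_to_bitscore(best$raw_score, scheme),
             stringsAsFactors = FALSE)
}

.frame_int <- function(fname) as.integer(sub("\\+", "", fname))

#' Precompute six-frame translations of a genome
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @return list, one element per contig, each a named character
#'   vector of six frame translations (see [six_frame_translate()]).
#'   Pass to [best_genome_hit()] to avoid re-translating per query.
#' @export
genome_frames <- function(genome) {
  lapply(setNames(names(genome), names(genome)),
         function(ctg) six_frame_translate(genome[[ctg]]))
}

# map 1-based inclusive aa positions in a frame translation back to
# 1-based inclusive forward-strand nucleotide coordinates
.frame_to_genomic <- function(aa_range, fname, contig_len) {
  f <- abs(.frame_int(fname))
  nt_start <- f + 3L * (aa_range[1] - 1L)
  nt_end <- f + 3L * aa_range[2] - 1L
  if (.frame_int(fname) > 0) return(c(nt_start, nt_end))
  # reverse frames are coordinates on the reverse complement
  c(contig_len - nt_end + 1L, contig_len - nt_start + 1L)
}

#' Table of best bit scores for queries against a genome panel
#'
#' Runs [best_genome_hit()] for every query against every genome and
#' returns a long-format hit table; query/genome combinations with no
#' hit above the floor are recorded with bit score 0.
#'
#' @param queries a named [Biostrings::AAStringSet] (or named character
#'   vector) of protein queries; names must be unique.
#' @param panel a named list of [Biostrings::DNAStringSet] genomes.
#' @param scheme a [scoring_scheme()].
#' @return data.frame with columns `query_id`, `genome_id`,
#'   `bit_score` plus hit coordinates (`NA` where absent).
#' @export
panel_best_hits <- function(queries, panel, scheme = scoring_scheme()) {
  queries <- .as_named_character(queries, "queries")
  stopifnot(is.list(panel), !is.null(names(panel)))
  frames <- lapply(panel, genome_frames)
  rows <- list()
  for (q in names(queries)) {
    for (g in names(panel)) {
      hit <- best_genome_hit(queries[[q]], panel[[g]], scheme,
                             query_id = q, genome_id = g,
                             frames = frames[[g]])
      if (is.null(hit)) {
        hit <- data.frame(query_id = q, genome_id = g,
                          contig_id = NA_character_,
                          subject_start = NA_integer_,
                          subject_end = NA_integer_,
                          frame = NA_integer_, raw_score = NA_real_,
                          bit_score = 0, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- hit
    }
  }
  do.call(rbind, rows)
}

.as_named_character <- function(x, what) {
  x <- as.character(Biostrings::AAStringSet(x))
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop(what, " must have unique names")
  x
}

#' Read a 12-column tabular homology-search file
#'
#' Parses the standard blast-tabular dialect (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`,
#' tab-separated, no header). `sstart > send` encodes a minus-strand
#' hit; coordinates are normalized so `subject_start <= subject_end`
#' and `frame` is reported as `-1`/`+1` (the tabular format does not
#' carry the reading frame). Only the maximum-bit-score row per
#' query/subject pair is kept.
#'
#' @param path file path.
#' @param genome_id genome identifier to assign to all hits (defaults
#'   to the `sseqid` column, the usual single-genome convention).
#' @return data.frame of hits as in [best_genome_hit()].
#' @export
read_tabular_hits <- function(path, genome_id = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(data.frame(query_id = character(), genome_id = character(),
                      contig_id = character(),
                      subject_start = integer(), subject_end = integer(),
                      frame = integer(), raw_score = numeric(),
                      bit_score = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad) > 0)
    stop("malformed hit row (expected 12 tab-separated fields) at line ",
         bad[1])
  m <- do.call(rbind, parts)
  sstart <- as.integer(m[, 9]); send <- as.integer(m[, 10])
  bits <- as.numeric(m[, 12])
  if (anyNA(sstart) || anyNA(send) || anyNA(bits))
    stop("malformed numeric field in hit table at line ",
         which(is.na(sstart) | is.na(send) | is.na(bits))[1])
  hits <- data.frame(
    query_id = m[, 1],
    genome_id = if (is.null(genome_id)) m[, 2] else genome_id,
    contig_id = m[, 2],
    subject_start = pmin(sstart, send),
    subject_end = pmax(sstart, send),
    frame = ifelse(sstart > send, -1L, 1L),
    raw_score = NA_real_,
    bit_score = bits,
    stringsAsFactors = FALSE)
  # keep per query x genome maximum
  key <- paste(hits$query_id, hits$genome_id, sep = "\r")
  hits <- hits[order(key, -hits$bit_score), ]
  hits <- hits[!duplicated(paste(hits$query_id, hits$genome_id,
                                 sep = "\r")), ]
  rownames(hits) <- NULL
  hits
}

#' Write a hit table as tab-separated text
#'
#' @param hits data.frame as produced by [panel_best_hits()].
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
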