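#' Read a genome assembly from FASTA
#'
#' @param path FASTA file of contigs/chromosomes.
#' @return named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome assembly to FASTA
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write every strain of a synthetic panel to FASTA
#'
#' @param sp a `synthetic_panel` (see [generate_strain_panel()]).
#' @param dir output directory (created if needed); one
#'   `<strain>.fasta` per strain plus `truth.tsv` with the planted
#'   placements.
#' @return `dir`, invisibly.
#' @export
write_strain_panel <- function(sp, dir) {
  stopifnot(inherits(sp, "synthetic_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in names(sp$panel))
    write_genome_fasta(sp$panel[[st]],
                       file.path(dir, paste0(st, ".fasta")))
  utils::write.table(sp$truth$placements, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write an annotation set as GFF3
#'
#' Gene models become `gene` features (`pseudogene` for pseudogene
#' status) with `ID`, `status`, and `source_track` attributes; tRNA
#' models become `tRNA` features.
#'
#' @param set an [annotation_set()].
#' @param path output file.
#' @export
write_annotation_gff3 <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  m <- set$models
  type <- ifelse(m$type == "tRNA", "tRNA",
                 ifelse(m$status == "pseudogene", "pseudogene", "gene"))
  gr <- GenomicRanges::GRanges(
    m$contig, IRanges::IRanges(m$start, m$end), strand = m$strand,
    type = type, ID = m$id, status = m$status, source_track = m$source)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an annotation set from GFF3
#'
#' Inverse of [write_annotation_gff3()]; also accepts generic GFF3
#' with `gene`/`pseudogene`/`tRNA` features, defaulting `status` from
#' the feature type when no `status` attribute is present.
#'
#' @param path GFF3 file.
#' @param genome_id assembly id to record on the set.
#' @param provenance track label.
#' @return an [annotation_set()].
#' @export
read_annotation_gff3 <- function(path, genome_id,
                                 provenance = basename(path)) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  keep <- type %in% c("gene", "pseudogene", "tRNA")
  gr <- gr[keep]; mc <- mc[keep, , drop = FALSE]
  type <- type[keep]
  status <- if ("status" %in% names(mc)) as.character(mc$status)
            else ifelse(type == "pseudogene", "pseudogene",
                        "valid_coding")
  status[is.na(status)] <- ifelse(type[is.na(status)] == "pseudogene",
                                  "pseudogene", "valid_coding")
  src <- if ("source_track" %in% names(mc))
    as.character(mc$source_track) else provenance
  models <- gene_models(
    id = as.character(mc$ID),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = IRanges::start(gr), end = IRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    status = status,
    type = ifelse(type == "tRNA", "tRNA", "gene"),
    source = src)
  annotation_set(genome_id, models, provenance)
}

#' Read/write the evidence tables as TSV
#'
#' Plain tab-separated round-trips for the transcript-alignment,
#' count, and peptide tables.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return the data.frame (readers) or `path` invisibly (writer).
#' @export
write_evidence_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence_tsv
#' @export
read_evidence_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
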