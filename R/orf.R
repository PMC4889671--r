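.STOPS <- c("TAA", "TAG", "TGA")

#' Construct a table of gene models
#'
#' Gene models are plain data.frames, one row per feature, with
#' columns `id`, `contig`, `start`, `end` (1-based inclusive genomic
#' coordinates), `strand` (`+`/`-`), `status` (`valid_coding`,
#' `pseudogene`, `dubious`, `invalid`), `type` (`gene` or `tRNA`), and
#' `source` (annotator track label).
#'
#' @param id,contig,start,end,strand,status,type,source vectors,
#'   recycled to a common length.
#' @return data.frame of gene models.
#' @export
gene_models <- function(id, contig, start, end, strand,
                        status = "valid_coding", type = "gene",
                        source = "unknown") {
  n <- length(id)
  df <- data.frame(id = as.character(id),
                   contig = rep_len(as.character(contig), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   strand = rep_len(as.character(strand), n),
                   status = rep_len(as.character(status), n),
                   type = rep_len(as.character(type), n),
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$start <= df$end), all(df$strand %in% c("+", "-")))
  df
}

#' Bundle gene models into an annotation set
#'
#' @param genome_id id of the assembly the models annotate.
#' @param models a [gene_models()] data.frame; ids must be unique;
#'   models are sorted by (contig, start).
#' @param provenance free-text label for the annotator track.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(genome_id, models, provenance = "unknown") {
  if (anyDuplicated(models$id))
    stop("duplicate gene model ids")
  models <- models[order(models$contig, models$start, models$end), ,
                   drop = FALSE]
  rownames(models) <- NULL
  structure(list(genome_id = genome_id, models = models,
                 provenance = provenance),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set '", x$provenance, "' on genome '", x$genome_id,
      "': ", nrow(x$models), " models\n", sep = "")
  invisible(x)
}

# oriented nucleotide sequence of a model (5'->3' of the gene)
.model_seq <- function(model, genome) {
  contig <- genome[[model$contig]]
  if (is.null(contig)) stop("contig '", model$contig, "' not in genome")
  if (model$start < 1 || model$end > length(contig))
    stop("model '", model$id, "' outside contig bounds")
  s <- Biostrings::subseq(contig, model$start, model$end)
  if (model$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

.codons <- function(seq) {
  n <- nchar(seq) %/% 3
  if (n == 0) return(character(0))
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

#' Validate the open reading frame of a gene model
#'
#' A model is `valid_coding` iff its oriented sequence starts with
#' `ATG`, ends with a stop codon, contains no internal in-frame stop,
#' and has length divisible by 3. Otherwise the defect list enumerates
#' what failed: `no_start`, `no_stop`, `internal_stop`, `frame_length`.
#'
#' @param model one-row data.frame (see [gene_models()]).
#' @param genome named [Biostrings::DNAStringSet].
#' @return list with `status` (`"valid_coding"` or `"invalid"`) and
#'   `defects` (character vector, empty when valid).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "ATGAAATAA"))
#' m <- gene_models("g1", "chr", 1, 9, "+")
#' validate_orf(m, g)$status
#' @export
validate_orf <- function(model, genome) {
  model <- as.list(model[1, , drop = FALSE])
  seq <- .model_seq(model, genome)
  defects <- character(0)
  n <- nchar(seq)
  if (n %% 3 != 0) defects <- c(defects, "frame_length")
  if (n < 3 || substr(seq, 1, 3) != "ATG")
    defects <- c(defects, "no_start")
  if (n < 3 || !substr(seq, n - 2, n) %in% .STOPS)
    defects <- c(defects, "no_stop")
  cod <- .codons(seq)
  internal <- if (n %% 3 == 0) cod[-c(1, length(cod))] else cod[-1]
  if (any(internal %in% .STOPS))
    defects <- c(defects, "internal_stop")
  list(status = if (length(defects) == 0) "valid_coding" else "invalid",
       defects = defects)
}

#' Correct a defective gene model by in-frame boundary search
#'
#' Searches within `window` bp of the annotated boundaries, in the
#' annotated frame, for the nearest repair that yields a valid ORF:
#' candidate 5' starts are in-frame `ATG` codons within the window
#' (extending or shortening the model), and for each start the 3' end
#' is the first in-frame stop codon (which must lie within `window` of
#' the annotated end). Among valid repairs the one minimizing the
#' total boundary displacement is returned; ties are broken toward
#' extension. A model that already validates is returned unchanged,
#' and a model with no repair in range is returned unchanged with
#' `uncorrectable = TRUE`.
#'
#' @param model one-row gene-model data.frame.
#' @param genome named [Biostrings::DNAStringSet].
#' @param window search radius in bp (whole codons are explored).
#' @return list with `model` (possibly corrected one-row data.frame),
#'   `corrected` (logical), `uncorrectable` (logical), and
#'   `correction_log` (character description of applied edits, `""`
#'   when none).
#' @export
correct_orf <- function(model, genome, window = 300) {
  model <- model[1, , drop = FALSE]
  v <- validate_orf(model, genome)
  if (v$status == "valid_coding")
    return(list(model = model, corrected = FALSE,
                uncorrectable = FALSE, correction_log = ""))
  contig <- genome[[model$contig]]
  L <- length(contig)
  minus <- model$strand == "-"
  # normalize to gene orientation: work on the reverse complement for
  # minus-strand models, with coordinates flipped
  if (minus) {
    seq <- as.character(Biostrings::reverseComplement(contig))
    s0 <- L - model$end + 1L; e0 <- L - model$start + 1L
  } else {
    seq <- as.character(contig)
    s0 <- model$start; e0 <- model$end
  }
  best <- NULL
  k <- as.integer(window %/% 3)
  # candidate start shifts ordered by |shift|, extension (negative) first
  shifts <- 3L * order_by_displacement(k)
  for (d in shifts) {
    s1 <- s0 + d
    if (s1 < 1L || s1 + 2L > nchar(seq)) next
    if (substr(seq, s1, s1 + 2L) != "ATG") next
    e1 <- .first_stop_end(seq, s1, e0 + window)
    if (is.na(e1) || abs(e1 - e0) > window) next
    disp <- abs(d) + abs(e1 - e0)
    span <- e1 - s1
    cand <- list(s = s1, e = e1, disp = disp, span = span, d = d)
    if (is.null(best) || disp < best$disp ||
        (disp == best$disp && span > best$span)) best <- cand
  }
  if (is.null(best))
    return(list(model = model, corrected = FALSE,
                uncorrectable = TRUE, correction_log = ""))
  if (minus) {
    new_start <- L - best$e + 1L; new_end <- L - best$s + 1L
  } else {
    new_start <- best$s; new_end <- best$e
  }
  log <- sprintf("start:%+d;end:%+d", best$d, best$e - e0)
  out <- model
  out$start <- new_start; out$end <- new_end
  out$status <- "valid_coding"
  list(model = out, corrected = TRUE, uncorrectable = FALSE,
       correction_log = log)
}

# 0, -3... no: returns c(0, -1, 1, -2, 2, ...) up to k (codon shifts);
# negative = 5' extension, tried first at equal magnitude
order_by_displacement <- function(k) {
  if (k == 0) return(0L)
  out <- integer(2 * k + 1)
  out[1] <- 0L
  idx <- 2L
  for (i in seq_len(k)) {
    out[idx] <- -i; out[idx + 1L] <- i
    idx <- idx + 2L
  }
  out
}

# end position (inclusive) of the first in-frame stop codon at or
# after position `from`, scanning no further than `limit`; NA if none
.first_stop_end <- function(seq, from, limit) {
  n <- min(nchar(seq), limit)
  p <- from
  while (p + 2L <= n) {
    if (substr(seq, p, p + 2L) %in% .STOPS) return(p + 2L)
    p <- p + 3L
  }
  NA_integer_
}
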