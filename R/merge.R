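#' Merge two annotation tracks into one call set
#'
#' Reconciles two annotator tracks for the same genome. Gene models
#' are paired across tracks by reciprocal interval overlap (> 50% of
#' both members, same contig and strand). Every defective model is
#' first run through [correct_orf()]; within a pair the member that
#' validates is kept; when both do, a member that validated without
#' repair outranks a repaired one, and track A wins ties. Unpaired valid
#' models from either track are kept. Models that remain defective
#' after correction are retained with status `pseudogene` (one model
#' per locus; when neither pair member validates, the longer-spanning
#' member is kept, since annotator errors truncate loci). `dubious` input labels are carried through. `tRNA`
#' rows from both tracks are passed through untouched (deduplicated on
#' identical coordinates).
#'
#' @param track_a,track_b [annotation_set()] objects on the same
#'   genome.
#' @param genome named [Biostrings::DNAStringSet].
#' @param window correction search radius in bp, see [correct_orf()].
#' @param min_overlap reciprocal overlap fraction for pairing.
#' @return list with `merged` (an `annotation_set`, provenance
#'   `"merged"`) and `report` (one-row data.frame: `corrected_A`,
#'   `corrected_B`, `kept`, `pseudogenes`, `uncorrectable`).
#' @export
merge_annotation_sets <- function(track_a, track_b, genome,
                                  window = 300, min_overlap = 0.5) {
  stopifnot(inherits(track_a, "annotation_set"),
            inherits(track_b, "annotation_set"))
  if (!identical(track_a$genome_id, track_b$genome_id))
    stop("annotation tracks are on different genomes: '",
         track_a$genome_id, "' vs '", track_b$genome_id, "'")

  prep <- function(set, label) {
    m <- set$models
    m$track <- label
    genes <- m[m$type != "tRNA", , drop = FALSE]
    trna <- m[m$type == "tRNA", , drop = FALSE]
    genes$ok <- FALSE
    genes$was_corrected <- FALSE
    genes$correction_log <- ""
    for (i in seq_len(nrow(genes))) {
      res <- correct_orf(genes[i, ], genome, window)
      genes$ok[i] <- !res$uncorrectable &&
        validate_orf(res$model, genome)$status == "valid_coding"
      if (res$corrected) {
        genes$start[i] <- res$model$start
        genes$end[i] <- res$model$end
        genes$was_corrected[i] <- TRUE
        genes$correction_log[i] <- res$correction_log
      }
    }
    list(genes = genes, trna = trna)
  }
  a <- prep(track_a, "trackA")
  b <- prep(track_b, "trackB")

  pairs <- .reciprocal_pairs(a$genes, b$genes, min_overlap)
  keep <- list()
  take <- function(row, status_override = NULL) {
    r <- row
    if (!is.null(status_override)) r$status <- status_override
    keep[[length(keep) + 1L]] <<- r
  }
  resolve_status <- function(row) {
    # carry dubious labels; everything else that validates is coding
    if (row$status == "dubious") "dubious" else "valid_coding"
  }
  used_a <- rep(FALSE, nrow(a$genes))
  used_b <- rep(FALSE, nrow(b$genes))
  n_uncorrectable <- 0L
  for (i in seq_len(nrow(pairs))) {
    ia <- pairs$ia[i]; ib <- pairs$ib[i]
    used_a[ia] <- TRUE; used_b[ib] <- TRUE
    ra <- a$genes[ia, ]; rb <- b$genes[ib, ]
    if (ra$ok && rb$ok) {
      # both validate: prefer the member that needed no repair (it is
      # the annotator's direct call), then track A
      pick <- if (ra$was_corrected && !rb$was_corrected) rb else ra
      take(pick, resolve_status(pick))
    } else if (ra$ok) {
      take(ra, resolve_status(ra))
    } else if (rb$ok) {
      take(rb, resolve_status(rb))
    } else {
      # neither validates: retain the longer-spanning member as the
      # pseudogene call (annotator errors truncate, so the maximal
      # extent is the better estimate of the disrupted locus)
      n_uncorrectable <- n_uncorrectable + 1L
      wa <- ra$end - ra$start; wb <- rb$end - rb$start
      take(if (wb > wa) rb else ra, "pseudogene")
    }
  }
  for (ia in which(!used_a)) {
    ra <- a$genes[ia, ]
    if (ra$ok) take(ra, resolve_status(ra))
    else { n_uncorrectable <- n_uncorrectable + 1L; take(ra, "pseudogene") }
  }
  for (ib in which(!used_b)) {
    rb <- b$genes[ib, ]
    if (rb$ok) take(rb, resolve_status(rb))
    else { n_uncorrectable <- n_uncorrectable + 1L; take(rb, "pseudogene") }
  }

  merged <- do.call(rbind, keep)
  merged$source <- merged$track
  trna <- rbind(a$trna, b$trna)
  if (nrow(trna) > 0) {
    trna$source <- trna$track
    trna <- trna[!duplicated(trna[, c("contig", "start", "end", "strand")]), ,
                 drop = FALSE]
  }
  all_models <- rbind(merged, trna)
  drop_cols <- c("track", "ok", "was_corrected")
  all_models <- all_models[, setdiff(names(all_models), drop_cols),
                           drop = FALSE]
  # pairing keeps one model per locus, so ids are unique unless the
  # two tracks reuse an id for non-overlapping loci
  if (anyDuplicated(all_models$id)) {
    dup <- duplicated(all_models$id)
    all_models$id[dup] <- paste0(all_models$id[dup], "_",
                                 all_models$source[dup])
  }
  report <- data.frame(
    corrected_A = sum(a$genes$was_corrected),
    corrected_B = sum(b$genes$was_corrected),
    kept = nrow(merged),
    pseudogenes = sum(merged$status == "pseudogene"),
    uncorrectable = n_uncorrectable)
  list(merged = annotation_set(track_a$genome_id, all_models, "merged"),
       report = report)
}

# reciprocal >min_overlap same-strand pairs between two model tables;
# greedy one-to-one by descending overlap width
.reciprocal_pairs <- function(ga, gb, min_overlap) {
  empty <- data.frame(ia = integer(), ib = integer())
  if (nrow(ga) == 0 || nrow(gb) == 0) return(empty)
  gra <- GenomicRanges::GRanges(ga$contig, IRanges::IRanges(ga$start, ga$end),
                                strand = ga$strand)
  grb <- GenomicRanges::GRanges(gb$contig, IRanges::IRanges(gb$start, gb$end),
                                strand = gb$strand)
  ov <- GenomicRanges::findOverlaps(gra, grb)
  if (length(ov) == 0) return(empty)
  ia <- S4Vectors::queryHits(ov); ib <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(GenomicRanges::pintersect(gra[ia], grb[ib]))
  frac_a <- w / (ga$end[ia] - ga$start[ia] + 1)
  fraz_b <- w / (gb$end[ib] - gb$start[ib] + 1)
  keep <- frac_a > min_overlap & fraz_b > min_overlap
  ia <- ia[keep]; ib <- ib[keep]; w <- w[keep]
  o <- order(-w)
  ia <- ia[o]; ib <- ib[o]
  sel_a <- logical(0); sel_b <- logical(0)
  out_ia <- integer(0); out_ib <- integer(0)
  seen_a <- rep(FALSE, max(ia, 0)); seen_b <- rep(FALSE, max(ib, 0))
  for (k in seq_along(ia)) {
    if (length(ia) == 0) break
    if (!seen_a[ia[k]] && !seen_b[ib[k]]) {
      seen_a[ia[k]] <- TRUE; seen_b[ib[k]] <- TRUE
      out_ia <- c(out_ia, ia[k]); out_ib <- c(out_ib, ib[k])
    }
  }
  data.frame(ia = out_ia, ib = out_ib)
}

#' Summarize an annotation set by status
#'
#' @param set an [annotation_set()].
#' @return one-row data.frame with counts `valid_coding`,
#'   `pseudogene`, `dubious`, `invalid`, `trna`, and `total`; the
#'   status counts partition the gene models.
#' @export
summarize_counts <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  m <- set$models
  genes <- m[m$type != "tRNA", , drop = FALSE]
  data.frame(
    valid_coding = sum(genes$status == "valid_coding"),
    pseudogene = sum(genes$status == "pseudogene"),
    dubious = sum(genes$status == "dubious"),
    invalid = sum(genes$status == "invalid"),
    trna = sum(m$type == "tRNA"),
    total = nrow(m))
}
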