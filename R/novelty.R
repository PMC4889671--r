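#' Novelty Metric for one query gene in one genome
#'
#' For query gene q and genome G, with best-hit bit scores B(q, .)
#' over a strain panel that includes the reference genome,
#'
#'   NM(q, G) = (B(q, G) - B(q, ref)) / max over the panel of B(q, .)
#'
#' A genome carrying a close homolog of a non-reference gene scores
#' near 1; a genome whose best hit is no better than the reference's
#' scores near 0. Values for the reference genome itself are 0 by
#' construction. When no genome in the panel has a hit (the maximum is
#' 0) the metric is undefined and `NA` is returned. Genomes absent
#' from the hit table for a query count as bit score 0.
#'
#' @param query_id query gene id.
#' @param genome_id genome to score; must be one of the panel genomes.
#' @param hits data.frame with columns `query_id`, `genome_id`,
#'   `bit_score` covering the panel (e.g. from [panel_best_hits()] or
#'   [read_tabular_hits()]).
#' @param reference_id id of the reference genome in the panel.
#' @return A single numeric value in `[-1, 1]`, or `NA`.
#' @export
novelty_metric <- function(query_id, genome_id, hits, reference_id) {
  stopifnot(all(c("query_id", "genome_id", "bit_score") %in% names(hits)))
  panel <- unique(hits$genome_id)
  if (!reference_id %in% panel)
    stop("reference genome '", reference_id, "' not in panel")
  if (!genome_id %in% panel)
    stop("genome '", genome_id, "' not in panel")
  h <- hits[hits$query_id == query_id, ]
  b <- function(g) {
    v <- h$bit_score[h$genome_id == g]
    if (length(v) == 0) 0 else max(v)
  }
  denom <- if (nrow(h) == 0) 0 else max(h$bit_score)
  if (denom <= 0) return(NA_real_)
  (b(genome_id) - b(reference_id)) / denom
}

#' Build the query-by-strain Novelty Metric matrix
#'
#' Rows are query genes, columns are the genomes being searched
#' (matching the heatmap orientation used for presence/absence
#' figures). Cells are [novelty_metric()] values; a cell is `NA` iff
#' the per-query panel maximum bit score is 0.
#'
#' @param hits hit table covering all query/genome pairs (see
#'   [novelty_metric()]); pairs missing from the table score 0.
#' @param reference_id reference genome id (its column is all zero
#'   wherever defined).
#' @param query_ids,genome_ids optional explicit row/column orderings;
#'   default: order of appearance in `hits`.
#' @return An object of class `novelty_matrix`: a list with `values`
#'   (numeric matrix), `query_ids`, `genome_ids`, `reference_id`, and
#'   `denominator` (per-query panel maximum bit score).
#' @export
build_novelty_matrix <- function(hits, reference_id,
                                 query_ids = NULL, genome_ids = NULL) {
  if (is.null(query_ids)) query_ids <- unique(hits$query_id)
  if (is.null(genome_ids)) genome_ids <- unique(hits$genome_id)
  if (anyDuplicated(query_ids))
    stop("duplicate query ids")
  if (!reference_id %in% genome_ids)
    stop("reference genome '", reference_id, "' not in panel")
  bit <- matrix(0, length(query_ids), length(genome_ids),
                dimnames = list(query_ids, genome_ids))
  for (i in seq_len(nrow(hits))) {
    q <- hits$query_id[i]; g <- hits$genome_id[i]
    if (q %in% query_ids && g %in% genome_ids)
      bit[q, g] <- max(bit[q, g], hits$bit_score[i])
  }
  denom <- apply(bit, 1, max)
  vals <- (bit - bit[, reference_id]) / ifelse(denom > 0, denom, NA)
  vals[denom <= 0, ] <- NA_real_
  structure(list(values = vals, query_ids = query_ids,
                 genome_ids = genome_ids, reference_id = reference_id,
                 denominator = denom),
            class = "novelty_matrix")
}

#' @export
print.novelty_matrix <- function(x, ...) {
  cat("novelty_matrix: ", length(x$query_ids), " queries x ",
      length(x$genome_ids), " genomes (reference: ", x$reference_id,
      ")\n", sep = "")
  print(utils::head(x$values, 10))
  invisible(x)
}

#' Compute a Novelty Metric matrix directly from sequences
#'
#' Convenience pipeline: runs the internal translated search for every
#' query against every genome in the panel, then assembles the matrix.
#'
#' @param queries named [Biostrings::AAStringSet] of protein queries.
#' @param panel named list of [Biostrings::DNAStringSet] genomes,
#'   including the reference.
#' @param reference_id name of the reference genome in `panel`.
#' @param scheme a [scoring_scheme()].
#' @return A `novelty_matrix` (see [build_novelty_matrix()]).
#' @export
compute_novelty <- function(queries, panel, reference_id,
                            scheme = scoring_scheme()) {
  if (!reference_id %in% names(panel))
    stop("reference genome '", reference_id, "' not in panel")
  hits <- panel_best_hits(queries, panel, scheme)
  build_novelty_matrix(hits, reference_id)
}

#' Cluster panel strains by gene content
#'
#' Unsupervised average-linkage hierarchical clustering of the strain
#' columns of a Novelty Metric matrix, on Euclidean distance with `NA`
#' treated as 0. Columns are sorted lexicographically before
#' clustering so the leaf order is deterministic and invariant to the
#' input column order.
#'
#' @param nm a `novelty_matrix`.
#' @return A list with `order` (genome ids in dendrogram leaf order)
#'   and `hclust` (the [stats::hclust] tree, `NULL` for fewer than two
#'   strains).
#' @export
cluster_strains <- function(nm) {
  stopifnot(inherits(nm, "novelty_matrix"))
  ids <- sort(nm$genome_ids)
  if (length(ids) < 2)
    return(list(order = nm$genome_ids, hclust = NULL))
  v <- nm$values[, ids, drop = FALSE]
  v[is.na(v)] <- 0
  hc <- stats::hclust(stats::dist(t(v), method = "euclidean"),
                      method = "average")
  list(order = ids[hc$order], hclust = hc)
}

#' Export a Novelty Metric matrix as a heatmap-ready TSV
#'
#' Wide tab-separated table, one row per query gene, one column per
#' strain, `NA` written literally. Column order follows `ordering`
#' when supplied (e.g. the result of [cluster_strains()]).
#'
#' @param nm a `novelty_matrix`.
#' @param path output file.
#' @param ordering optional character vector of genome ids.
#' @return `path`, invisibly.
#' @export
export_heatmap_table <- function(nm, path, ordering = NULL) {
  stopifnot(inherits(nm, "novelty_matrix"))
  v <- nm$values
  if (!is.null(ordering)) {
    stopifnot(setequal(ordering, nm$genome_ids))
    v <- v[, ordering, drop = FALSE]
  }
  df <- data.frame(query_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a heatmap TSV as a plain matrix
#'
#' @param path file written by [export_heatmap_table()].
#' @return numeric matrix with query ids as rownames.
#' @export
read_heatmap_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
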