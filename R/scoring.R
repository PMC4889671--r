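#' Scoring scheme for translated homology search
#'
#' Bundles the substitution matrix, affine gap penalties, and the
#' Karlin--Altschul parameters used to convert raw local-alignment
#' scores to bit scores. Defaults are the standard values for gapped
#' protein search: BLOSUM62, gap existence 11, gap extension 1,
#' lambda = 0.267 nats per raw-score unit, K = 0.041.
#'
#' The matrix is taken from [Biostrings::BLOSUM62] with one
#' modification: `X` (unknown residue, produced when a codon contains
#' `N`) scores 0 against every letter, so ambiguous positions neither
#' reward nor penalize an alignment. Stop symbols (`*`) keep their
#' BLOSUM62 penalties so alignments extending through an in-frame stop
#' are strongly discouraged.
#'
#' @param gap_open positive integer, gap existence cost.
#' @param gap_extend positive integer, per-residue gap extension cost.
#'   A gap of length L costs `gap_open + L * gap_extend`.
#' @param lambda Karlin--Altschul scale, nats per raw-score unit.
#' @param karlin_k Karlin--Altschul K (dimensionless).
#' @param raw_floor minimum raw score for [best_genome_hit()] to report
#'   a hit; hits below the floor are treated as absent (bit score 0 in
#'   downstream arithmetic).
#' @return An object of class `scoring_scheme`.
#' @examples
#' sc <- scoring_scheme()
#' raw_to_bitscore(15, sc)
#' @export
scoring_scheme <- function(gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, karlin_k = 0.041,
                           raw_floor = 35) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, karlin_k > 0)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  mat <- env$BLOSUM62
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  stopifnot(isSymmetric(unname(mat)))
  structure(
    list(substitution_matrix = mat, gap_open = as.integer(gap_open),
         gap_extend = as.integer(gap_extend), lambda = lambda,
         karlin_k = karlin_k, raw_floor = raw_floor),
    class = "scoring_scheme")
}

#' Convert a raw alignment score to a bit score
#'
#' `bits = (lambda * raw - log(K)) / log(2)`, the Karlin--Altschul
#' normalization that makes scores comparable across scoring systems.
#' Monotone increasing in `raw`.
#'
#' @param raw numeric vector of raw scores in substitution-matrix units.
#' @param scheme a [scoring_scheme()].
#' @return numeric vector of bit scores.
#' @export
raw_to_bitscore <- function(raw, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  (scheme$lambda * raw - log(scheme$karlin_k)) / log(2)
}
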