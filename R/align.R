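# Pairwise protein alignment layer. All scoring uses BLOSUM62 with affine
# gaps costing 11 to open plus 1 per gap position (BLAST's default protein
# scoring), so raw scores are on the scale the Karlin-Altschul constants
# below were fitted for.

.pkg_env <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#' @return Integer matrix including the X and * rows.
#' @export
blosum62 <- function() {
  if (is.null(.pkg_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_env$blosum62 <- e$BLOSUM62
  }
  .pkg_env$blosum62
}

.check_protein <- function(x, what = "sequence") {
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX*]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-amino-acid character '%s' in %s at position %d",
                 substr(x[i], bad[i], bad[i]), what, bad[i]))
  }
  invisible(x)
}

#' Local (Smith-Waterman) alignment of protein queries against a subject
#'
#' @param patterns Character vector or \code{AAStringSet} of queries.
#' @param subject Single subject sequence (character or \code{AAString}).
#' @return Data.frame with raw score and 1-based pattern/subject
#'   start/end coordinates of the optimal local alignment, one row per query.
#' @export
align_local <- function(patterns, subject) {
  if (is.character(patterns)) patterns <- Biostrings::AAStringSet(patterns)
  if (is.character(subject)) subject <- Biostrings::AAString(subject)
  pa <- Biostrings::pairwiseAlignment(patterns, subject,
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 11, gapExtension = 1,
                                      type = "local")
  pat <- Biostrings::pattern(pa)
  sub <- Biostrings::subject(pa)
  data.frame(score = Biostrings::score(pa),
             p_start = IRanges::start(pat), p_end = IRanges::end(pat),
             s_start = IRanges::start(sub), s_end = IRanges::end(sub))
}

#' Global (Needleman-Wunsch) alignment score of two proteins
#' @param a,b Protein sequences (character).
#' @return Raw alignment score.
#' @export
align_global_score <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 11, gapExtension = 1,
                                      type = "global")
  Biostrings::score(pa)
}

#' Global pairwise identity between two proteins
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 11, extend 1);
#' identity is the number of identical aligned residue pairs divided by the
#' full alignment length including gap columns (terminal gaps count), i.e.
#' gaps are scored as mismatches, the convention of pairwise sequence
#' demarcation plots.
#'
#' @param a,b Non-empty protein sequences (character).
#' @return Identity in [0, 1].
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  .check_protein(c(a, b))
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 11, gapExtension = 1,
                                      type = "global")
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  n <- nchar(ap)
  pm <- strsplit(ap, "")[[1]]
  sm <- strsplit(as_, "")[[1]]
  sum(pm == sm & pm != "-") / n
}

#' Karlin-Altschul bitscore and E-value
#'
#' Converts a raw gapped BLOSUM62 (11/1) local-alignment score into a
#' bitscore S' = (lambda * S - ln K) / ln 2 and an E-value E = m * n * 2^-S',
#' using the gapped constants lambda = 0.267, K = 0.041.
#'
#' @param raw_score Raw alignment score(s).
#' @param m Query length (residues).
#' @param n Search-space length (residues).
#' @param lambda,K Karlin-Altschul constants.
#' @return list(bitscore, evalue), vectorized over raw_score.
#' @export
karlin_altschul_evalue <- function(raw_score, m, n, lambda = 0.267, K = 0.041) {
  if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive")
  bit <- (lambda * raw_score - log(K)) / log(2)
  list(bitscore = bit, evalue = as.numeric(m) * as.numeric(n) * 2^(-bit))
}
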