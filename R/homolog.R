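# The WhiB/Lsr2 detection pipeline: translated (six-frame) local search of
# protein queries against genomes, merging of overlapping hit loci, locus
# extension, ORF translation, and a reciprocal best-hit filter against the
# query library. The alignment engine is Smith-Waterman (BLOSUM62, affine
# 11/1) with Karlin-Altschul E-values, so the E-value thresholds carry
# BLAST-like semantics without an external binary; an adapter for real BLAST
# tabular output can be layered on the same locus operations.

# translate the 6 reading frames; returns list of list(frame, offset, aa)
.six_frames <- function(genome_chr) {
  L <- nchar(genome_chr)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome_chr)))
  out <- list()
  for (f in 1:3) {
    out[[length(out) + 1L]] <- list(frame = f, aa = .translate_frame(substr(genome_chr, f, L)))
    out[[length(out) + 1L]] <- list(frame = -f, aa = .translate_frame(substr(rc, f, L)))
  }
  out
}

# map 1-based aa positions [p1,p2] in frame f to 0-based half-open genome nt
.frame_to_genome <- function(f, p1, p2, L) {
  off <- abs(f) - 1L
  s <- off + 3L * (p1 - 1L)
  e <- off + 3L * p2
  if (f > 0) c(s, e) else c(L - e, L - s)
}

#' Translated search of protein queries against a genome
#'
#' Aligns every query against all six reading frames of the genome by local
#' Smith-Waterman (BLOSUM62, gap open 11, extend 1). Raw scores are converted
#' to bitscores and E-values with the Karlin-Altschul formula, using the
#' query length times the total translated search space (all six frames,
#' about 2 x genome length residues). Hits with E-value <= \code{evalue_max}
#' are reported with frame-aware genome coordinates. After each significant
#' hit the matched frame region is masked and the query re-aligned, so
#' multiple copies of a gene in the same frame are all recovered.
#'
#' @param genome Genome sequence (\code{DNAString} or character).
#' @param queries Named \code{AAStringSet} (or named character vector).
#' @param evalue_max E-value threshold (1e-5 in the survey).
#' @param max_hits_per_frame Cap on masking iterations per query x frame.
#' @return Data.frame: query_id, frame, start, end (0-based half-open genome
#'   coords), strand, raw_score, bitscore, evalue.
#' @export
translated_search <- function(genome, queries, evalue_max = 1e-5,
                              max_hits_per_frame = 8L) {
  genome <- toupper(as.character(genome))
  L <- nchar(genome)
  if (is.character(queries)) queries <- Biostrings::AAStringSet(queries)
  if (length(queries) == 0L) stop("queries must be non-empty")
  qchr <- as.character(queries)
  .check_protein(qchr, "query")
  n_space <- sum(vapply(1:3, function(f) (L - f + 1L) %/% 3L, integer(1))) * 2L
  frames <- .six_frames(genome)
  rows <- list()
  for (fr in frames) {
    if (!nzchar(fr$aa)) next
    aln <- align_local(qchr, fr$aa)
    for (qi in seq_along(qchr)) {
      sub_aa <- fr$aa
      a <- aln[qi, ]
      for (iter in seq_len(max_hits_per_frame)) {
        ka <- karlin_altschul_evalue(a$score, nchar(qchr[qi]), n_space)
        if (!is.finite(ka$evalue) || ka$evalue > evalue_max || a$s_end < a$s_start) break
        gcoord <- .frame_to_genome(fr$frame, a$s_start, a$s_end, L)
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = names(queries)[qi], frame = fr$frame,
          start = gcoord[1L], end = gcoord[2L],
          strand = if (fr$frame > 0) "+" else "-",
          raw_score = a$score, bitscore = ka$bitscore, evalue = ka$evalue,
          stringsAsFactors = FALSE)
        # mask the hit (stop symbols score -4 against everything) and re-align
        substr(sub_aa, a$s_start, a$s_end) <-
          strrep("*", a$s_end - a$s_start + 1L)
        a <- align_local(qchr[qi], sub_aa)[1L, ]
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(query_id = character(), frame = integer(), start = integer(),
                      end = integer(), strand = character(), raw_score = numeric(),
                      bitscore = numeric(), evalue = numeric(), stringsAsFactors = FALSE)
  }
  out[order(out$start, out$evalue), , drop = FALSE]
}

#' Reciprocal best-hit filter of candidate proteins against a query library
#'
#' Aligns each candidate ORF protein locally (Smith-Waterman, BLOSUM62, 11/1)
#' to every library protein. The best hit is the lowest E-value, ties broken
#' by higher raw score then lexicographic query id. A candidate passes if its
#' best E-value is at most \code{evalue_max}; the best-scoring passing
#' candidate is flagged as the locus protein (at most one per locus).
#'
#' @param candidates Character vector (or \code{AAStringSet}) of ORF proteins.
#' @param library Named \code{AAStringSet} of family library proteins.
#' @param evalue_max E-value threshold (1e-5 in the survey).
#' @return Data.frame, one row per candidate: best_query, best_identity
#'   (global identity to the best query), best_evalue, raw_score, passed,
#'   retained (TRUE for the single retained protein).
#' @export
reciprocal_filter <- function(candidates, library, evalue_max = 1e-5) {
  if (length(library) == 0L) stop("library must be non-empty")
  if (is.character(library)) library <- Biostrings::AAStringSet(library)
  cand <- if (is.character(candidates)) candidates else as.character(candidates)
  lib <- as.character(library)
  lib_ids <- names(library)
  res <- lapply(cand, function(cc) {
    aln <- align_local(lib, cc)
    ka <- karlin_altschul_evalue(aln$score, nchar(cc), nchar(lib))
    ord <- order(ka$evalue, -aln$score, lib_ids)
    b <- ord[1L]
    data.frame(best_query = lib_ids[b],
               best_identity = global_identity(cc, lib[b]),
               best_evalue = ka$evalue[b], raw_score = aln$score[b],
               passed = ka$evalue[b] <= evalue_max, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(candidate = seq_along(cand), out)
  out$retained <- FALSE
  pass <- which(out$passed)
  if (length(pass)) {
    best <- pass[order(out$best_evalue[pass], -out$raw_score[pass])][1L]
    out$retained[best] <- TRUE
  }
  out
}

#' Run the full homolog detection pipeline over a genome collection
#'
#' For each genome: translated search of the query library, strand-ignorant
#' merging of overlapping/bookended hit intervals into loci, extension by
#' \code{gene_pad} (to complete the gene) and \code{context_pad} (to define
#' the context region), ORF extraction in the gene-extended interval, and the
#' reciprocal best-hit filter. Loci whose best reciprocal hit fails the
#' E-value threshold are reported with \code{passed_reciprocal = FALSE} and
#' do not count towards copy numbers.
#'
#' @param genomes Named \code{DNAStringSet}.
#' @param query_library Named \code{AAStringSet} of family queries.
#' @param evalue_max E-value threshold for both search and reciprocal filter.
#' @param gene_pad Gene-completion padding in bp (500 in the survey).
#' @param context_pad Context padding in bp (5000 in the survey).
#' @param min_len_aa Minimum ORF length in residues.
#' @param metadata Optional metadata (genome_id, host_genus, cluster,
#'   lifestyle) used for the per-group summary.
#' @return list(loci = locus table, copy_number = named integer vector,
#'   summary = list of proportion tables) of class "homolog_scan".
#' @export
run_detection <- function(genomes, query_library, evalue_max = 1e-5,
                          gene_pad = 500L, context_pad = 5000L,
                          min_len_aa = 30L, metadata = NULL) {
  stopifnot(!is.null(names(genomes)))
  loci <- list()
  for (gid in names(genomes)) {
    gseq <- as.character(genomes[[gid]])
    L <- nchar(gseq)
    hits <- translated_search(gseq, query_library, evalue_max = evalue_max)
    if (!nrow(hits)) next
    hits$genome_id <- gid
    merged <- merge_loci(hits)
    for (mi in seq_len(nrow(merged))) {
      gext <- extend_locus(merged$start[mi], merged$end[mi], gene_pad, L)
      cext <- extend_locus(merged$start[mi], merged$end[mi], context_pad, L)
      orfs <- extract_orf_protein(gseq, gext$start, gext$end, min_len_aa)
      lid <- sprintf("%s_L%02d", gid, mi)
      if (!nrow(orfs)) {
        loci[[length(loci) + 1L]] <- data.frame(
          locus_id = lid, genome_id = gid,
          merged_start = merged$start[mi], merged_end = merged$end[mi],
          ext_start = gext$start, ext_end = gext$end,
          context_start = cext$start, context_end = cext$end,
          strand = NA_character_, protein = NA_character_,
          best_query = NA_character_, best_identity = NA_real_,
          best_evalue = NA_real_, passed_reciprocal = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      rf <- reciprocal_filter(orfs$protein, query_library, evalue_max)
      ret <- which(rf$retained)
      if (!length(ret)) ret <- 1L
      loci[[length(loci) + 1L]] <- data.frame(
        locus_id = lid, genome_id = gid,
        merged_start = merged$start[mi], merged_end = merged$end[mi],
        ext_start = gext$start, ext_end = gext$end,
        context_start = cext$start, context_end = cext$end,
        strand = orfs$strand[ret], protein = orfs$protein[ret],
        best_query = rf$best_query[ret], best_identity = rf$best_identity[ret],
        best_evalue = rf$best_evalue[ret],
        passed_reciprocal = rf$passed[ret], stringsAsFactors = FALSE)
    }
  }
  loci <- if (length(loci)) do.call(rbind, loci) else data.frame(
    locus_id = character(), genome_id = character(), merged_start = integer(),
    merged_end = integer(), ext_start = integer(), ext_end = integer(),
    context_start = integer(), context_end = integer(), strand = character(),
    protein = character(), best_query = character(), best_identity = numeric(),
    best_evalue = numeric(), passed_reciprocal = logical(), stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  passed <- loci[loci$passed_reciprocal, , drop = FALSE]
  copy_number <- stats::setNames(integer(length(genomes)), names(genomes))
  tb <- table(passed$genome_id)
  copy_number[names(tb)] <- as.integer(tb)
  summary <- list(
    n_genomes = length(genomes),
    n_carriers = sum(copy_number > 0L),
    carrier_fraction = mean(copy_number > 0L),
    copy_histogram = table(copy_number))
  if (!is.null(metadata)) {
    md <- metadata[match(names(copy_number), metadata$genome_id), , drop = FALSE]
    for (grp in c("host_genus", "cluster")) {
      if (!grp %in% names(md)) next
      agg <- stats::aggregate(list(n_total = copy_number),
                              by = stats::setNames(list(md[[grp]]), grp), length)
      agg$n_carrier <- stats::aggregate(list(x = copy_number > 0L),
                                        by = list(md[[grp]]), sum)$x
      # proportion normalized to group size
      agg$fraction <- agg$n_carrier / agg$n_total
      summary[[paste0("by_", grp)]] <- agg
    }
  }
  structure(list(loci = loci, copy_number = copy_number, summary = summary),
            class = "homolog_scan")
}

#' @export
print.homolog_scan <- function(x, ...) {
  cat("Homolog scan:", x$summary$n_carriers, "of", x$summary$n_genomes,
      sprintf("genomes carry the gene (%.1f%%);", 100 * x$summary$carrier_fraction),
      sum(x$loci$passed_reciprocal), "loci passed the reciprocal filter\n")
  invisible(x)
}
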