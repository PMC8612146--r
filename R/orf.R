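# Six-frame translation and ORF calling, bacterial/phage translation
# table 11 (start codons ATG/GTG/TTG, all translated as initiator M).

.START_CODONS <- c("ATG", "GTG", "TTG")

# translate a DNA character string (length multiple-of-3 not required;
# trailing partial codon dropped); codons containing N give X
.translate_frame <- function(dna_chr) {
  n <- nchar(dna_chr) - nchar(dna_chr) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna_chr, 1L, n)),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

#' Find open reading frames in a DNA sequence
#'
#' Calls ORFs on both strands in all three frames using translation
#' table 11: from a start codon (ATG, GTG or TTG) to the next in-frame stop
#' codon, stop required to lie inside the sequence. For each stop the longest
#' ORF (the most upstream start) is reported. The first residue is reported
#' as M regardless of the start codon (initiator convention).
#'
#' @param seq DNA sequence (character, \code{DNAString}).
#' @param min_len_aa Minimum protein length (excluding the stop) to report.
#' @return Data.frame with 0-based half-open coordinates on the input
#'   sequence (start/end spanning start codon through stop codon), strand,
#'   frame and protein; ordered by protein length, longest first.
#' @export
find_orfs <- function(seq, min_len_aa = 30L) {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (f in 1:3) {
      sub <- substr(s, f, L)
      aa <- .translate_frame(sub)
      if (!nzchar(aa)) next
      codons <- substring(sub, seq(1L, 3L * nchar(aa), by = 3L) ,
                          seq(3L, 3L * nchar(aa), by = 3L))
      stops <- c(0L, which(strsplit(aa, "")[[1]] == "*"))
      for (k in seq_len(length(stops) - 1L)) {
        lo <- stops[k] + 1L; hi <- stops[k + 1L]  # codon indices; hi is the stop
        starts_here <- which(codons[lo:(hi - 1L)] %in% .START_CODONS)
        if (!length(starts_here)) next
        st <- lo + starts_here[1L] - 1L
        prot_len <- hi - st
        if (prot_len < min_len_aa) next
        prot <- paste0("M", substr(aa, st + 1L, hi - 1L))
        # strand-local 0-based nt coords, including the stop codon
        ls <- (f - 1L) + 3L * (st - 1L)
        le <- (f - 1L) + 3L * hi
        if (strand == "+") {
          g0 <- ls; g1 <- le
        } else {
          g0 <- L - le; g1 <- L - ls
        }
        res[[length(res) + 1L]] <- data.frame(
          start = g0, end = g1, strand = strand, frame = if (strand == "+") f else -f,
          protein = prot, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      frame = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(-nchar(out$protein), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate proteins from an extended genomic locus
#'
#' Extracts the extended interval from a genome and returns all ORFs of at
#' least \code{min_len_aa} residues on both strands (translation table 11),
#' with genome-absolute coordinates, ordered by length descending.
#'
#' @param genome \code{DNAString}/character genome sequence.
#' @param start,end 0-based half-open extended interval.
#' @param min_len_aa Minimum protein length.
#' @return Data.frame as \code{\link{find_orfs}} with genome-absolute coords.
#' @export
extract_orf_protein <- function(genome, start, end, min_len_aa = 30L) {
  genome <- as.character(genome)
  L <- nchar(genome)
  if (start < 0 || end > L || end <= start) stop("interval outside genome")
  sub <- substr(genome, start + 1L, end)
  orfs <- find_orfs(sub, min_len_aa = min_len_aa)
  orfs$start <- orfs$start + start
  orfs$end <- orfs$end + start
  orfs
}
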