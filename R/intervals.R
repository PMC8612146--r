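# Genomic intervals are plain data.frames with columns
# genome_id, start, end, strand -- 0-based, half-open [start, end).
# A single internal convention avoids off-by-one drift between modules;
# conversion to 1-based happens only at the GFF3/IRanges boundary.

#' Construct a genomic interval table
#'
#' @param genome_id Character vector.
#' @param start,end Integer vectors, 0-based half-open; end > start.
#' @param strand "+", "-" or "both".
#' @return A data.frame with class c("genomic_interval", "data.frame").
#' @export
genomic_interval <- function(genome_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  if (!all(strand %in% c("+", "-", "both"))) stop("strand must be +, - or both")
  df <- data.frame(genome_id = as.character(genome_id), start = start,
                   end = end, strand = strand, stringsAsFactors = FALSE)
  class(df) <- c("genomic_interval", "data.frame")
  df
}

# 0-based half-open -> IRanges (1-based closed) and back
.to_iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)
.from_iranges <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Merge overlapping or bookended intervals
#'
#' Strand-ignorant single-linkage merge of intervals on the same genome.
#' Overlapping and bookended intervals ([a,b) followed by [b,c)) are joined,
#' matching the samtools/bedtools merge convention. Output is sorted by
#' (genome, start) and pairwise disjoint.
#'
#' @param intervals Data.frame with columns genome_id, start, end.
#' @return Data.frame genome_id/start/end of merged intervals.
#' @export
merge_loci <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(data.frame(genome_id = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(intervals, intervals$genome_id), function(df) {
    red <- IRanges::reduce(.to_iranges(df$start, df$end), min.gapwidth = 1L)
    cbind(genome_id = df$genome_id[1L], .from_iranges(red))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$genome_id, res$start), , drop = FALSE]
}

#' Extend an interval by a fixed pad, clamped to the genome
#'
#' Pads both sides by \code{pad_bp} and clamps to [0, genome_length) with no
#' wraparound (linear genome convention).
#'
#' @param start,end 0-based half-open interval.
#' @param pad_bp Non-negative padding in bp.
#' @param genome_length Genome length in bp.
#' @return list(start, end) of the extended interval.
#' @export
extend_locus <- function(start, end, pad_bp, genome_length) {
  if (pad_bp < 0) stop("pad_bp must be >= 0")
  if (start < 0 || end > genome_length || end <= start)
    stop("interval outside genome")
  list(start = max(0L, as.integer(start - pad_bp)),
       end = min(as.integer(genome_length), as.integer(end + pad_bp)))
}
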