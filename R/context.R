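# Neighboring-genomic-context analysis of extended loci: library-based ORF
# annotation, per-cluster domain abundance, sliding-window GC profiles and
# detection of AT-rich dips upstream of a gene (the signature of xenogeneic
# silencer binding regions).

#' Annotate an extended locus by best library hit
#'
#' Calls ORFs (translation table 11, both strands) in the extended locus
#' sequence and assigns each ORF the label of its best hit in the annotation
#' library -- accepted when the global identity is at least
#' \code{min_identity} and the local-alignment E-value is at most
#' \code{evalue_max} -- or "hypothetical" otherwise. Overlapping ORF calls
#' are resolved by keeping, in order of precedence, annotated over
#' hypothetical, higher alignment score, then longer ORF; surviving genes are
#' non-overlapping and sorted by start.
#'
#' @param extended_seq DNA sequence of the extended locus.
#' @param annotation_library Named \code{AAStringSet}.
#' @param locus_id Id carried into the output rows.
#' @param min_len_aa Minimum ORF length.
#' @param min_identity Identity floor for accepting an annotation.
#' @param evalue_max E-value ceiling for accepting an annotation.
#' @return Data.frame of synteny rows: locus_id, gene_index, start, end
#'   (0-based, locus-relative), strand, label, identity_to_library.
#' @export
annotate_locus <- function(extended_seq, annotation_library, locus_id = "locus",
                           min_len_aa = 30L, min_identity = 0.3,
                           evalue_max = 1e-5) {
  if (length(annotation_library) == 0L) stop("annotation library must be non-empty")
  if (is.character(annotation_library))
    annotation_library <- Biostrings::AAStringSet(annotation_library)
  orfs <- find_orfs(extended_seq, min_len_aa = min_len_aa)
  if (!nrow(orfs)) {
    return(data.frame(locus_id = character(), gene_index = integer(),
                      start = integer(), end = integer(), strand = character(),
                      label = character(), identity_to_library = numeric(),
                      stringsAsFactors = FALSE))
  }
  lib <- as.character(annotation_library)
  ann <- lapply(orfs$protein, function(p) {
    aln <- align_local(lib, p)
    ka <- karlin_altschul_evalue(aln$score, nchar(p), nchar(lib))
    b <- order(ka$evalue, -aln$score, names(annotation_library))[1L]
    idt <- global_identity(p, lib[b])
    ok <- idt >= min_identity && ka$evalue[b] <= evalue_max
    list(label = if (ok) names(annotation_library)[b] else "hypothetical",
         identity = if (ok) idt else NA_real_, score = aln$score[b])
  })
  orfs$label <- vapply(ann, `[[`, character(1), "label")
  orfs$identity_to_library <- vapply(ann, `[[`, numeric(1), "identity")
  orfs$score <- vapply(ann, `[[`, numeric(1), "score")
  # overlap resolution: annotated first, then score, then length
  ord <- order(orfs$label == "hypothetical", -orfs$score,
               -(orfs$end - orfs$start))
  orfs <- orfs[ord, , drop = FALSE]
  kept <- logical(0); ks <- integer(0); ke <- integer(0)
  keep_idx <- integer(0)
  for (i in seq_len(nrow(orfs))) {
    if (!length(ks) || all(orfs$end[i] <= ks | orfs$start[i] >= ke)) {
      keep_idx <- c(keep_idx, i)
      ks <- c(ks, orfs$start[i]); ke <- c(ke, orfs$end[i])
    }
  }
  out <- orfs[keep_idx, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  data.frame(locus_id = locus_id, gene_index = seq_len(nrow(out)),
             start = out$start, end = out$end, strand = out$strand,
             label = out$label, identity_to_library = out$identity_to_library,
             stringsAsFactors = FALSE)
}

#' Per-cluster domain abundance in annotated loci
#'
#' For each (cluster, domain label) pair: the fraction of the cluster's loci
#' containing at least one gene with that label. Fractions at or above
#' \code{majority_fraction} are flagged (the "found in more than half of the
#' cluster's sequences" rule; the boundary is configurable).
#'
#' @param rows Synteny rows from \code{\link{annotate_locus}} (stacked).
#' @param locus_clusters Named vector locus_id -> cluster label.
#' @param majority_fraction Flagging threshold.
#' @param drop_hypothetical Exclude the "hypothetical" label.
#' @return Data.frame: cluster, domain, n_loci, n_with, fraction, flagged.
#' @export
domain_abundance <- function(rows, locus_clusters, majority_fraction = 0.5,
                             drop_hypothetical = TRUE) {
  rows$cluster <- unname(locus_clusters[rows$locus_id])
  if (anyNA(rows$cluster)) stop("every locus needs a cluster label")
  if (drop_hypothetical) rows <- rows[rows$label != "hypothetical", , drop = FALSE]
  loci_per_cluster <- table(unname(locus_clusters))
  out <- list()
  for (cl in names(loci_per_cluster)) {
    sub <- rows[rows$cluster == cl, , drop = FALSE]
    if (!nrow(sub)) next
    for (dom in sort(unique(sub$label))) {
      n_with <- length(unique(sub$locus_id[sub$label == dom]))
      frac <- n_with / as.integer(loci_per_cluster[[cl]])
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, domain = dom, n_loci = as.integer(loci_per_cluster[[cl]]),
        n_with = n_with, fraction = frac,
        flagged = frac >= majority_fraction, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(cluster = character(), domain = character(),
                                      n_loci = integer(), n_with = integer(),
                                      fraction = numeric(), flagged = logical(),
                                      stringsAsFactors = FALSE)
  res
}

#' Sliding-window GC profile
#'
#' GC fraction in windows of \code{window_bp}, advanced by \code{step_bp}.
#' N bases are excluded from numerator and denominator; an all-N window
#' yields NA.
#'
#' @param seq DNA sequence.
#' @param window_bp Window size (100 bp in the survey).
#' @param step_bp Step size.
#' @return list(window_bp, step_bp, starts (0-based), gc) of class "gc_profile".
#' @export
gc_profile <- function(seq, window_bp = 100L, step_bp = 100L) {
  s <- Biostrings::DNAString(toupper(as.character(seq)))
  L <- length(s)
  if (L < window_bp) stop("sequence shorter than window")
  starts1 <- seq.int(1L, L - window_bp + 1L, by = step_bp)
  v <- Biostrings::Views(s, start = starts1, width = window_bp)
  cnt <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
  denom <- rowSums(cnt)
  gcv <- (cnt[, "G"] + cnt[, "C"]) / denom
  gcv[denom == 0] <- NA_real_
  structure(list(window_bp = as.integer(window_bp), step_bp = as.integer(step_bp),
                 starts = starts1 - 1L, gc = unname(gcv)),
            class = "gc_profile")
}

#' Detect a GC drop upstream of a gene
#'
#' A dip is called when the smoothed GC minimum over the windows lying fully
#' inside [gene_start - upstream_span_bp, gene_start) is at least
#' \code{drop_min} below the locus-wide median GC (a baseline robust to the
#' gene body's own composition). Smoothing is a rolling mean over
#' \code{smooth} consecutive windows (default 3); computing the profile with
#' overlapping windows (step 50 at the default 100 bp window) makes this a
#' 200 bp matched span on a 50 bp grid, which suppresses single-window
#' sampling noise while staying fully sensitive to the multi-window dips
#' that AT-rich silencer-bound regions produce.
#'
#' @param profile A \code{\link{gc_profile}} of the locus.
#' @param gene_start_offset 0-based gene start within the locus.
#' @param upstream_span_bp Width of the upstream search region.
#' @param drop_min Minimum depth below the locus median to call a dip.
#' @param smooth Number of consecutive windows averaged for the dip statistic.
#' @return list(found, dip_location (0-based start of the minimizing smoothed
#'   window or NA), dip_depth = median - smoothed minimum).
#' @export
detect_gc_drop <- function(profile, gene_start_offset, upstream_span_bp = 1000L,
                           drop_min = 0.10, smooth = 3L) {
  lo <- gene_start_offset - upstream_span_bp
  inside <- which(profile$starts >= lo &
                  (profile$starts + profile$window_bp) <= gene_start_offset)
  if (!length(inside)) {
    warning("no complete window in the upstream span")
    return(list(found = FALSE, dip_location = NA_integer_, dip_depth = NA_real_))
  }
  med <- stats::median(profile$gc, na.rm = TRUE)
  up <- profile$gc[inside]
  if (all(is.na(up))) return(list(found = FALSE, dip_location = NA_integer_,
                                  dip_depth = NA_real_))
  k <- min(smooth, length(up))
  sm <- vapply(seq_len(length(up) - k + 1L), function(i) mean(up[i:(i + k - 1L)]),
               numeric(1))
  i_min <- which.min(sm)
  depth <- med - sm[i_min]
  list(found = isTRUE(depth >= drop_min),
       dip_location = profile$starts[inside[i_min]], dip_depth = depth)
}

#' GC contrast between a direct terminal repeat and the rest of the genome
#'
#' @param genome DNA sequence.
#' @param start,end 0-based half-open repeat interval, a proper subset of the
#'   genome.
#' @return list(gc_repeat, gc_rest).
#' @export
dtr_gc_contrast <- function(genome, start, end) {
  g <- toupper(as.character(genome))
  L <- nchar(g)
  if (start < 0 || end > L || end <= start) stop("repeat interval outside genome")
  if (start == 0 && end == L) stop("repeat must be a proper subset of the genome")
  inside <- substr(g, start + 1L, end)
  rest <- paste0(substr(g, 1L, start), substr(g, end + 1L, L))
  list(gc_repeat = gc_fraction(inside), gc_rest = gc_fraction(rest))
}

#' Write synteny rows as GFF3
#'
#' Converts the internal 0-based half-open coordinates to GFF3's 1-based
#' inclusive convention at the boundary.
#'
#' @param rows Synteny rows from \code{\link{annotate_locus}}.
#' @param path Output path.
#' @param seqid Sequence id for column 1 (defaults to the locus_id).
#' @export
write_gff3 <- function(rows, path, seqid = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(rows))) {
    attrs <- sprintf("ID=%s_g%d;product=%s", rows$locus_id[i],
                     rows$gene_index[i], rows$label[i])
    if (!is.na(rows$identity_to_library[i]))
      attrs <- sprintf("%s;identity=%.3f", attrs, rows$identity_to_library[i])
    writeLines(paste(seqid %||% rows$locus_id[i], "phageTF", "CDS",
                     rows$start[i] + 1L, rows$end[i], ".", rows$strand[i], "0",
                     attrs, sep = "\t"), con)
  }
  invisible(path)
}
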