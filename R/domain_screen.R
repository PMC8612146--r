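# Post-processing of conserved-domain hit tables into a per-genome TF domain
# count matrix: the same domain locus is typically reported by several source
# databases at overlapping coordinates, so cross-database duplicates are
# collapsed to one locus before counting.

#' Load the bundled transcription-factor domain catalog
#'
#' @return Data.frame with columns domain_id, family, source_db; the set of
#'   regulator families screened for, mapping database-specific domain ids to
#'   the collapsed family label. User-editable: any table with these columns
#'   can be substituted.
#' @export
tf_domain_catalog <- function() {
  f <- system.file("extdata", "tf_domain_catalog.tsv", package = "phageTF")
  utils::read.delim(f, stringsAsFactors = FALSE)
}

#' Filter domain hits by catalog membership and E-value
#'
#' @param hits Data.frame with columns genome_id, domain_id, start, end, evalue.
#' @param tf_catalog Character vector of domain ids (or a catalog data.frame
#'   with a domain_id column).
#' @param evalue_max Screening E-value threshold (the survey's domain screen
#'   used 0.001).
#' @return The subset of rows with domain_id in the catalog and
#'   evalue <= evalue_max, input order preserved.
#' @export
filter_hits <- function(hits, tf_catalog, evalue_max = 0.001) {
  if (is.data.frame(tf_catalog)) tf_catalog <- tf_catalog$domain_id
  if (!length(tf_catalog)) stop("tf_catalog must be non-empty")
  hits[hits$domain_id %in% tf_catalog & hits$evalue <= evalue_max, , drop = FALSE]
}

# overlap of [a1,a2) and [b1,b2) as a fraction of the shorter interval
.overlap_fraction <- function(a1, a2, b1, b2) {
  ov <- pmax(0, pmin(a2, b2) - pmax(a1, b1))
  ov / pmin(a2 - a1, b2 - b1)
}

# single-linkage grouping of rows of one genome by >= frac overlap
.group_once <- function(df, frac) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (.overlap_fraction(df$start[i], df$end[i], df$start[j], df$end[j]) >= frac) {
      parent[max(find(i), find(j))] <- min(find(i), find(j))
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Collapse cross-database duplicate domain hits into loci
#'
#' Within each genome, hits whose intervals overlap by at least
#' \code{min_overlap_fraction} of the shorter interval are grouped by single
#' linkage into one locus. Each locus is labeled with the family of its
#' lowest-E-value member (via \code{family_map}), keeps the spanning
#' interval and the minimum E-value, and the grouping is re-applied to the
#' locus spans until stable, so the output is idempotent and loci never
#' overlap under the same criterion.
#'
#' @param hits Filtered hit table (genome_id, domain_id, start, end, evalue).
#' @param min_overlap_fraction Overlap threshold in (0, 1], default 0.5.
#' @param family_map Named character vector domain_id -> family (defaults to
#'   the bundled catalog); unmapped ids keep their domain_id as family.
#' @return Data.frame: genome_id, family, start, end, evalue (min),
#'   n_hits, source_dbs (comma list).
#' @export
collapse_overlapping <- function(hits, min_overlap_fraction = 0.5, family_map = NULL) {
  if (min_overlap_fraction <= 0 || min_overlap_fraction > 1)
    stop("min_overlap_fraction must be in (0, 1]")
  if (is.null(family_map)) {
    cat_ <- tf_domain_catalog()
    family_map <- stats::setNames(cat_$family, cat_$domain_id)
  }
  if (nrow(hits) == 0L) {
    return(data.frame(genome_id = character(), family = character(),
                      start = integer(), end = integer(), evalue = numeric(),
                      n_hits = integer(), source_dbs = character(),
                      stringsAsFactors = FALSE))
  }
  fam <- unname(family_map[hits$domain_id])
  fam[is.na(fam)] <- hits$domain_id[is.na(fam)]
  hits$family <- fam
  if (is.null(hits$source_db)) hits$source_db <- "NA"
  out <- lapply(split(hits, hits$genome_id), function(df) {
    df <- df[order(df$start), , drop = FALSE]
    # collapse, then re-collapse the spans until stable
    repeat {
      grp <- .group_once(df, min_overlap_fraction)
      coll <- do.call(rbind, lapply(split(seq_len(nrow(df)), grp), function(ix) {
        sub <- df[ix, , drop = FALSE]
        best <- which.min(sub$evalue)
        data.frame(genome_id = sub$genome_id[1L], family = sub$family[best],
                   start = min(sub$start), end = max(sub$end),
                   evalue = min(sub$evalue), n_hits = sum(sub$n_hits %||% rep(1L, nrow(sub))),
                   source_dbs = paste(sort(unique(unlist(strsplit(sub$source_db, ",")))),
                                      collapse = ","),
                   stringsAsFactors = FALSE)
      }))
      if (nrow(coll) == nrow(df)) break
      df <- coll[order(coll$start), , drop = FALSE]
      df$source_db <- df$source_dbs
    }
    coll
  })
  res <- do.call(rbind, out)
  res <- res[order(res$genome_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the genomes x TF-families count matrix
#'
#' Counts collapsed loci per (genome, family); families present in fewer
#' than \code{prevalence_min} genomes are dropped (the survey's "domains
#' encoded by at least 10 phage genomes" rule; the boundary is configurable
#' because >=10 vs >10 differs between descriptions of the original screen).
#'
#' @param collapsed Output of \code{\link{collapse_overlapping}}.
#' @param prevalence_min Minimum number of genomes a family must occur in.
#' @param all_genomes Optional character vector of all genome ids, so genomes
#'   with zero loci are retained as all-zero rows.
#' @return list(counts = integer matrix genomes x families,
#'   prevalence = data.frame(family, n_genomes, fraction), n_genomes).
#' @export
build_matrix <- function(collapsed, prevalence_min = 10L, all_genomes = NULL) {
  genomes <- sort(unique(c(collapsed$genome_id, all_genomes)))
  fams <- sort(unique(collapsed$family))
  counts <- matrix(0L, nrow = length(genomes), ncol = length(fams),
                   dimnames = list(genomes, fams))
  if (nrow(collapsed)) {
    tab <- table(collapsed$genome_id, collapsed$family)
    counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  n_with <- colSums(counts > 0L)
  prevalence <- data.frame(family = fams, n_genomes = as.integer(n_with),
                           fraction = as.numeric(n_with) / length(genomes),
                           stringsAsFactors = FALSE)
  keep <- n_with >= prevalence_min
  list(counts = counts[, keep, drop = FALSE],
       prevalence = prevalence[order(-prevalence$n_genomes), , drop = FALSE],
       n_genomes = length(genomes))
}

#' Pairwise co-occurrence correlation of TF domain counts
#'
#' Pearson correlation between the count columns of the TF domain matrix.
#' Zero-variance columns yield NA (not 0) in their row/column.
#'
#' @param counts Count matrix from \code{\link{build_matrix}} (or the list it
#'   returns).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
cooccurrence <- function(counts) {
  if (is.list(counts) && !is.matrix(counts)) counts <- counts$counts
  if (ncol(counts) < 2L) stop("need >= 2 domain columns")
  if (nrow(counts) < 3L) stop("need >= 3 genomes")
  suppressWarnings(r <- stats::cor(counts, method = "pearson"))
  diag(r) <- ifelse(apply(counts, 2, stats::sd) > 0, 1, NA_real_)
  r
}
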