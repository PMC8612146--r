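# Alignment-free whole-genome phylogeny: k-mer frequency profiles compared
# by Jensen-Shannon divergence, clustered by neighbor joining.

#' k-mer frequency profile of a genome
#'
#' Counts all overlapping k-mers consisting only of A/C/G/T (windows
#' containing N are skipped) and normalizes to a probability vector over the
#' 4^k k-mers. With \code{canonical = TRUE} the profile is computed over both
#' strands (counts of the sequence plus its reverse complement).
#'
#' @param seq Genome sequence (\code{DNAString} or character).
#' @param k Word size, 1-10; 6 is the default used for phage-genome trees
#'   (4096 features).
#' @param canonical Merge reverse-complement counts.
#' @param genome_id Optional id carried in the result.
#' @return list(genome_id, k, freq) of class "kmer_profile"; \code{freq} is a
#'   named numeric vector of length 4^k summing to 1.
#' @export
kmer_profile <- function(seq, k = 6L, canonical = FALSE, genome_id = NULL) {
  if (k < 1L || k > 10L) stop("k must be in 1..10")
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  if (length(seq) < k) stop("genome shorter than k")
  cnt <- Biostrings::oligonucleotideFrequency(seq, width = k)
  if (canonical) {
    cnt <- cnt + Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(seq), width = k)
  }
  tot <- sum(cnt)
  if (tot == 0) stop("no valid (N-free) k-mer windows")
  structure(list(genome_id = genome_id, k = as.integer(k), freq = cnt / tot),
            class = "kmer_profile")
}

.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence between two k-mer profiles
#'
#' JSD(P, Q) = H(M) - (H(P) + H(Q)) / 2 with M = (P + Q)/2 and H the Shannon
#' entropy in bits, so the result lies in [0, 1] (1 for distributions with
#' disjoint support). Symmetric; 0 log 0 is taken as 0.
#'
#' @param p,q \code{kmer_profile}s (or bare probability vectors) with equal k.
#' @return JSD in [0, 1].
#' @export
jsd <- function(p, q) {
  if (inherits(p, "kmer_profile") || inherits(q, "kmer_profile")) {
    if (!inherits(p, "kmer_profile") || !inherits(q, "kmer_profile") || p$k != q$k)
      stop("profiles must share the same k")
    p <- p$freq; q <- q$freq
  }
  if (length(p) != length(q)) stop("profiles must share the same k")
  m <- (p + q) / 2
  d <- .entropy2(m) - (.entropy2(p) + .entropy2(q)) / 2
  min(max(d, 0), 1)
}

#' Pairwise Jensen-Shannon distance matrix
#'
#' By default the matrix holds sqrt(JSD), which is a true metric and behaves
#' far closer to tree-additivity than raw JSD; neighbor joining on raw JSD
#' systematically misplaces intermediate-composition genomes, so the raw
#' divergence is available but not the default.
#'
#' @param profiles List of \code{kmer_profile}s with unique genome_ids and a
#'   shared k.
#' @param sqrt_jsd If TRUE (default) return sqrt(JSD); FALSE gives raw JSD.
#' @return Symmetric labeled distance matrix with zero diagonal.
#' @export
jsd_matrix <- function(profiles, sqrt_jsd = TRUE) {
  if (length(profiles) < 3L) stop("need >= 3 profiles")
  ids <- vapply(profiles, function(p) p$genome_id %||% NA_character_, character(1))
  if (anyNA(ids)) stop("profiles must carry genome_ids")
  if (anyDuplicated(ids)) stop("duplicate genome_id: ", ids[duplicated(ids)][1L])
  ks <- vapply(profiles, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L) stop("profiles must share the same k")
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- jsd(profiles[[i]], profiles[[j]])
    if (sqrt_jsd) v <- sqrt(v)
    d[i, j] <- d[j, i] <- v
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler Q-criterion. On an
#' additive distance matrix the generating topology and branch lengths are
#' recovered exactly (up to floating point). Ties in the Q minimization are
#' broken by the lowest (row, column) index pair for determinism. Negative
#' branch lengths are clamped to zero with the deficit transferred to the
#' adjacent branch of the joined pair, preserving their summed length.
#'
#' @param d Symmetric numeric matrix with labeled rows/columns, zero
#'   diagonal, non-negative entries.
#' @return An unrooted \code{phylo} object (basal trifurcation).
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must have labels")
  n <- nrow(d)
  if (n < 3L) stop("need >= 3 taxa")
  if (any(d < 0)) stop("negative distance entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  fmt <- function(v) sprintf("%.15g", max(v, 0))
  sub <- .nwk_label(labels)
  while (n > 3L) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    m <- min(Q)
    hit <- which(Q == m, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newsub <- paste0("(", sub[i], ":", fmt(vi), ",", sub[j], ":", fmt(vj), ")")
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    sub <- c(sub[keep], newsub)
    n <- n - 1L
    rownames(d) <- colnames(d) <- NULL
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", sub[1], ":", fmt(v1), ",", sub[2], ":", fmt(v2),
                ",", sub[3], ":", fmt(v3), ");")
  read_newick(text = txt)
}

# For each edge of an unrooted tree, the set of tip indices on the side of
# the edge's child node (tree oriented from ape's root). Pendant edges give
# singleton sets.
.edge_tip_sets <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) sort(below[[tree$edge[e, 2L]]]))
}

#' Per-cluster monophyly of a genome tree
#'
#' For each cluster with >= 2 labeled members, reports whether the cluster's
#' leaves form a clade of the unrooted tree, i.e. lie on one side of some
#' edge. Leaves without a cluster label (or labeled "singleton") are excluded
#' from the bipartition comparison.
#'
#' @param tree A \code{phylo} object.
#' @param metadata Data.frame with genome_id and cluster columns.
#' @return list(per_cluster = data.frame(cluster, n, monophyletic),
#'   fraction = proportion of concordant clusters).
#' @export
cluster_concordance <- function(tree, metadata) {
  cl <- stats::setNames(metadata$cluster, metadata$genome_id)[tree$tip.label]
  labeled <- which(!is.na(cl) & cl != "" & tolower(cl) != "singleton")
  sets <- .edge_tip_sets(tree)
  sets <- lapply(sets, function(s) intersect(s, labeled))
  keys <- unique(vapply(sets, paste, character(1), collapse = ","))
  clusters <- sort(unique(cl[labeled]))
  rows <- lapply(clusters, function(cc) {
    members <- sort(labeled[cl[labeled] == cc])
    if (length(members) < 2L) return(NULL)
    comp <- sort(setdiff(labeled, members))
    mono <- paste(members, collapse = ",") %in% keys ||
      paste(comp, collapse = ",") %in% keys ||
      length(comp) == 0L
    data.frame(cluster = cc, n = length(members), monophyletic = mono,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  if (is.null(per)) {
    per <- data.frame(cluster = character(), n = integer(),
                      monophyletic = logical(), stringsAsFactors = FALSE)
  }
  list(per_cluster = per,
       fraction = if (nrow(per)) mean(per$monophyletic) else NA_real_)
}
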