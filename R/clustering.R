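# Greedy centroid clustering at an identity threshold (the UCLUST scheme)
# and all-vs-all pairwise identity matrices for group comparisons.

#' Greedy identity clustering of protein sequences
#'
#' Sequences are processed in length-descending order (ties by id); each is
#' assigned to the first existing centroid with global identity at least the
#' threshold, otherwise it founds a new cluster with itself as centroid --
#' greedy centroid-anchored assignment, not single linkage. The
#' representative of each cluster is its longest member (ties broken by
#' lexicographic id). The survey clustered at 90\% identity and took the
#' longest sequence of each cluster forward.
#'
#' @param seqs Named character vector or \code{AAStringSet}.
#' @param threshold Identity threshold in (0, 1].
#' @return list(threshold, clusters, assignments, representatives) of class
#'   "cluster_set"; \code{clusters} is a data.frame (cluster_id, centroid,
#'   representative, n, members).
#' @export
greedy_cluster <- function(seqs, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  s <- if (is.character(seqs)) seqs else stats::setNames(as.character(seqs), names(seqs))
  if (is.null(names(s)) || anyNA(names(s))) stop("sequences must be named")
  ord <- order(-nchar(s), names(s))
  s <- s[ord]
  centroids <- character(0)
  assign <- integer(length(s))
  names(assign) <- names(s)
  for (i in seq_along(s)) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      if (global_identity(s[i], s[centroids[ci]]) >= threshold) {
        assign[i] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids <- c(centroids, names(s)[i])
      assign[i] <- length(centroids)
    }
  }
  clusters <- do.call(rbind, lapply(seq_along(centroids), function(ci) {
    mem <- names(assign)[assign == ci]
    lens <- nchar(s[mem])
    rep_ <- mem[order(-lens, mem)][1L]
    data.frame(cluster_id = ci, centroid = centroids[ci], representative = rep_,
               n = length(mem), members = paste(mem, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  structure(list(threshold = threshold, clusters = clusters,
                 assignments = assign,
                 representatives = stats::setNames(s[clusters$representative],
                                                   clusters$representative)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("Greedy identity clustering at", x$threshold, ":",
      length(x$assignments), "sequences ->", nrow(x$clusters), "clusters\n")
  invisible(x)
}

#' All-vs-all pairwise identity matrix
#'
#' Global pairwise identities (see \code{\link{global_identity}}) between all
#' sequence pairs, plus a per-source-group summary (median and IQR of
#' within-group pairwise identities) for comparing, e.g., phage- vs
#' bacteria-encoded members of a family.
#'
#' @param seqs Named character vector or \code{AAStringSet} (>= 2 sequences).
#' @param group_labels Optional vector of source groups, parallel to seqs.
#' @return list(identity = symmetric matrix with unit diagonal,
#'   group_summary = data.frame or NULL, long = long-format pair table).
#' @export
identity_matrix <- function(seqs, group_labels = NULL) {
  s <- if (is.character(seqs)) seqs else stats::setNames(as.character(seqs), names(seqs))
  n <- length(s)
  if (n < 2L) stop("need >= 2 sequences")
  ids <- names(s)
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  long <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- global_identity(s[i], s[j])
    m[i, j] <- m[j, i] <- v
    long[[length(long) + 1L]] <- data.frame(
      a = ids[i], b = ids[j], identity = v,
      group_a = if (is.null(group_labels)) NA_character_ else group_labels[i],
      group_b = if (is.null(group_labels)) NA_character_ else group_labels[j],
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, long)
  group_summary <- NULL
  if (!is.null(group_labels)) {
    within <- long[long$group_a == long$group_b, , drop = FALSE]
    if (nrow(within)) {
      group_summary <- do.call(rbind, lapply(split(within, within$group_a), function(df) {
        q <- stats::quantile(df$identity, c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(group = df$group_a[1L], n_pairs = nrow(df),
                   median = q[2L], q25 = q[1L], q75 = q[3L],
                   stringsAsFactors = FALSE)
      }))
      rownames(group_summary) <- NULL
    }
  }
  list(identity = m, group_summary = group_summary, long = long)
}
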