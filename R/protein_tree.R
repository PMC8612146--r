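# Gene trees for clustered family representatives, built by neighbor joining
# on identity-derived distances, and a clade-count ("paraphyly") index that
# scores how scattered a source group (phage / bacteria / plasmid) is across
# the unrooted tree.

#' Distances from a pairwise identity matrix
#'
#' p-distance d = 1 - identity, or Poisson-corrected d = -ln(identity)
#' (multiple-hit correction). Identity 1 maps to 0 under both. An identity of
#' 0 is undefined under the Poisson correction and is capped at \code{d_max}
#' with a warning.
#'
#' @param identity Symmetric identity matrix in (0, 1] (or the list returned
#'   by \code{\link{identity_matrix}}).
#' @param correction "poisson" (default) or "p".
#' @param d_max Cap for infinite Poisson distances.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
distance_from_identity <- function(identity, correction = c("poisson", "p"),
                                   d_max = 5.0) {
  correction <- match.arg(correction)
  if (is.list(identity) && !is.matrix(identity)) identity <- identity$identity
  d <- if (correction == "p") 1 - identity else -log(identity)
  if (any(!is.finite(d))) {
    warning("identity 0 under poisson correction capped at d_max = ", d_max)
    d[!is.finite(d)] <- d_max
  }
  d[d > d_max] <- d_max
  diag(d) <- 0
  d
}

#' Build a gene tree from family representatives
#'
#' Computes all pairwise global identities, converts them to corrected
#' distances and runs neighbor joining. Leaf labels are prefixed with the
#' source group (e.g. \code{phage_}, \code{bacteria_}, \code{plasmid_}) when
#' groups are supplied.
#'
#' @param representatives Named character vector / \code{AAStringSet}, >= 4.
#' @param groups Optional source-group vector parallel to representatives.
#' @param correction Distance correction, see
#'   \code{\link{distance_from_identity}}.
#' @return An unrooted \code{phylo} object.
#' @export
build_gene_tree <- function(representatives, groups = NULL,
                            correction = c("poisson", "p")) {
  s <- if (is.character(representatives)) representatives else
    stats::setNames(as.character(representatives), names(representatives))
  if (length(s) < 4L) stop("need >= 4 representatives")
  if (!is.null(groups)) names(s) <- paste(groups, names(s), sep = "_")
  im <- identity_matrix(s)
  d <- distance_from_identity(im$identity, correction)
  neighbor_joining(d)
}

# orient the unrooted tree away from a reference leaf and return, per node,
# the tip indices below it
.orient_from <- function(tree, ref_tip) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  adj <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  parent <- rep(NA_integer_, nnode)
  order_ <- integer(0)
  stack <- ref_tip
  seen <- logical(nnode); seen[ref_tip] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_ <- c(order_, v)
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; parent[w] <- v; stack <- c(stack, w)
    }
  }
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (v in rev(order_)) {
    for (w in adj[[v]]) if (!is.na(parent[w]) && parent[w] == v)
      below[[v]] <- c(below[[v]], below[[w]])
  }
  list(parent = parent, below = lapply(below, sort), order = order_)
}

#' Source-group interleaving report for an unrooted tree
#'
#' For each source group, counts the number of maximal same-group clades
#' (a clade being one side of some edge of the unrooted tree). A count of 1
#' means the group is monophyletic; larger counts quantify how scattered the
#' group is -- e.g. phage sequences falling inside several distinct bacterial
#' clades yield a phage clade count > 1.
#'
#' @param tree A \code{phylo} object.
#' @param groups Named vector (leaf label -> source group) or vector parallel
#'   to \code{tree$tip.label}.
#' @return Data.frame: group, n_leaves, n_clades, monophyletic.
#' @export
source_interleaving <- function(tree, groups) {
  ntip <- length(tree$tip.label)
  grp <- if (!is.null(names(groups))) unname(groups[tree$tip.label]) else groups
  if (anyNA(grp)) stop("every leaf needs a source group")
  rows <- lapply(sort(unique(grp)), function(g) {
    tips_g <- which(grp == g)
    if (length(tips_g) == ntip) {
      return(data.frame(group = g, n_leaves = ntip, n_clades = 1L,
                        monophyletic = TRUE, stringsAsFactors = FALSE))
    }
    ref <- which(grp != g)[1L]
    ori <- .orient_from(tree, ref)
    pure <- vapply(ori$below, function(s) length(s) > 0 && all(grp[s] == g), logical(1))
    maximal <- vapply(seq_along(pure), function(v) {
      pure[v] && (is.na(ori$parent[v]) || !pure[ori$parent[v]])
    }, logical(1))
    data.frame(group = g, n_leaves = length(tips_g), n_clades = sum(maximal),
               monophyletic = sum(maximal) == 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
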