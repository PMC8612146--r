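# Group statistics: two-sample Wilcoxon rank-sum implemented from first
# principles (exact enumeration for small samples, tie-corrected normal
# approximation with continuity correction otherwise), the significance-star
# ladder used in the figures, lifestyle enrichment normalized to group size,
# and the GC / genome-size comparisons.

#' Wilcoxon rank-sum test
#'
#' Two-sided two-sample Wilcoxon test on the rank sum W of the first group
#' (mid-ranks for ties). In exact mode the null distribution is obtained by
#' enumerating all C(n_x + n_y, n_x) assignments of the pooled values to the
#' groups and the p-value is 2 * min(P(W <= w), P(W >= w)) capped at 1; in
#' normal mode a tie-corrected variance and a 0.5 continuity correction are
#' used. \code{mode = "auto"} uses the exact test when n_x + n_y <= 12.
#' If all pooled values are identical, p = 1.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param mode "auto", "exact" or "normal".
#' @return list(W (rank sum of x), p_value, mode).
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both groups must be non-empty")
  pooled <- c(x, y)
  N <- nx + ny
  rk <- rank(pooled)
  W <- sum(rk[seq_len(nx)])
  if (length(unique(pooled)) == 1L) {
    return(list(W = W, p_value = 1, mode = "degenerate"))
  }
  if (mode == "auto") mode <- if (N <= 12L) "exact" else "normal"
  if (mode == "exact") {
    combos <- utils::combn(N, nx)
    Wnull <- colSums(matrix(rk[combos], nrow = nx))
    p <- 2 * min(mean(Wnull <= W + 1e-9), mean(Wnull >= W - 1e-9))
    p <- min(p, 1)
  } else {
    mu <- nx * (N + 1) / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- nx * ny / 12 * ((N + 1) - tie_term)
    dev <- W - mu
    z <- (dev - sign(dev) * 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(W = W, p_value = p, mode = mode)
}

#' Significance code for a p-value
#'
#' The star ladder used in the survey's figure legends: **** for p < 0.0001,
#' *** for p < 0.001, ** for p < 0.01, * for p < 0.05, "ns" otherwise.
#'
#' @param p p-value(s) in (0, 1].
#' @return Character vector of codes.
#' @export
significance_code <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must be in (0, 1]")
  vapply(p, function(pp) {
    if (pp < 0.0001) "****" else if (pp < 0.001) "***"
    else if (pp < 0.01) "**" else if (pp < 0.05) "*" else "ns"
  }, character(1))
}

#' Lifestyle enrichment of gene carriers, normalized to group size
#'
#' Computes, per lifestyle, the proportion of genomes carrying the gene
#' (carriers / group size) and the temperate:virulent ratio of those
#' proportions. Genomes without lifestyle information are excluded from both
#' numerator and denominator.
#'
#' @param carrier_ids Character vector of carrier genome ids (or a
#'   \code{homolog_scan}, whose positive-copy genomes are used).
#' @param metadata Data.frame with genome_id and lifestyle.
#' @return list(proportions = data.frame(lifestyle, n_total, n_carrier,
#'   proportion), ratio_temperate_virulent).
#' @export
lifestyle_enrichment <- function(carrier_ids, metadata) {
  if (inherits(carrier_ids, "homolog_scan"))
    carrier_ids <- names(carrier_ids$copy_number)[carrier_ids$copy_number > 0L]
  md <- metadata[metadata$lifestyle %in% c("temperate", "virulent"), , drop = FALSE]
  rows <- lapply(c("temperate", "virulent"), function(ls) {
    sub <- md[md$lifestyle == ls, , drop = FALSE]
    n <- nrow(sub); k <- sum(sub$genome_id %in% carrier_ids)
    data.frame(lifestyle = ls, n_total = n, n_carrier = k,
               proportion = if (n > 0) k / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  props <- do.call(rbind, rows)
  pt <- props$proportion[props$lifestyle == "temperate"]
  pv <- props$proportion[props$lifestyle == "virulent"]
  ratio <- if (!is.na(pt) && !is.na(pv) && pv > 0) pt / pv else NA_real_
  list(proportions = props, ratio_temperate_virulent = ratio)
}

#' GC and genome-size comparisons of carriers vs non-carriers
#'
#' Within each lifestyle (temperate, virulent), compares carriers against
#' non-carriers for GC content and genome size by two-sided Wilcoxon tests,
#' reporting medians, the W statistic, the p-value and its significance code.
#' Comparisons with fewer than 2 genomes on a side are skipped with a
#' warning.
#'
#' @param metadata Data.frame with genome_id, lifestyle, gc, length_bp.
#' @param carrier_ids Carrier genome ids (or a \code{homolog_scan}).
#' @param mode Wilcoxon mode passed through.
#' @return Data.frame: variable, lifestyle, n_carrier, n_noncarrier,
#'   median_carrier, median_noncarrier, W, p_value, code.
#' @export
compare_gc_size <- function(metadata, carrier_ids, mode = "auto") {
  if (inherits(carrier_ids, "homolog_scan"))
    carrier_ids <- names(carrier_ids$copy_number)[carrier_ids$copy_number > 0L]
  md <- metadata[metadata$lifestyle %in% c("temperate", "virulent"), , drop = FALSE]
  md$carrier <- md$genome_id %in% carrier_ids
  out <- list()
  for (var in c("gc", "length_bp")) {
    for (ls in c("temperate", "virulent")) {
      sub <- md[md$lifestyle == ls, , drop = FALSE]
      xc <- sub[[var]][sub$carrier]; xn <- sub[[var]][!sub$carrier]
      if (length(xc) < 2L || length(xn) < 2L) {
        warning("skipping ", var, " / ", ls, ": fewer than 2 genomes per side")
        next
      }
      wt <- wilcoxon_rank_sum(xc, xn, mode = mode)
      out[[length(out) + 1L]] <- data.frame(
        variable = var, lifestyle = ls,
        n_carrier = length(xc), n_noncarrier = length(xn),
        median_carrier = stats::median(xc), median_noncarrier = stats::median(xn),
        W = wt$W, p_value = wt$p_value, code = significance_code(wt$p_value),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame()
  res
}
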