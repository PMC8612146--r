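# Synthetic actinobacteriophage genome collections with ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: cluster-structured relatedness (independent cluster ancestors,
# per-site substitution within clusters), per-cluster background GC,
# implanted regulator ORFs at controlled amino-acid divergence (0-2 copies),
# AT-rich dips upstream of lsr2-like implants, direct terminal repeats that
# carry a gene copy, and lifestyle labels enriched among implant carriers.

.HOST_GENERA <- c("Mycobacterium", "Streptomyces", "Gordonia", "Arthrobacter",
                  "Microbacterium", "Corynebacterium", "Rhodococcus",
                  "Propionibacterium")

#' Simulation configuration
#'
#' Builds and validates the configuration object for
#' \code{\link{simulate_collection}}. Defaults describe a small but
#' structured collection: 4 clusters of 5 genomes, 50 kb each, distinct
#' per-cluster GC, 2\% within-cluster divergence.
#'
#' @param n_clusters Number of clusters (independent ancestors).
#' @param genomes_per_cluster Genomes per cluster.
#' @param genome_length_bp Genome length in bp.
#' @param cluster_gc Per-cluster background GC fractions (length n_clusters);
#'   default evenly spaced 0.45-0.65.
#' @param within_cluster_divergence Per-site substitution probability from the
#'   cluster ancestor, in [0, 0.3].
#' @param implant_plan Data.frame with columns cluster (1-based index),
#'   gene ("whiB-like"/"lsr2-like"), copies (0-2), aa_divergence ([0, 0.75]);
#'   each row applies to every genome of that cluster. NULL = no implants.
#' @param at_dip list(depth, width_bp): GC is lowered by \code{depth} over
#'   \code{width_bp} immediately upstream of every lsr2-like implant.
#' @param dtr_length_bp Direct terminal repeat length; if > 0 the genome's
#'   first and last \code{dtr_length_bp} bases are identical copies and the
#'   first implant copy is placed inside the repeat.
#' @param dtr_gc Optional GC fraction at which the repeat region is resampled
#'   (models the GC-rich DTR blocks seen in real Streptomyces phages).
#' @param lifestyle_odds Odds multiplier for implant carriers to be temperate.
#' @param lifestyle_base_prob Baseline temperate probability for non-carriers.
#' @param seed RNG seed; the whole collection is deterministic given the seed.
#' @return A validated list of class "simulation_config".
#' @export
simulation_config <- function(n_clusters = 4L, genomes_per_cluster = 5L,
                              genome_length_bp = 50000L, cluster_gc = NULL,
                              within_cluster_divergence = 0.02,
                              implant_plan = NULL,
                              at_dip = list(depth = 0.15, width_bp = 300L),
                              dtr_length_bp = 0L, dtr_gc = NULL,
                              lifestyle_odds = 3, lifestyle_base_prob = 0.5,
                              seed = 1L) {
  if (n_clusters < 1L || genomes_per_cluster < 1L) stop("need >= 1 cluster and genome")
  if (is.null(cluster_gc)) {
    cluster_gc <- if (n_clusters == 1L) 0.55 else seq(0.45, 0.65, length.out = n_clusters)
  }
  if (length(cluster_gc) != n_clusters) stop("length(cluster_gc) must equal n_clusters")
  if (any(cluster_gc <= 0 | cluster_gc >= 1)) stop("cluster_gc must be in (0,1)")
  if (within_cluster_divergence < 0 || within_cluster_divergence > 0.3)
    stop("within_cluster_divergence must be in [0, 0.3]")
  if (dtr_length_bp < 0) stop("dtr_length_bp must be >= 0")
  if (dtr_length_bp >= genome_length_bp / 2) stop("dtr_length_bp must be < genome_length/2")
  if (!is.null(implant_plan)) {
    implant_plan <- as.data.frame(implant_plan)
    stopifnot(all(c("cluster", "gene", "copies", "aa_divergence") %in% names(implant_plan)))
    if (!all(implant_plan$gene %in% c("whiB-like", "lsr2-like")))
      stop("implant gene must be whiB-like or lsr2-like")
    if (!all(implant_plan$copies %in% 0:2)) stop("copies must be 0, 1 or 2")
    if (any(implant_plan$aa_divergence < 0 | implant_plan$aa_divergence > 0.75))
      stop("aa_divergence must be in [0, 0.75]")
    if (any(implant_plan$cluster < 1 | implant_plan$cluster > n_clusters))
      stop("implant_plan cluster index out of range")
  }
  if (at_dip$depth < 0 || at_dip$depth > 0.4) stop("at_dip depth must be in [0, 0.4]")
  if (lifestyle_odds < 0) stop("lifestyle_odds must be >= 0")
  structure(list(n_clusters = as.integer(n_clusters),
                 genomes_per_cluster = as.integer(genomes_per_cluster),
                 genome_length_bp = as.integer(genome_length_bp),
                 cluster_gc = cluster_gc,
                 within_cluster_divergence = within_cluster_divergence,
                 implant_plan = implant_plan, at_dip = at_dip,
                 dtr_length_bp = as.integer(dtr_length_bp), dtr_gc = dtr_gc,
                 lifestyle_odds = lifestyle_odds,
                 lifestyle_base_prob = lifestyle_base_prob,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.BASES <- c("A", "C", "G", "T")

.base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

.random_dna <- function(n, gc) sample(.BASES, n, replace = TRUE, prob = .base_probs(gc))

# substitute each site independently with probability p, uniform over the
# three alternative bases (no transition bias)
.mutate_dna <- function(x, p) {
  if (p <= 0) return(x)
  idx <- which(stats::runif(length(x)) < p)
  if (!length(idx)) return(x)
  cur <- match(x[idx], .BASES)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  x[idx] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
  x
}

.codon_table <- function() {
  if (is.null(.pkg_env$codons)) {
    gcode <- Biostrings::getGeneticCode("11")
    .pkg_env$codons <- split(names(gcode), unname(gcode))
  }
  .pkg_env$codons
}

# back-translate a protein at a background GC bias; codon chosen among
# synonymous codons with probability proportional to the product of base
# probabilities under that bias; initial codon forced to ATG
.back_translate <- function(protein, gc) {
  tab <- .codon_table()
  pb <- .base_probs(gc)
  names(pb) <- .BASES
  res <- character(nchar(protein))
  aas <- strsplit(protein, "")[[1]]
  for (i in seq_along(aas)) {
    cods <- tab[[aas[i]]]
    if (is.null(cods)) stop("cannot back-translate residue ", aas[i])
    w <- vapply(cods, function(cd) prod(pb[strsplit(cd, "")[[1]]]), numeric(1))
    res[i] <- sample(cods, 1L, prob = w)
  }
  res[1L] <- "ATG"
  stop_cods <- tab[["*"]]
  w <- vapply(stop_cods, function(cd) prod(pb[strsplit(cd, "")[[1]]]), numeric(1))
  paste0(paste(res, collapse = ""), sample(stop_cods, 1L, prob = w))
}

# mutate a protein to a target proportion of substituted residues;
# position 1 (initiator M) is never touched
.mutate_protein <- function(protein, divergence) {
  aas <- strsplit(protein, "")[[1]]
  nmut <- round(divergence * length(aas))
  if (nmut == 0L) return(protein)
  nmut <- min(nmut, length(aas) - 1L)
  pos <- sample(2:length(aas), nmut)
  alphabet <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  for (p in pos) aas[p] <- sample(setdiff(alphabet, aas[p]), 1L)
  paste(aas, collapse = "")
}

#' Bundled synthetic query/annotation protein libraries
#'
#' Loads one of the synthetic protein family libraries shipped with the
#' package (constructed stand-ins, not curated natural sequences; see the
#' methods vignette).
#'
#' @param which "whib", "lsr2" or "annotation".
#' @return An \code{AAStringSet}.
#' @export
default_library <- function(which = c("whib", "lsr2", "annotation")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0(which, "_library_synthetic.faa"),
                   package = "phageTF")
  if (!nzchar(f)) stop("bundled library not found; is the package installed?")
  read_fasta(f, "protein")
}

.seed_protein <- function(gene) {
  lib <- default_library(if (gene == "whiB-like") "whib" else "lsr2")
  as.character(lib[[1L]])
}

#' Simulate a phage genome collection with ground truth
#'
#' Draws one random ancestor per cluster at that cluster's background GC,
#' derives genomes by independent per-site substitution, then implants
#' regulator ORFs per the implant plan: each implant is a back-translation
#' (GC-biased codon choice) of the family seed protein mutated to the
#' requested amino-acid divergence. lsr2-like implants get an AT-rich dip
#' (GC lowered by \code{at_dip$depth} over \code{at_dip$width_bp}) resampled
#' immediately upstream. If \code{dtr_length_bp > 0} the first and last
#' \code{dtr_length_bp} bases are identical copies and the first implant copy
#' is placed inside the repeat, so it appears twice with 100\% identity.
#' Lifestyles are Bernoulli draws whose log-odds of "temperate" are shifted
#' by \code{log(lifestyle_odds)} for implant carriers.
#'
#' Non-repeat implants keep a >= 6 kb margin from the genome ends (and from
#' the repeat region) so 5 kb context windows are always well-defined.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param seed_proteins Optional named list (whib/lsr2) of seed proteins;
#'   defaults to the first member of each bundled synthetic library.
#' @return list(genomes = DNAStringSet, metadata = data.frame, truth = list)
#'   of class "phage_sim". \code{truth$implants} holds ground-truth implant
#'   coordinates (0-based half-open), strand, divergence and in_dtr flags.
#' @export
simulate_collection <- function(config, seed_proteins = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$genome_length_bp
  if (is.null(seed_proteins)) {
    genes_needed <- unique(config$implant_plan$gene)
    seed_proteins <- list()
    if ("whiB-like" %in% genes_needed) seed_proteins$whib <- .seed_protein("whiB-like")
    if ("lsr2-like" %in% genes_needed) seed_proteins$lsr2 <- .seed_protein("lsr2-like")
  }
  genomes <- list(); meta <- list(); implants <- list()
  for (ci in seq_len(config$n_clusters)) {
    gc_bg <- config$cluster_gc[ci]
    ancestor <- .random_dna(L, gc_bg)
    plan <- config$implant_plan
    plan <- if (is.null(plan)) NULL else plan[plan$cluster == ci, , drop = FALSE]
    for (gi in seq_len(config$genomes_per_cluster)) {
      gid <- sprintf("C%d_G%02d", ci, gi)
      g <- .mutate_dna(ancestor, config$within_cluster_divergence)
      if (config$dtr_length_bp > 0L && !is.null(config$dtr_gc)) {
        g[seq_len(config$dtr_length_bp)] <- .random_dna(config$dtr_length_bp, config$dtr_gc)
      }
      reserved <- .to_iranges(integer(0), integer(0))
      dtr_implant_idx <- NA_integer_
      if (!is.null(plan) && nrow(plan)) {
        for (ri in seq_len(nrow(plan))) {
          if (plan$copies[ri] == 0L) next
          gene <- plan$gene[ri]
          seedp <- if (gene == "whiB-like") seed_proteins$whib else seed_proteins$lsr2
          if (is.null(seedp)) stop("no seed protein for ", gene)
          for (cp in seq_len(plan$copies[ri])) {
            prot <- .mutate_protein(seedp, plan$aa_divergence[ri])
            nt <- .back_translate(prot, gc_bg)
            len_nt <- nchar(nt)
            if (len_nt > L) stop("implant longer than genome")
            dip_w <- if (gene == "lsr2-like" && config$at_dip$depth > 0)
              as.integer(config$at_dip$width_bp) else 0L
            in_dtr <- config$dtr_length_bp > 0L && ri == 1L && cp == 1L
            if (in_dtr) {
              lo <- max(100L, dip_w + 50L)
              hi <- config$dtr_length_bp - len_nt - 100L
              if (hi < lo) stop("DTR too short for the implant")
              pos <- sample(lo:hi, 1L)
              strand <- "+"
            } else {
              margin <- max(6000L, config$dtr_length_bp + 500L)
              ok <- FALSE
              for (try in 1:200) {
                pos <- sample(margin:(L - margin - len_nt), 1L)
                strand <- sample(c("+", "-"), 1L)
                span_lo <- pos - if (strand == "+") dip_w else 0L
                span_hi <- pos + len_nt + if (strand == "-") dip_w else 0L
                cand <- .to_iranges(span_lo, span_hi)
                if (!any(IRanges::overlapsAny(cand, reserved))) { ok <- TRUE; break }
              }
              if (!ok) stop("could not place implant without overlap")
            }
            ins <- strsplit(if (strand == "+") nt else
              as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt))),
              "")[[1]]
            g[(pos + 1L):(pos + len_nt)] <- ins
            if (dip_w > 0L) {
              win <- if (strand == "+") c(pos - dip_w, pos) else c(pos + len_nt, pos + len_nt + dip_w)
              win[1L] <- max(0L, win[1L]); win[2L] <- min(L, win[2L])
              if (win[2L] > win[1L]) {
                g[(win[1L] + 1L):win[2L]] <-
                  .random_dna(win[2L] - win[1L], max(0.02, gc_bg - config$at_dip$depth))
              }
            }
            span_lo <- pos - if (strand == "+") dip_w else 0L
            span_hi <- pos + len_nt + if (strand == "-") dip_w else 0L
            reserved <- c(reserved, .to_iranges(max(0L, span_lo), span_hi))
            implants[[length(implants) + 1L]] <- data.frame(
              genome_id = gid, gene = gene, start = pos, end = pos + len_nt,
              strand = strand, aa_divergence = plan$aa_divergence[ri],
              copy_index = cp, in_dtr = in_dtr, protein = prot,
              stringsAsFactors = FALSE)
            if (in_dtr) dtr_implant_idx <- length(implants)
          }
        }
      }
      if (config$dtr_length_bp > 0L) {
        dtr <- config$dtr_length_bp
        g[(L - dtr + 1L):L] <- g[seq_len(dtr)]
        if (!is.na(dtr_implant_idx)) {
          dup <- implants[[dtr_implant_idx]]
          dup$start <- dup$start + (L - dtr); dup$end <- dup$end + (L - dtr)
          dup$copy_index <- dup$copy_index + 1L
          implants[[length(implants) + 1L]] <- dup
        }
      }
      genomes[[gid]] <- paste(g, collapse = "")
      meta[[gid]] <- data.frame(genome_id = gid,
                                host_genus = .HOST_GENERA[(ci - 1L) %% length(.HOST_GENERA) + 1L],
                                cluster = paste0("C", ci),
                                stringsAsFactors = FALSE)
    }
  }
  implants <- if (length(implants)) do.call(rbind, implants) else
    data.frame(genome_id = character(), gene = character(), start = integer(),
               end = integer(), strand = character(), aa_divergence = numeric(),
               copy_index = integer(), in_dtr = logical(), protein = character(),
               stringsAsFactors = FALSE)
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  carrier <- metadata$genome_id %in% implants$genome_id
  logit <- stats::qlogis(config$lifestyle_base_prob) +
    ifelse(carrier, log(config$lifestyle_odds), 0)
  metadata$lifestyle <- ifelse(stats::runif(nrow(metadata)) < stats::plogis(logit),
                               "temperate", "virulent")
  gset <- Biostrings::DNAStringSet(unlist(genomes))
  metadata$gc <- gc_fraction(gset)
  metadata$length_bp <- nchar(as.character(gset))
  truth <- list(implants = implants,
                clusters = stats::setNames(metadata$cluster, metadata$genome_id),
                genome_length = stats::setNames(metadata$length_bp, metadata$genome_id),
                carrier = stats::setNames(carrier, metadata$genome_id),
                dtr_length_bp = config$dtr_length_bp,
                config = config)
  structure(list(genomes = gset, metadata = metadata, truth = truth),
            class = "phage_sim")
}

#' @export
print.phage_sim <- function(x, ...) {
  cat("Synthetic phage collection:", length(x$genomes), "genomes,",
      length(unique(x$metadata$cluster)), "clusters,",
      nrow(x$truth$implants), "implanted loci\n")
  invisible(x)
}

.DECOY_DOMAINS <- c("Terminase_6", "Portal", "Phage_capsid", "DnaB_helicase",
                    "NADB_Rossmann", "Glycohydrolase")

#' Emit a synthetic conserved-domain hit table
#'
#' Emulates the tabular output of a domain screen over the simulated
#' collection: every true implant yields \code{redundancy} hit rows with
#' identical or slightly jittered (<= 10 bp) coordinates, one per source
#' database (Pfam, COG, Smart, TIGR), mirroring how the same domain is
#' reported by several databases at overlapping coordinates. Optional decoy
#' (non-TF) hits are added at a configurable per-genome rate.
#'
#' @param truth The \code{truth} element of a \code{\link{simulate_collection}} result.
#' @param redundancy Number of source databases reporting each true domain (1-4).
#' @param decoy_rate Expected number of decoy hits per genome.
#' @param seed Optional RNG seed for the jitter/decoys.
#' @return Data.frame: genome_id, domain_id, source_db, start, end, strand, evalue.
#' @export
emit_domain_hits <- function(truth, redundancy = 1L, decoy_rate = 0, seed = NULL) {
  if (redundancy < 1L || redundancy > 4L) stop("redundancy must be in 1..4")
  if (!is.null(seed)) set.seed(seed)
  dbs <- c("Pfam", "COG", "Smart", "TIGR")[seq_len(redundancy)]
  imp <- truth$implants
  rows <- list()
  fam <- ifelse(imp$gene == "whiB-like", "WhiB", "Lsr2")
  for (i in seq_len(nrow(imp))) {
    for (db in dbs) {
      j1 <- sample(-10:10, 1L); j2 <- sample(-10:10, 1L)
      s <- max(0L, imp$start[i] + j1)
      e <- min(truth$genome_length[[imp$genome_id[i]]], imp$end[i] + j2)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = imp$genome_id[i],
        domain_id = paste0(db, "_", fam[i]), source_db = db,
        start = s, end = e, strand = imp$strand[i],
        evalue = 10^-stats::runif(1, 6, 30), stringsAsFactors = FALSE)
    }
  }
  if (decoy_rate > 0) {
    for (gid in names(truth$genome_length)) {
      nd <- stats::rpois(1, decoy_rate)
      if (nd == 0) next
      Lg <- truth$genome_length[[gid]]
      for (k in seq_len(nd)) {
        s <- sample.int(Lg - 400L, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = gid, domain_id = sample(.DECOY_DOMAINS, 1L),
          source_db = sample(dbs, 1L), start = s, end = s + sample(200:400, 1L),
          strand = sample(c("+", "-"), 1L), evalue = 10^-stats::runif(1, 4, 10),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(genome_id = character(), domain_id = character(),
                      source_db = character(), start = integer(), end = integer(),
                      strand = character(), evalue = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
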