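# One-shot orchestration of the whole survey over a (simulated or supplied)
# genome collection, with fail-fast config validation and a run manifest.

.default_params <- function() {
  list(evalue = 1e-5, domain_evalue = 0.001, gene_pad = 500L,
       context_pad = 5000L, identity_threshold = 0.9, gc_window = 100L,
       k = 6L, prevalence_min = 10L, min_len_aa = 30L, min_overlap_fraction = 0.5,
       redundancy = 4L, decoy_rate = 0)
}

.validate_config <- function(cfg) {
  if (is.null(cfg$simulation) && is.null(cfg$inputs))
    stop("config must define either a 'simulation' or an 'inputs' block")
  if (is.null(cfg$simulation)) {
    for (f in c("genomes", "metadata")) {
      if (is.null(cfg$inputs[[f]])) stop("config inputs block is missing field '", f, "'")
      if (!file.exists(cfg$inputs[[f]])) stop("input file not found: ", cfg$inputs[[f]])
    }
  }
  for (nm in names(cfg$libraries %||% list())) {
    if (!is.null(cfg$libraries[[nm]]) && !file.exists(cfg$libraries[[nm]]))
      stop("library file not found: ", cfg$libraries[[nm]])
  }
  invisible(cfg)
}

.resolve_library <- function(cfg, which) {
  p <- cfg$libraries[[which]]
  if (is.null(p)) default_library(which) else read_fasta(p, "protein")
}

#' Run the full survey pipeline
#'
#' Executes, in order: simulation (or input loading), the domain screen
#' (filter, collapse, count matrix, co-occurrence), the alignment-free
#' whole-genome tree with cluster concordance, WhiB-like and Lsr2-like
#' homolog detection, identity clustering of the detected proteins, gene
#' trees with source-interleaving reports (when enough representatives
#' exist), genomic-context annotation with GC profiles and upstream-dip
#' detection for Lsr2 loci, and the lifestyle/GC/genome-size statistics.
#' Every stage writes TSV/newick outputs under \code{out_dir} plus a
#' manifest JSON (package version, seed, parameters, output checksums).
#' Reruns with the same config and seed are byte-identical.
#'
#' @param config Path to a YAML config or an equivalent named list. Blocks:
#'   \code{simulation} (fields of \code{\link{simulation_config}}) or
#'   \code{inputs} (genomes/metadata paths), optional \code{libraries}
#'   (whib/lsr2/annotation FASTA paths) and \code{params} overriding the
#'   defaults (evalue 1e-5, domain_evalue 0.001, pads 500/5000, identity 0.9,
#'   gc_window 100, k 6).
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides the config seed when not NULL.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_all <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  .validate_config(cfg)
  params <- utils::modifyList(.default_params(), cfg$params %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    if (!is.null(seed)) sim_args$seed <- seed
    if (!is.null(sim_args$implant_plan))
      sim_args$implant_plan <- do.call(rbind, lapply(sim_args$implant_plan, as.data.frame))
    sc <- do.call(simulation_config, sim_args)
    sim <- simulate_collection(sc)
    genomes <- sim$genomes; metadata <- sim$metadata
    results$sim <- sim
    write_fasta(genomes, file.path(out_dir, "genomes.fasta"))
    write_tsv(metadata, file.path(out_dir, "metadata.tsv"))
    jsonlite::write_json(sim$truth$implants, file.path(out_dir, "truth_implants.json"),
                         dataframe = "rows", digits = NA)
    hits <- emit_domain_hits(sim$truth, redundancy = params$redundancy,
                             decoy_rate = params$decoy_rate, seed = sc$seed + 1L)
    write_tsv(hits, file.path(out_dir, "domain_hits.tsv"))
  } else {
    genomes <- read_fasta(cfg$inputs$genomes, "dna")
    metadata <- read_metadata(cfg$inputs$metadata)
    hits <- if (!is.null(cfg$inputs$domain_hits))
      utils::read.delim(cfg$inputs$domain_hits, stringsAsFactors = FALSE) else NULL
  }
  used_seed <- if (!is.null(seed)) seed else cfg$simulation$seed %||% 1L

  message("[screen-domains] ", if (is.null(hits)) "no hit table; skipped" else
    paste0(nrow(hits), " raw hits"))
  if (!is.null(hits)) {
    filt <- filter_hits(hits, tf_domain_catalog(), params$domain_evalue)
    coll <- collapse_overlapping(filt, params$min_overlap_fraction)
    mat <- build_matrix(coll, prevalence_min = min(params$prevalence_min, length(genomes)),
                        all_genomes = names(genomes))
    write_tsv(coll, file.path(out_dir, "domain_loci.tsv"))
    write_tsv(cbind(genome_id = rownames(mat$counts), as.data.frame(mat$counts)),
              file.path(out_dir, "domain_matrix.tsv"))
    write_tsv(mat$prevalence, file.path(out_dir, "domain_prevalence.tsv"))
    if (ncol(mat$counts) >= 2L) {
      rr <- cooccurrence(mat$counts)
      write_tsv(cbind(domain = rownames(rr), as.data.frame(rr)),
                file.path(out_dir, "domain_cooccurrence.tsv"))
    }
    results$domain_matrix <- mat
  }

  message("[kmer-tree] k=", params$k, " over ", length(genomes), " genomes")
  profs <- lapply(names(genomes), function(g)
    kmer_profile(genomes[[g]], k = params$k, genome_id = g))
  dm <- jsd_matrix(profs)
  tree <- neighbor_joining(dm)
  write_newick(tree, file.path(out_dir, "genome_tree.nwk"))
  conc <- cluster_concordance(tree, metadata)
  write_tsv(conc$per_cluster, file.path(out_dir, "cluster_concordance.tsv"),
            comment = sprintf("concordant fraction: %.3f", conc$fraction))
  results$tree <- tree; results$concordance <- conc

  scans <- list()
  for (gene in c("whib", "lsr2")) {
    message("[find-homologs] ", gene)
    lib <- .resolve_library(cfg, gene)
    scan <- run_detection(genomes, lib, evalue_max = params$evalue,
                          gene_pad = params$gene_pad, context_pad = params$context_pad,
                          min_len_aa = params$min_len_aa, metadata = metadata)
    write_tsv(scan$loci, file.path(out_dir, paste0("loci_", gene, ".tsv")))
    scans[[gene]] <- scan
    pass <- scan$loci[scan$loci$passed_reciprocal, , drop = FALSE]
    if (nrow(pass) >= 2L) {
      prot <- stats::setNames(pass$protein, pass$locus_id)
      cs <- greedy_cluster(prot, params$identity_threshold)
      write_tsv(cs$clusters, file.path(out_dir, paste0("clusters_", gene, ".tsv")))
      if (length(cs$representatives) >= 4L) {
        gt <- build_gene_tree(cs$representatives,
                              groups = rep("phage", length(cs$representatives)))
        write_newick(gt, file.path(out_dir, paste0("gene_tree_", gene, ".nwk")))
      }
    }
  }
  results$scans <- scans

  message("[context] annotating Lsr2 extended loci")
  ann_lib <- .resolve_library(cfg, "annotation")
  lsr2_pass <- scans$lsr2$loci[scans$lsr2$loci$passed_reciprocal, , drop = FALSE]
  syn_rows <- list(); gc_rows <- list(); dips <- list()
  for (i in seq_len(nrow(lsr2_pass))) {
    row <- lsr2_pass[i, ]
    gseq <- as.character(genomes[[row$genome_id]])
    ctx <- substr(gseq, row$context_start + 1L, row$context_end)
    syn_rows[[i]] <- annotate_locus(ctx, ann_lib, locus_id = row$locus_id,
                                    min_len_aa = params$min_len_aa)
    prof <- gc_profile(ctx, params$gc_window, params$gc_window %/% 2L)
    gc_rows[[i]] <- data.frame(locus_id = row$locus_id, window_start = prof$starts,
                               gc = prof$gc, stringsAsFactors = FALSE)
    offset <- row$merged_start - row$context_start
    dip <- detect_gc_drop(prof, offset, upstream_span_bp = 1000L)
    dips[[i]] <- data.frame(locus_id = row$locus_id, found = dip$found,
                            dip_location = dip$dip_location,
                            dip_depth = dip$dip_depth, stringsAsFactors = FALSE)
  }
  if (length(syn_rows)) {
    write_tsv(do.call(rbind, syn_rows), file.path(out_dir, "synteny_lsr2.tsv"))
    write_tsv(do.call(rbind, gc_rows), file.path(out_dir, "gc_profiles_lsr2.tsv"))
    write_tsv(do.call(rbind, dips), file.path(out_dir, "gc_dips_lsr2.tsv"))
  }

  message("[stats] lifestyle / GC / genome size")
  if (all(c("gc", "length_bp") %in% names(metadata))) {
    for (gene in names(scans)) {
      enr <- lifestyle_enrichment(scans[[gene]], metadata)
      write_tsv(enr$proportions, file.path(out_dir, paste0("lifestyle_", gene, ".tsv")),
                comment = sprintf("temperate:virulent ratio: %s",
                                  format(enr$ratio_temperate_virulent)))
      cmp <- compare_gc_size(metadata, scans[[gene]])
      if (nrow(cmp)) write_tsv(cmp, file.path(out_dir, paste0("stats_", gene, ".tsv")))
    }
  }

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(package = "phageTF",
                   version = as.character(utils::packageVersion("phageTF")),
                   seed = used_seed, params = params,
                   outputs = as.list(tools::md5sum(file.path(out_dir, sort(files)))))
  names(manifest$outputs) <- sort(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
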