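# The generator is the ground-truth source for every downstream recovery
# test, so its own statistical contracts are checked here on small genomes.

test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(n_clusters = 2, genomes_per_cluster = 3,
                           genome_length_bp = 15000,
                           implant_plan = data.frame(cluster = 1, gene = "whiB-like",
                                                     copies = 1, aa_divergence = 0.2),
                           seed = 7)
  a <- simulate_collection(cfg)
  b <- simulate_collection(cfg)
  expect_identical(as.character(a$genomes), as.character(b$genomes))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$implants, b$truth$implants)
})

test_that("zero-divergence implants translate exactly to the seed protein", {
  cfg <- simulation_config(n_clusters = 1, genomes_per_cluster = 2,
                           genome_length_bp = 15000,
                           implant_plan = data.frame(cluster = 1, gene = "lsr2-like",
                                                     copies = 1, aa_divergence = 0),
                           seed = 3)
  sim <- simulate_collection(cfg)
  seed_prot <- as.character(default_library("lsr2")[[1]])
  for (i in seq_len(nrow(sim$truth$implants))) {
    imp <- sim$truth$implants[i, ]
    g <- as.character(sim$genomes[[imp$genome_id]])
    nt <- substr(g, imp$start + 1, imp$end)
    if (imp$strand == "-") {
      nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    }
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                             genetic.code = Biostrings::getGeneticCode("11")))
    expect_equal(sub("\\*$", "", aa), seed_prot)
  }
})

test_that("requested amino-acid divergence is realized within 5 percentage points", {
  cfg <- simulation_config(n_clusters = 1, genomes_per_cluster = 4,
                           genome_length_bp = 15000,
                           implant_plan = data.frame(cluster = 1, gene = "whiB-like",
                                                     copies = 1, aa_divergence = 0.3),
                           seed = 5)
  sim <- simulate_collection(cfg)
  seed_prot <- as.character(default_library("whib")[[1]])
  for (p in sim$truth$implants$protein) {
    expect_lt(abs((1 - global_identity(p, seed_prot)) - 0.3), 0.05)
  }
})

test_that("generated genomes match the configured per-cluster GC within 0.01", {
  cfg <- simulation_config(n_clusters = 3, genomes_per_cluster = 2,
                           genome_length_bp = 50000,
                           cluster_gc = c(0.45, 0.55, 0.65), seed = 9)
  sim <- simulate_collection(cfg)
  for (ci in 1:3) {
    gcs <- sim$metadata$gc[sim$metadata$cluster == paste0("C", ci)]
    expect_lt(max(abs(gcs - cfg$cluster_gc[ci])), 0.01)
  }
})

test_that("realized within-cluster nucleotide divergence matches the substitution model", {
  p <- 0.02
  cfg <- simulation_config(n_clusters = 1, genomes_per_cluster = 4,
                           genome_length_bp = 50000,
                           within_cluster_divergence = p, seed = 13)
  sim <- simulate_collection(cfg)
  s <- as.character(sim$genomes)
  # two independent descendants of one ancestor: expected mismatch fraction
  # 2p(1-p) + p^2 * 2/3 (both mutated, may coincide with prob 1/3)
  expected <- 2 * p * (1 - p) + p^2 * 2 / 3
  for (pair in list(c(1, 2), c(3, 4))) {
    a <- strsplit(s[pair[1]], "")[[1]]; b <- strsplit(s[pair[2]], "")[[1]]
    obs <- mean(a != b)
    expect_lt(abs(obs - expected) / expected, 0.2)
  }
})

test_that("lifestyle odds enrich temperate labels among implant carriers", {
  cfg <- simulation_config(n_clusters = 2, genomes_per_cluster = 100,
                           genome_length_bp = 14000,
                           implant_plan = data.frame(cluster = 1, gene = "whiB-like",
                                                     copies = 1, aa_divergence = 0.1),
                           lifestyle_odds = 4, seed = 21)
  sim <- simulate_collection(cfg)
  md <- sim$metadata
  carrier <- sim$truth$carrier[md$genome_id]
  p_carrier <- mean(md$lifestyle[carrier] == "temperate")
  p_non <- mean(md$lifestyle[!carrier] == "temperate")
  expect_gt(p_carrier, p_non)
})

test_that("DTR duplication places two identical implant copies at the genome ends", {
  cfg <- simulation_config(n_clusters = 1, genomes_per_cluster = 1,
                           genome_length_bp = 50000, dtr_length_bp = 12000,
                           implant_plan = data.frame(cluster = 1, gene = "lsr2-like",
                                                     copies = 1, aa_divergence = 0.1),
                           seed = 17)
  sim <- simulate_collection(cfg)
  g <- as.character(sim$genomes[[1]])
  expect_identical(substr(g, 1, 12000), substr(g, 50000 - 12000 + 1, 50000))
  imp <- sim$truth$implants
  expect_equal(nrow(imp), 2L)
  expect_true(all(imp$in_dtr))
  expect_identical(imp$protein[1], imp$protein[2])
  expect_equal(imp$start[2] - imp$start[1], 50000 - 12000)
})

test_that("generator rejects invalid configurations", {
  expect_error(simulation_config(n_clusters = 2, cluster_gc = 0.5), "cluster_gc")
  expect_error(simulation_config(genome_length_bp = 10000, dtr_length_bp = 6000),
               "dtr")
  expect_error(simulation_config(within_cluster_divergence = 0.5), "divergence")
  expect_error(simulation_config(
    implant_plan = data.frame(cluster = 1, gene = "whiB-like", copies = 3,
                              aa_divergence = 0)), "copies")
})

test_that("synthetic domain hits mirror implants with database redundancy", {
  cfg <- simulation_config(n_clusters = 2, genomes_per_cluster = 3,
                           genome_length_bp = 15000,
                           implant_plan = data.frame(cluster = c(1, 2),
                                                     gene = c("whiB-like", "lsr2-like"),
                                                     copies = c(1, 2),
                                                     aa_divergence = c(0.1, 0.1)),
                           seed = 19)
  sim <- simulate_collection(cfg)
  n_imp <- nrow(sim$truth$implants)
  h1 <- emit_domain_hits(sim$truth, redundancy = 1, seed = 1)
  expect_equal(nrow(h1), n_imp)
  h4 <- emit_domain_hits(sim$truth, redundancy = 4, seed = 1)
  expect_equal(nrow(h4), 4L * n_imp)
  expect_setequal(unique(h4$source_db), c("Pfam", "COG", "Smart", "TIGR"))
  # zero decoy rate: every hit overlaps a truth implant
  imp <- sim$truth$implants
  for (i in seq_len(nrow(h4))) {
    same <- imp[imp$genome_id == h4$genome_id[i], ]
    expect_true(any(pmax(same$start, h4$start[i]) < pmin(same$end, h4$end[i])))
  }
})
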