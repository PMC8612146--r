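# Detection pipeline: translated search, ORF extraction, reciprocal filter
# and end-to-end recovery on small simulated genomes (larger-scale recovery
# rates live in the acceptance suite).

planted_genome <- function(protein, L = 12000, gc = 0.5, strand = "+", pos = 6000) {
  nt <- phageTF:::.back_translate(protein, gc)
  if (strand == "-") {
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  }
  g <- strsplit(random_dna(L, gc), "")[[1]]
  g[(pos + 1):(pos + nchar(nt))] <- strsplit(nt, "")[[1]]
  list(seq = paste(g, collapse = ""), start = pos, end = pos + nchar(nt))
}

test_that("translated search finds a planted exact back-translation with a tiny E-value", {
  set.seed(59)
  q <- paste0("M", random_protein(59))
  pg <- planted_genome(q)
  hits <- translated_search(pg$seq, c(q1 = q), evalue_max = 1e-5)
  expect_gte(nrow(hits), 1L)
  best <- hits[which.min(hits$evalue), ]
  expect_lt(best$evalue, 1e-10)
  expect_equal(best$strand, "+")
  # the hit covers the implant (up to the stop codon)
  expect_lte(abs(best$start - pg$start), 3)
  expect_lte(abs(best$end - (pg$end - 3)), 3)
})

test_that("minus-strand hits back-map so the reverse complement contains the peptide", {
  set.seed(61)
  q <- paste0("M", random_protein(59))
  pg <- planted_genome(q, strand = "-")
  hits <- translated_search(pg$seq, c(q1 = q), evalue_max = 1e-5)
  expect_gte(nrow(hits), 1L)
  best <- hits[which.min(hits$evalue), ]
  expect_equal(best$strand, "-")
  sub <- substr(pg$seq, best$start + 1, best$end)
  aa <- as.character(Biostrings::translate(
    Biostrings::reverseComplement(Biostrings::DNAString(sub)),
    genetic.code = Biostrings::getGeneticCode("11"), no.init.codon = TRUE))
  expect_true(grepl(substr(q, 5, 25), aa, fixed = TRUE))
})

test_that("two same-frame copies are both recovered via masking iterations", {
  set.seed(67)
  q <- paste0("M", random_protein(59))
  nt <- phageTF:::.back_translate(q, 0.5)
  g <- strsplit(random_dna(12000), "")[[1]]
  # same reading frame: positions congruent mod 3
  g[3001:(3000 + nchar(nt))] <- strsplit(nt, "")[[1]]
  g[9001:(9000 + nchar(nt))] <- strsplit(nt, "")[[1]]
  hits <- translated_search(paste(g, collapse = ""), c(q1 = q), evalue_max = 1e-5)
  merged <- merge_loci(transform(hits, genome_id = "g"))
  expect_equal(nrow(merged), 2L)
})

test_that("ORF extraction honors table 11 starts, both strands and the length floor", {
  # minimal ORF: ATG AAA TAA -> MK
  orfs <- find_orfs("GGGATGAAATAAGGG", min_len_aa = 2)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$protein, "MK")
  expect_equal(c(orfs$start, orfs$end), c(3, 12))
  expect_equal(orfs$strand, "+")

  # GTG start translates as initiator M
  orfs2 <- find_orfs("GTGAAATAA", min_len_aa = 2)
  expect_equal(orfs2$protein, "MK")

  # reverse-strand ORF equals forward ORF of the reverse complement
  set.seed(71)
  s <- paste0(random_dna(30), "ATG", random_protein_dna <- "", "AAACCCGGG", "TAA",
              random_dna(30))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- find_orfs(s, min_len_aa = 2)
  rev_ <- find_orfs(rc, min_len_aa = 2)
  expect_setequal(fwd$protein, rev_$protein)

  # length floor
  expect_equal(nrow(find_orfs("ATGAAATAA", min_len_aa = 50)), 0L)

  # extraction clamps to the genome
  expect_error(extract_orf_protein("ACGT", 0, 10), "outside")
})

test_that("the reciprocal filter keeps the best library match and rejects noise", {
  lib <- default_library("whib")
  member <- as.character(lib[[2]])
  set.seed(73)
  noise <- random_protein(100)
  rf <- reciprocal_filter(c(member, noise), lib, evalue_max = 1e-5)
  expect_true(rf$passed[1])
  expect_equal(rf$best_identity[1], 1.0)
  expect_equal(rf$best_query[1], names(lib)[2])
  expect_false(rf$passed[2])
  expect_true(rf$retained[1])
  expect_false(rf$retained[2])
  expect_error(reciprocal_filter(member, Biostrings::AAStringSet()), "non-empty")
})

test_that("detection recovers implanted genomes and copy numbers with no false positives", {
  cfg <- simulation_config(n_clusters = 3, genomes_per_cluster = 2,
                           genome_length_bp = 14000,
                           implant_plan = data.frame(cluster = c(1, 2),
                                                     gene = "whiB-like",
                                                     copies = c(1, 2),
                                                     aa_divergence = c(0.2, 0.3)),
                           seed = 79)
  sim <- simulate_collection(cfg)
  scan <- run_detection(sim$genomes, default_library("whib"), metadata = sim$metadata)
  truth_copies <- table(factor(sim$truth$implants$genome_id,
                               levels = names(sim$genomes)))
  expect_equal(unname(scan$copy_number), as.vector(truth_copies))
  expect_equal(scan$summary$n_carriers, 4L)
  # summary proportions normalized by group size
  byc <- scan$summary$by_cluster
  expect_equal(byc$fraction[byc$cluster == "C1"], 1)
  expect_equal(byc$fraction[byc$cluster == "C3"], 0)
})

test_that("detection pipeline output is deterministic", {
  cfg <- simulation_config(n_clusters = 1, genomes_per_cluster = 2,
                           genome_length_bp = 14000,
                           implant_plan = data.frame(cluster = 1, gene = "lsr2-like",
                                                     copies = 1, aa_divergence = 0.2),
                           seed = 83)
  sim <- simulate_collection(cfg)
  s1 <- run_detection(sim$genomes, default_library("lsr2"))
  s2 <- run_detection(sim$genomes, default_library("lsr2"))
  expect_identical(s1$loci, s2$loci)
})
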