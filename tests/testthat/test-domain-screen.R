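mk_hits <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$source_db)) df$source_db <- "Pfam"
  if (is.null(df$evalue)) df$evalue <- 1e-10
  df
}

test_that("hit filtering enforces catalog membership and the screening E-value", {
  hits <- mk_hits(genome_id = "g", domain_id = c("Pfam_WhiB", "Pfam_Lsr2", "Foo",
                                                 "Bar", "Baz"),
                  start = 0L, end = 100L, evalue = 1e-6)
  out <- filter_hits(hits, c("Pfam_WhiB", "Pfam_Lsr2"), 0.001)
  expect_equal(nrow(out), 2L)
  expect_equal(out$domain_id, c("Pfam_WhiB", "Pfam_Lsr2"))

  hits2 <- mk_hits(genome_id = "g", domain_id = "Pfam_WhiB", start = 0L,
                   end = 100L, evalue = 0.01)
  expect_equal(nrow(filter_hits(hits2, "Pfam_WhiB", 0.001)), 0L)

  expect_equal(nrow(filter_hits(hits[0, ], "Pfam_WhiB", 0.001)), 0L)
  expect_error(filter_hits(hits, character(0), 0.001), "non-empty")
})

test_that("cross-database duplicates collapse by overlap fraction of the shorter hit", {
  h <- mk_hits(genome_id = "g", domain_id = c("Pfam_WhiB", "COG_WhiB"),
               source_db = c("Pfam", "COG"), start = c(100L, 100L),
               end = c(250L, 250L), evalue = c(1e-10, 1e-8))
  cc <- collapse_overlapping(h, 0.5)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$family, "WhiB")
  expect_equal(cc$source_dbs, "COG,Pfam")

  h2 <- mk_hits(genome_id = c("g1", "g2"), domain_id = "Pfam_WhiB",
                start = 0L, end = 100L)
  expect_equal(nrow(collapse_overlapping(h2, 0.5)), 2L)

  # 0-100 and 95-200: overlap 5 of shorter 100 -> separate at 0.5, joined at 0.04
  h3 <- mk_hits(genome_id = "g", domain_id = "Pfam_WhiB",
                start = c(0L, 95L), end = c(100L, 200L))
  expect_equal(nrow(collapse_overlapping(h3, 0.5)), 2L)
  expect_equal(nrow(collapse_overlapping(h3, 0.04)), 1L)

  expect_error(collapse_overlapping(h, 0), "overlap_fraction")
  expect_error(collapse_overlapping(h, 1.5), "overlap_fraction")
})

test_that("collapsing is idempotent and labels loci by the lowest-E-value member", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    s <- sample(0:1000, n, replace = TRUE)
    h <- mk_hits(genome_id = sample(c("g1", "g2"), n, replace = TRUE),
                 domain_id = sample(c("Pfam_WhiB", "COG_Lsr2", "Smart_MerR"), n,
                                    replace = TRUE),
                 source_db = sample(c("Pfam", "COG", "Smart"), n, replace = TRUE),
                 start = s, end = s + sample(50:300, n, replace = TRUE),
                 evalue = 10^-runif(n, 4, 20))
    once <- collapse_overlapping(h, 0.5)
    twice <- collapse_overlapping(once[, c("genome_id", "family", "start", "end",
                                           "evalue", "source_dbs")] |>
                                    transform(domain_id = family,
                                              source_db = source_dbs), 0.5)
    expect_equal(nrow(twice), nrow(once))
    expect_equal(twice$start, once$start)
    expect_equal(twice$end, once$end)
  }
})

test_that("count matrix applies the prevalence filter and keeps all-zero genomes", {
  coll <- data.frame(
    genome_id = c(paste0("g", 1:9), "g1", "g1"),
    family = c(rep("Rare", 9), "WhiB", "WhiB"),
    start = 0L, end = 100L, evalue = 1e-9, stringsAsFactors = FALSE)
  m <- build_matrix(coll, prevalence_min = 10, all_genomes = paste0("g", 1:12))
  expect_false("Rare" %in% colnames(m$counts))  # present in 9 < 10 genomes
  expect_equal(nrow(m$counts), 12L)

  m2 <- build_matrix(coll, prevalence_min = 1, all_genomes = paste0("g", 1:12))
  expect_equal(m2$counts["g1", "WhiB"], 2L)     # two loci -> cell value 2
  expect_equal(unname(rowSums(m2$counts)["g12"]), 0L)
  # column sums conserve collapsed locus counts per family
  expect_equal(unname(colSums(m2$counts)[c("Rare", "WhiB")]), c(9L, 2L))
  expect_equal(m2$prevalence$fraction[m2$prevalence$family == "WhiB"], 1 / 12)
})

test_that("co-occurrence is Pearson on counts with NA for zero-variance domains", {
  cnt <- cbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1), C = c(1, 1, 0, 0),
               K = c(2, 2, 2, 2))
  r <- cooccurrence(cnt)
  expect_equal(r["A", "B"], -1)
  expect_equal(r["A", "C"], 1)
  expect_true(all(is.na(r["K", ])))
  expect_true(all(is.na(r[, "K"])))
  expect_equal(r["A", "A"], 1)
  expect_equal(r, t(r))
  expect_error(cooccurrence(cnt[, 1, drop = FALSE]), ">= 2")
})

test_that("collapsed locus counts recover implant counts at every database redundancy", {
  cfg <- simulation_config(n_clusters = 2, genomes_per_cluster = 4,
                           genome_length_bp = 15000,
                           implant_plan = data.frame(cluster = c(1, 2),
                                                     gene = c("whiB-like", "lsr2-like"),
                                                     copies = c(2, 1),
                                                     aa_divergence = 0.1),
                           seed = 29)
  sim <- simulate_collection(cfg)
  n_imp <- nrow(sim$truth$implants)
  for (r in 1:4) {
    hits <- emit_domain_hits(sim$truth, redundancy = r, seed = 100 + r)
    coll <- collapse_overlapping(filter_hits(hits, tf_domain_catalog(), 0.001), 0.5)
    expect_equal(nrow(coll), n_imp)
  }
})
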