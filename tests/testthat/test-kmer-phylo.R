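profile_of <- function(freq, k = NULL) {
  structure(list(genome_id = NULL, k = k %||% as.integer(log(length(freq), 4)),
                 freq = freq), class = "kmer_profile")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("k-mer profiles count overlapping words and skip N windows", {
  p <- kmer_profile("AAAA", k = 2)
  expect_equal(unname(p$freq["AA"]), 1)
  expect_equal(sum(p$freq), 1)

  p1 <- kmer_profile("ACGT", k = 1)
  expect_equal(unname(p1$freq[c("A", "C", "G", "T")]), rep(0.25, 4))

  pn <- kmer_profile("ACGNA", k = 2)
  expect_equal(unname(pn$freq["AC"]), 0.5)
  expect_equal(unname(pn$freq["CG"]), 0.5)
  expect_equal(sum(pn$freq > 0), 2L)

  expect_error(kmer_profile("ACG", k = 6), "shorter")
  pc <- kmer_profile("AAAT", k = 2, canonical = TRUE)
  expect_equal(unname(pc$freq["AA"] + pc$freq["TT"] + pc$freq["AT"]), 1)
})

test_that("Jensen-Shannon divergence matches direct entropy evaluation", {
  expect_equal(jsd(profile_of(c(0.3, 0.7), 1), profile_of(c(0.3, 0.7), 1)), 0)
  expect_equal(jsd(profile_of(c(1, 0), 1), profile_of(c(0, 1), 1)), 1)
  expect_equal(jsd(profile_of(c(1, 0), 1), profile_of(c(0.5, 0.5), 1)),
               0.311278, tolerance = 1e-5)
  expect_error(jsd(kmer_profile("ACGTACGT", 2), kmer_profile("ACGTACGT", 3)),
               "same k")
})

test_that("the JSD matrix is symmetric, labeled and elementwise consistent", {
  set.seed(31)
  profs <- lapply(1:5, function(i)
    kmer_profile(random_dna(2000, runif(1, 0.3, 0.7)), k = 3,
                 genome_id = paste0("g", i)))
  d <- jsd_matrix(profs, sqrt_jsd = FALSE)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], jsd(profs[[i]], profs[[j]]))
  }
  ds <- jsd_matrix(profs)
  expect_equal(ds, sqrt(d))
  profs[[2]]$genome_id <- "g1"
  expect_error(jsd_matrix(profs), "duplicate")
})

test_that("identical genomes give an all-zero distance matrix", {
  g <- random_dna(1000)
  profs <- lapply(1:3, function(i) kmer_profile(g, 4, genome_id = paste0("g", i)))
  expect_equal(max(jsd_matrix(profs)), 0)
})

test_that("neighbor joining solves the three-point problem exactly", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(neighbor_joining(d - 1), "negative")
  d2 <- d; d2[1, 2] <- 3
  expect_error(neighbor_joining(d2), "symmetric")
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(37)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    rt <- ape::rtree(n)
    rt$edge.length <- runif(nrow(rt$edge), 0.05, 1)
    dm <- ape::cophenetic.phylo(rt)
    tr <- neighbor_joining(dm)
    expect_equal(ape::dist.topo(ape::unroot(rt), tr), 0, ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)] - dm)),
              1e-9)
  }
})

test_that("equidistant taxa yield equal external branches", {
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tr <- neighbor_joining(d)
  ext <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_equal(ext, rep(ext[1], 4))
})

test_that("agreement with an independent neighbor-joining implementation", {
  set.seed(41)
  profs <- lapply(1:8, function(i)
    kmer_profile(random_dna(3000, runif(1, 0.35, 0.65)), k = 3,
                 genome_id = paste0("g", i)))
  d <- jsd_matrix(profs)
  expect_equal(ape::dist.topo(neighbor_joining(d), ape::unroot(ape::nj(d))), 0,
               ignore_attr = TRUE)
})

test_that("cluster concordance equals brute-force bipartition enumeration", {
  tr <- read_newick(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  md <- data.frame(genome_id = c("a1", "a2", "b1", "b2"),
                   cluster = c("A", "A", "B", "B"))
  expect_equal(cluster_concordance(ape::unroot(tr), md)$fraction, 1)

  trx <- read_newick(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  expect_equal(cluster_concordance(ape::unroot(trx), md)$fraction, 0)

  set.seed(43)
  for (rep in 1:10) {
    rt <- ape::unroot(ape::rtree(12))
    cl <- sample(c("X", "Y", "Z"), 12, replace = TRUE)
    md <- data.frame(genome_id = rt$tip.label, cluster = cl)
    got <- cluster_concordance(rt, md)$per_cluster
    sides <- oracle_bipartitions(rt)
    for (i in seq_len(nrow(got))) {
      members <- sort(which(cl == got$cluster[i]))
      want <- any(vapply(sides, function(s)
        identical(s, members) || identical(sort(setdiff(1:12, s)), members),
        logical(1)))
      expect_identical(got$monophyletic[i], want)
    }
  }
})

test_that("whole-genome tree separates simulated clusters perfectly", {
  cfg <- simulation_config(n_clusters = 4, genomes_per_cluster = 4,
                           genome_length_bp = 20000,
                           cluster_gc = c(0.44, 0.50, 0.56, 0.62),
                           within_cluster_divergence = 0.02, seed = 47)
  sim <- simulate_collection(cfg)
  profs <- lapply(names(sim$genomes), function(g)
    kmer_profile(sim$genomes[[g]], k = 6, genome_id = g))
  tree <- neighbor_joining(jsd_matrix(profs))
  expect_equal(cluster_concordance(tree, sim$metadata)$fraction, 1.0)
})
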