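# Independent brute-force oracles used to validate the fast implementations.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

random_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}

# Gotoh dynamic program written independently of the alignment library:
# affine gaps, a gap of length k costs open + k * ext.
oracle_global_score <- function(a, b, open = 11, ext = 1) {
  B <- phageTF::blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1); X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, 1] <- 0
  for (i in seq_len(m)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(n)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    s <- B[av[i], bv[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

oracle_local_score <- function(a, b, open = 11, ext = 1) {
  B <- phageTF::blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1); X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    s <- B[av[i], bv[j]]
    M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) + s)
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# covered-positions oracle for interval merging (bookended intervals join)
oracle_merge <- function(starts, ends) {
  if (!length(starts)) return(data.frame(start = integer(), end = integer()))
  covered <- sort(unique(unlist(mapply(function(s, e) s:(e - 1), starts, ends,
                                       SIMPLIFY = FALSE))))
  breaks <- which(diff(covered) > 1)
  run_start <- covered[c(1, breaks + 1)]
  run_end <- covered[c(breaks, length(covered))] + 1L
  data.frame(start = run_start, end = run_end)
}

# all bipartitions of an unrooted tree, by cutting each edge and flooding
oracle_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  adj <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  lapply(seq_len(nrow(tree$edge)), function(e) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    seen <- logical(nnode); seen[a] <- TRUE; stack <- b; seen[b] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in adj[[v]]) if (!seen[w] && !(v == b && w == a)) {
        if (v == b && w == a) next
        seen[w] <- TRUE; stack <- c(stack, w)
      }
    }
    sort(which(seen[seq_len(ntip)]))
  })
}

# mutate a protein at exactly round(d * len) positions (never position 1)
mutate_protein <- function(p, d) phageTF:::.mutate_protein(p, d)

tiny_sim <- function(..., seed = 1) {
  simulate_collection(simulation_config(..., seed = seed))
}
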