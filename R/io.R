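#' Read a FASTA file with strict alphabet validation
#'
#' Reads nucleotide or protein FASTA. Sequences are uppercased; for DNA,
#' \code{U} is converted to \code{T}. Record ids are the first
#' whitespace-delimited token of each header. For proteins a single trailing
#' stop symbol \code{*} is stripped before validation.
#'
#' The permitted alphabets are deliberately strict: \code{A,C,G,T,N} for DNA
#' and the 20 standard residues plus \code{X} for protein. Anything else is an
#' error reporting the record and position, so malformed inputs fail at the
#' boundary rather than deep inside an analysis.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either \code{"dna"} or \code{"protein"}.
#' @return A \code{DNAStringSet} or \code{AAStringSet} named by record id.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(raw), "[ \t]+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1L])
  seqs <- toupper(as.character(raw))
  if (alphabet == "dna") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    allowed <- "ACGTN"
  } else {
    seqs <- sub("\\*$", "", seqs)
    allowed <- "ACDEFGHIKLMNPQRSTVWYX"
  }
  bad <- regexpr(sprintf("[^%s]", allowed), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid %s character '%s' in record '%s' at position %d",
                 alphabet, substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence in record '", ids[which(nchar(seqs) == 0L)[1L]], "'")
  }
  out <- if (alphabet == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x A named \code{XStringSet} (or named character vector).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  if (is.null(names(x))) stop("sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  s <- as.character(x)
  for (i in seq_along(s)) {
    writeLines(paste0(">", names(x)[i]), con)
    n <- nchar(s[i])
    starts <- seq(1L, n, by = width)
    writeLines(substring(s[i], starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a genome metadata table
#'
#' Reads a tab-separated table with a header row. The column
#' \code{genome_id} is required; \code{host_genus}, \code{cluster} and
#' \code{lifestyle} are optional and filled with \code{NA} /
#' \code{"unknown"} when absent. Lifestyle values other than
#' \code{temperate} / \code{virulent} (case-insensitive) are mapped to
#' \code{unknown} with a warning, so e.g. a "Lytic" label from an external
#' table never silently enters the enrichment statistics.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns genome_id, host_genus, cluster, lifestyle.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  if (!"genome_id" %in% names(df)) stop("metadata is missing the genome_id column")
  for (col in c("host_genus", "cluster")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  if (!"lifestyle" %in% names(df)) df$lifestyle <- "unknown"
  ls <- tolower(as.character(df$lifestyle))
  ls[is.na(ls) | ls == ""] <- "unknown"
  bad <- !ls %in% c("temperate", "virulent", "unknown")
  if (any(bad)) {
    warning(sum(bad), " lifestyle value(s) outside {temperate, virulent} mapped to unknown (e.g. '",
            df$lifestyle[which(bad)[1L]], "')")
    ls[bad] <- "unknown"
  }
  df$lifestyle <- ls
  df[c("genome_id", "host_genus", "cluster", "lifestyle",
       setdiff(names(df), c("genome_id", "host_genus", "cluster", "lifestyle")))]
}

#' GC fraction of a DNA sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); N bases are excluded from both numerator
#' and denominator. Returns NA for an all-N (or empty) sequence.
#'
#' @param seq A \code{DNAString}, \code{DNAStringSet} or character vector.
#' @return Numeric vector of GC fractions in [0, 1].
#' @export
gc_fraction <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAStringSet(seq)
  if (inherits(seq, "DNAString")) seq <- Biostrings::DNAStringSet(list(seq))
  cnt <- Biostrings::letterFrequency(seq, letters = c("A", "C", "G", "T"))
  denom <- rowSums(cnt)
  out <- (cnt[, "G"] + cnt[, "C"]) / denom
  out[denom == 0] <- NA_real_
  unname(out)
}

# quote a newick label if it contains reserved characters
.nwk_label <- function(x) {
  needs <- grepl("[][():;,'\"[:space:]]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Write a phylogenetic tree as newick
#'
#' Serializes an \code{ape} \code{phylo} object with branch lengths at 6
#' significant digits. Leaf labels containing newick-reserved characters
#' (parentheses, commas, colons, whitespace, quotes) are single-quoted, so
#' labels such as \code{"my phage"} round-trip intact.
#'
#' @param tree A \code{phylo} object with >= 2 labeled leaves.
#' @param path Output path.
#' @param digits Significant digits for branch lengths.
#' @return The newick string, invisibly.
#' @export
write_newick <- function(tree, path, digits = 6L) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 leaves")
  if (anyNA(tree$tip.label) || any(tree$tip.label == ""))
    stop("unlabeled leaf in tree")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length")
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(v) sprintf("%.*g", digits, v)
  rec <- function(node) {
    ke <- kids[[as.character(node)]]
    if (is.null(ke)) return(.nwk_label(tree$tip.label[node]))
    parts <- vapply(ke, function(e) {
      s <- rec(tree$edge[e, 2L])
      if (!is.null(tree$edge.length)) s <- paste0(s, ":", fmt(tree$edge.length[e]))
      s
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(rec(ntip + 1L), ";")
  writeLines(txt, path)
  invisible(txt)
}

#' Read a newick tree
#'
#' Wrapper around \code{ape::read.tree} that additionally strips the
#' surrounding single quotes \code{ape} leaves on quoted labels.
#'
#' @param path Path to a newick file (or use \code{text}).
#' @param text Newick string, overriding \code{path}.
#' @return A \code{phylo} object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tr)) stop("failed to parse newick")
  qq <- grepl("^'.*'$", tr$tip.label)
  tr$tip.label[qq] <- gsub("''", "'", sub("^'(.*)'$", "\\1", tr$tip.label[qq]))
  tr
}

#' Write a table as TSV with a header row
#' @param df A data.frame.
#' @param path Output path.
#' @param comment Optional character vector of comment lines (written with '#').
#' @export
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
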