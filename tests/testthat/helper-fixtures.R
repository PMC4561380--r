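# Shared in-code fixtures for the test suite.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

mutate_dna <- function(seq, positions, to = NULL) {
  b <- strsplit(seq, "")[[1]]
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), b[p])
    b[p] <- if (is.null(to)) alt[1] else to
  }
  paste(b, collapse = "")
}

# small rooted taxonomy: root -> B1,B2; B1 -> g1,g2; g1 -> s1,s2; g2 -> s3
toy_taxonomy <- function() {
  taxonomy_tree(data.frame(
    node_id = c("root", "B1", "B2", "g1", "g2", "s1", "s2", "s3"),
    parent_id = c("root", "root", "root", "B1", "B1", "g1", "g1", "g2"),
    rank = c("root", "phylum", "phylum", "genus", "genus",
             "species", "species", "species"),
    name = c("root", "B1", "B2", "g1", "g2", "s1", "s2", "s3"),
    stringsAsFactors = FALSE))
}

# random rooted tree with n internal + leaf nodes, for LCA oracle tests
random_taxonomy <- function(n_nodes, seed) {
  set.seed(seed)
  ids <- c("root", sprintf("n%02d", seq_len(n_nodes - 1)))
  parent <- c("root",
              vapply(seq_len(n_nodes - 1), function(i)
                ids[sample.int(i, 1)], character(1)))
  taxonomy_tree(data.frame(node_id = ids, parent_id = parent,
                           rank = "clade", name = ids,
                           stringsAsFactors = FALSE))
}

# independent LCA oracle: intersect explicit root paths, pick the deepest
lca_oracle <- function(node_ids, tree) {
  paths <- lapply(unique(node_ids), function(x) tax_path(tree, x))
  depth <- lengths(paths)
  common <- paths[[which.max(depth)]]
  for (p in paths) common <- common[common %in% p]
  common[length(common)]
}

# Biostrings-based identity oracle (CD-HIT convention: identities over the
# shorter sequence), independent of the package's DP implementation
bios_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 1, gapExtension = 1)
  Biostrings::nmatch(pa) / min(nchar(a), nchar(b))
}

# brute-force greedy clustering simulation on the Biostrings oracle
greedy_oracle <- function(reads, threshold) {
  o <- order(-nchar(reads), names(reads), method = "radix")
  reads <- reads[o]
  reps <- integer(0)
  membership <- integer(length(reads))
  for (i in seq_along(reads)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (bios_identity(reads[[i]], reads[[reps[ci]]]) >= threshold) {
        membership[i] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, i); membership[i] <- length(reps) }
  }
  lapply(seq_along(reps), function(ci) names(reads)[membership == ci])
}

# blast-tab style hit row constructor
hit_row <- function(qseqid = "r1", sseqid = "s1", pident = 100,
                    length = 90, mismatch = 0, gapopen = 0, qstart = 1,
                    qend = 270, sstart = 1, send = 90, evalue = 1e-30,
                    bitscore = 180, qlen = 270) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = mismatch, gapopen = gapopen,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             evalue = evalue, bitscore = bitscore, qlen = qlen,
             stringsAsFactors = FALSE)
}
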