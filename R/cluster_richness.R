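# Greedy identity clustering of reads within a family and the richness
# statistic (clusters per retrieved read at the 97% nucleotide identity
# cut-off).

#' Greedy incremental clustering at a nucleotide-identity threshold
#'
#' Reads are processed longest-first (ties by id, ascending); each read
#' joins the first existing cluster whose representative it matches at or
#' above the identity threshold (global alignment identities over the
#' shorter sequence, the CD-HIT convention), otherwise it founds a new
#' cluster with itself as representative. Representatives are therefore
#' always the longest member. Reverse-complement matching is off by
#' default (inputs are orientation-normalised upstream) but can be
#' enabled.
#'
#' @param reads Named character vector of sequences.
#' @param threshold Identity threshold in \[0, 1\] (default 0.97).
#' @param family Optional family tag carried in the result.
#' @param check_rc Also compare against the reverse complement and use the
#'   better identity (default `FALSE`).
#' @return An object of class `cluster_set`: list with `family`,
#'   `threshold` and `clusters` (list of `list(representative, members)`).
#' @export
greedy_cluster <- function(reads, threshold = 0.97, family = NA_character_,
                           check_rc = FALSE) {
  stopifnot(length(reads) >= 1)
  if (is.null(names(reads)))
    names(reads) <- sprintf("seq_%04d", seq_along(reads))
  o <- order(-nchar(reads), names(reads), method = "radix")
  reads <- reads[o]
  reps <- integer(0)                       # indices of representatives
  membership <- integer(length(reads))
  for (i in seq_along(reads)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      rep_seq <- reads[[reps[ci]]]
      idt <- pairwise_identity(reads[[i]], rep_seq)
      if (check_rc) {
        idt <- max(idt, pairwise_identity(cpp_revcomp(reads[[i]]), rep_seq))
      }
      if (idt >= threshold) {
        membership[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      membership[i] <- length(reps)
    }
  }
  clusters <- lapply(seq_along(reps), function(ci) {
    list(representative = names(reads)[reps[ci]],
         members = names(reads)[membership == ci])
  })
  structure(list(family = family, threshold = threshold,
                 clusters = clusters, n_reads = length(reads)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %s: %d clusters / %d reads at %.0f%%\n",
              x$family, length(x$clusters), x$n_reads, 100 * x$threshold))
  invisible(x)
}

#' Richness of a clustered family
#'
#' The number of clusters at the identity cut-off divided by the number of
#' retrieved reads in the family — a within-family diversity proxy in
#' (0, 1\].
#'
#' @param cluster_set A [greedy_cluster()] result.
#' @return List with `family`, `n_clusters`, `n_reads` and `richness`.
#' @export
richness <- function(cluster_set) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  if (cluster_set$n_reads == 0) stop("no reads in cluster set")
  list(family = cluster_set$family,
       n_clusters = length(cluster_set$clusters),
       n_reads = cluster_set$n_reads,
       richness = length(cluster_set$clusters) / cluster_set$n_reads)
}
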