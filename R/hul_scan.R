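# Contig-level screening for (hemi)cellulose utilization loci: GH-contig
# selection, hotspot rules, tetranucleotide frequency vectors, fragment
# ANI and reference affiliation.

.hul_gh_families <- c("GH2", "GH3", "GH29", "GH31", "GH43", "GH92", "GH95")

#' Select contigs carrying target glycosyl hydrolase genes
#'
#' Contigs of at least `min_len` bp with at least one gene annotated to
#' one of the target GH families.
#'
#' @param contigs Named character vector of contig sequences, or a named
#'   numeric vector of contig lengths.
#' @param annotations data.frame with `contig_id`, `start`, `end`
#'   (0-based half-open), `strand`, `label`.
#' @param min_len Minimum contig length (default 5000).
#' @param families Target GH families (default GH2, GH3, GH29, GH31,
#'   GH43, GH92, GH95).
#' @return Character vector of selected contig ids.
#' @export
select_gh_contigs <- function(contigs, annotations, min_len = 5000,
                              families = .hul_gh_families) {
  lens <- if (is.character(contigs)) nchar(contigs) else contigs
  dangling <- setdiff(unique(annotations$contig_id), names(lens))
  if (length(dangling) > 0)
    stop("annotation references unknown contig(s): ",
         paste(head(dangling, 5), collapse = ", "))
  hit <- annotations$label %in% families
  ids <- unique(annotations$contig_id[hit])
  ids[lens[ids] >= min_len]
}

#' Select GH hotspot contigs (candidate utilization loci)
#'
#' Two rules, reported per contig: (1) length >= 10 kb with at least two
#' GH genes; (2) length >= 35 kb with at least one GH gene. Any GH family
#' (label `GH<n>`) counts.
#'
#' @inheritParams select_gh_contigs
#' @param min_len_2gh,min_len_1gh Size bounds of the two rules.
#' @return data.frame `contig_id`, `length`, `n_gh`, `gh_genes`
#'   (comma-separated labels), `rules` (comma-separated rule tags) — one
#'   row per selected contig.
#' @export
select_hotspots <- function(contigs, annotations, min_len_2gh = 10000,
                            min_len_1gh = 35000) {
  lens <- if (is.character(contigs)) nchar(contigs) else contigs
  dangling <- setdiff(unique(annotations$contig_id), names(lens))
  if (length(dangling) > 0)
    stop("annotation references unknown contig(s): ",
         paste(head(dangling, 5), collapse = ", "))
  is_gh <- grepl("^GH[0-9]+$", annotations$label)
  gh <- annotations[is_gh, , drop = FALSE]
  ids <- names(lens)
  n_gh <- setNames(integer(length(ids)), ids)
  tab <- table(gh$contig_id)
  n_gh[names(tab)] <- as.integer(tab)
  rule1 <- lens >= min_len_2gh & n_gh >= 2
  rule2 <- lens >= min_len_1gh & n_gh >= 1
  sel <- which(rule1 | rule2)
  if (length(sel) == 0) {
    return(data.frame(contig_id = character(0), length = numeric(0),
                      n_gh = integer(0), gh_genes = character(0),
                      rules = character(0)))
  }
  data.frame(
    contig_id = ids[sel], length = unname(lens[sel]),
    n_gh = unname(n_gh[sel]),
    gh_genes = vapply(ids[sel], function(id)
      paste(gh$label[gh$contig_id == id], collapse = ","), character(1)),
    rules = vapply(sel, function(i)
      paste(c(if (rule1[i]) "hotspot-10kb-2GH",
              if (rule2[i]) "hotspot-35kb-1GH"), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Tetranucleotide frequency vector
#'
#' Frequencies of all 256 overlapping 4-mers counted on the sequence plus
#' its reverse complement (strand-symmetric), windows containing ambiguous
#' bases skipped, normalised to sum 1.
#'
#' @param sequence Nucleotide string (length >= 4).
#' @return Named numeric vector of length 256.
#' @export
tnf_vector <- function(sequence) {
  if (nchar(sequence) < 4) stop("sequence shorter than 4 bp")
  d <- Biostrings::DNAString(sequence)
  cnt <- Biostrings::oligonucleotideFrequency(d, width = 4) +
    Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(d),
                                         width = 4)
  if (sum(cnt) == 0) stop("no unambiguous 4-mer window in sequence")
  cnt / sum(cnt)
}

#' Pearson correlation of two tetranucleotide frequency vectors
#'
#' @param vec_a,vec_b Equal-length numeric vectors (from [tnf_vector()]).
#' @return Correlation r, or `NA` (with a warning) for a zero-variance
#'   vector.
#' @export
ttnf_correlation <- function(vec_a, vec_b) {
  stopifnot(length(vec_a) == length(vec_b))
  if (sd(vec_a) == 0 || sd(vec_b) == 0) {
    warning("zero-variance tetranucleotide vector; correlation undefined")
    return(NA_real_)
  }
  cor(vec_a, vec_b)
}

#' Fragment-based average nucleotide identity (ANIb-style)
#'
#' The query contig is cut into consecutive `frag_len` pieces (the last
#' piece is kept when at least `frag_len / 2`); each piece is aligned
#' locally against the reference with the exact seeded aligner. Pieces
#' with identity >= `min_id` percent over at least `min_cov` of their
#' length count as hits; the ANI is the mean percent identity of the
#' hits and the aligned fraction is hits / pieces.
#'
#' @param query_contig,reference_genome Nucleotide strings.
#' @param frag_len Fragment length (default 1020).
#' @param min_id Minimum percent identity of a counting fragment
#'   (default 30).
#' @param min_cov Minimum aligned fraction of a fragment (default 0.70).
#' @param k,margin,band Seeding and banding parameters of the aligner.
#' @return List with `ani` (percent, `NA` when no fragment hits),
#'   `aligned_fraction` and `n_fragments`.
#' @export
anib <- function(query_contig, reference_genome, frag_len = 1020,
                 min_id = 30, min_cov = 0.70, k = 15L, margin = 100L,
                 band = 32L) {
  qlen <- nchar(query_contig)
  if (qlen < frag_len / 2)
    stop("contig shorter than half a fragment")
  starts <- seq(1, qlen, by = frag_len)
  frags <- substring(query_contig, starts,
                     pmin(qlen, starts + frag_len - 1))
  frags <- frags[nchar(frags) >= frag_len / 2]
  h <- cpp_batch_hits(frags, reference_genome, as.integer(k), 1L,
                      as.integer(margin), 1L, -1L, -2L, -1L, TRUE,
                      as.integer(band))
  idents <- rep(NA_real_, length(frags))
  if (nrow(h) > 0) {
    h <- h[order(h$query_idx, -h$score), , drop = FALSE]
    h <- h[!duplicated(h$query_idx), , drop = FALSE]
    covered <- (h$qend - h$qstart + 1) / nchar(frags[h$query_idx])
    pid <- 100 * h$identities / h$aln_length
    ok <- pid >= min_id & covered >= min_cov
    idents[h$query_idx[ok]] <- pid[ok]
  }
  hits <- !is.na(idents)
  list(ani = if (any(hits)) mean(idents[hits]) else NA_real_,
       aligned_fraction = mean(hits),
       n_fragments = length(frags))
}

#' Affiliate a contig with its best-matching reference genome
#'
#' Scores the contig against every reference by fragment ANI and
#' tetranucleotide-frequency correlation; the best reference is the one
#' with the highest ANI (ties: higher TTNF correlation, then
#' lexicographically smaller id). When no reference yields any ANI
#' fragment hit, affiliation falls back to the TTNF correlation alone and
#' is flagged.
#'
#' @param contig Nucleotide string.
#' @param reference_set Named character vector of reference genome
#'   sequences.
#' @param ... Passed to [anib()].
#' @return List with `best`, `anib`, `ttnf_r`, `by_ttnf_only` and `table`
#'   (per-reference scores).
#' @export
affiliate <- function(contig, reference_set, ...) {
  stopifnot(length(reference_set) >= 1)
  tq <- tnf_vector(contig)
  tab <- data.frame(reference = names(reference_set),
                    anib = NA_real_, aligned_fraction = NA_real_,
                    ttnf_r = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(reference_set)) {
    a <- anib(contig, reference_set[[i]], ...)
    tab$anib[i] <- a$ani
    tab$aligned_fraction[i] <- a$aligned_fraction
    tab$ttnf_r[i] <- ttnf_correlation(tq, tnf_vector(reference_set[[i]]))
  }
  by_ttnf <- all(is.na(tab$anib))
  key_ani <- ifelse(is.na(tab$anib), -Inf, tab$anib)
  o <- order(-key_ani, -tab$ttnf_r, tab$reference, method = "radix")
  best <- o[1]
  list(best = tab$reference[best], anib = tab$anib[best],
       ttnf_r = tab$ttnf_r[best], by_ttnf_only = by_ttnf, table = tab)
}

#' Mean read coverage of a contig
#'
#' Sum of aligned read bases over the contig length (overlaps counted
#' with multiplicity), the conventional "X" coverage.
#'
#' @param contig_length Contig length in bp.
#' @param read_placements data.frame with `start`, `end` (0-based
#'   half-open read placements on the contig).
#' @return Coverage in X.
#' @export
contig_read_coverage <- function(contig_length, read_placements) {
  stopifnot(contig_length > 0)
  if (nrow(read_placements) == 0) return(0)
  sum(read_placements$end - read_placements$start) / contig_length
}
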