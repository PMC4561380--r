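#' Exact pairwise alignment
#'
#' Optimal global or local alignment of two nucleotide sequences under an
#' affine gap model (Gotoh dynamic programming). A gap of length \eqn{k}
#' scores \code{gap_open + (k - 1) * gap_extend}. The traceback is
#' deterministic: on score ties the diagonal move is preferred, then the
#' vertical (query-consuming) move, then the horizontal one.
#'
#' @param seq_a,seq_b Character scalars (query and subject).
#' @param mode `"global"` or `"local"`.
#' @param match,mismatch,gap_open,gap_extend Integer scores; defaults
#'   +1/-1/-2/-1.
#' @return A list with `score`, `identities`, `aln_length` (alignment
#'   columns including gaps), `mismatches`, `gapopens`, 1-based coordinates
#'   `qstart`/`qend`/`sstart`/`send`, `identity` (identities / aln_length)
#'   and `empty` (`TRUE` for a local alignment with no positive-scoring
#'   segment).
#' @examples
#' align_pair("ACGT", "AGGT")$identities  # 3 of 4
#' @export
align_pair <- function(seq_a, seq_b, mode = c("global", "local"),
                       match = 1L, mismatch = -1L,
                       gap_open = -2L, gap_extend = -1L) {
  mode <- match.arg(mode)
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  r <- cpp_align_pair(as.character(seq_a), as.character(seq_b), mode,
                      as.integer(match), as.integer(mismatch),
                      as.integer(gap_open), as.integer(gap_extend))
  r$identity <- if (r$aln_length > 0) r$identities / r$aln_length else NA_real_
  r
}

#' Pairwise identity of two sequences
#'
#' Identities from the optimal global alignment divided by the length of
#' the shorter sequence (the CD-HIT global-identity convention used for the
#' 97% clustering threshold).
#'
#' @inheritParams align_pair
#' @return Fraction in \[0, 1\].
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1L, mismatch = -1L,
                              gap_open = -2L, gap_extend = -1L) {
  r <- align_pair(seq_a, seq_b, "global", match, mismatch,
                  gap_open, gap_extend)
  r$identities / min(nchar(seq_a), nchar(seq_b))
}

#' Seeded local alignment against a long subject
#'
#' Finds the best-supported shared k-mer diagonal, restricts the subject to
#' a window around it, and runs the exact local DP there. Returns `NULL`
#' when query and subject share no k-mer (no plausible hit).
#'
#' @inheritParams align_pair
#' @param k Seed word size (exact match).
#' @param margin Extra subject bases kept either side of the seeded window.
#' @param band Half-width of the DP band around the seeded diagonal; 0
#'   runs the full (unbanded) DP over the seeded window.
#' @return As [align_pair()], with subject coordinates on the full subject,
#'   or `NULL`.
#' @export
seeded_local <- function(seq_a, seq_b, k = 12L, margin = 50L,
                         match = 1L, mismatch = -1L,
                         gap_open = -2L, gap_extend = -1L, band = 0L) {
  r <- cpp_seeded_local(as.character(seq_a), as.character(seq_b),
                        as.integer(k), as.integer(margin),
                        as.integer(match), as.integer(mismatch),
                        as.integer(gap_open), as.integer(gap_extend),
                        as.integer(band))
  if (isTRUE(r$empty)) return(NULL)
  r$identity <- r$identities / r$aln_length
  r
}

#' Reverse complement of a nucleotide string
#' @param x Character scalar.
#' @return Character scalar.
#' @export
revcomp <- function(x) cpp_revcomp(as.character(x))
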