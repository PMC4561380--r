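# Read-level annotation: blast-tab parsing, the coverage-times-identity
# ratio filter, best-hit family assignment, the general functional filter
# and the 16S read ratio.

.blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")

#' Parse a tabular alignment file (blast-tab dialect)
#'
#' Reads a 12-column blast-tab file, or the 13-column dialect whose last
#' column is the query length in nucleotides. For 12-column input the
#' query lengths are taken from a companion FASTA of the query sequences.
#'
#' @param path Path to the tab-separated file (no header).
#' @param query_fasta Optional FASTA path supplying query lengths for
#'   12-column input.
#' @return data.frame with the 12 standard columns plus `qlen`.
#' @export
parse_tabular_hits <- function(path, query_fasta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) {
    out <- as.data.frame(setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 11)),
      c(.blast_cols, "qlen")))
    return(out)
  }
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(!(nf %in% c(12L, 13L)))
  if (length(bad) > 0)
    stop(sprintf("malformed alignment row(s) at line(s) %s of %s (12 or 13 columns expected)",
                 paste(head(bad, 5), collapse = ", "), path))
  ncol_in <- nf[1]
  if (any(nf != ncol_in))
    stop("mixed 12- and 13-column rows in ", path)
  m <- do.call(rbind, parts)
  df <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                   stringsAsFactors = FALSE)
  num_cols <- c("pident", "length", "mismatch", "gapopen", "qstart",
                "qend", "sstart", "send", "evalue", "bitscore")
  for (i in seq_along(num_cols)) df[[num_cols[i]]] <- as.numeric(m[, i + 2])
  if (ncol_in == 13L) {
    df$qlen <- as.numeric(m[, 13])
  } else {
    if (is.null(query_fasta))
      stop("12-column input needs a companion query FASTA for query lengths (first missing query: ",
           df$qseqid[1], ")")
    qs <- Biostrings::readDNAStringSet(query_fasta)
    ql <- setNames(Biostrings::width(qs), names(qs))
    miss <- setdiff(unique(df$qseqid), names(ql))
    if (length(miss) > 0)
      stop("query length missing from FASTA for: ",
           paste(head(miss, 5), collapse = ", "))
    df$qlen <- unname(ql[df$qseqid])
  }
  nn <- which(!is.finite(df$evalue) | !is.finite(df$bitscore) |
                !is.finite(df$pident))
  if (length(nn) > 0)
    stop("non-numeric fields at line(s) ",
         paste(head(nn, 5), collapse = ", "), " of ", path)
  df
}

#' Alignment coverage-times-identity ratio
#'
#' `aln_length * pct_identity / query_length_units`, where the query
#' length of a translated (protein-level) search is converted to amino
#' acids as `floor(qlen_nt / 3)` so a full-length perfect hit scores ~100;
#' nucleotide searches use the nucleotide query length unchanged.
#'
#' @param hits data.frame with `length`, `pident`, `qlen`.
#' @param translated Is the alignment a translated search? Default `TRUE`.
#' @return Numeric vector of ratios (`NA` where the unit query length
#'   is zero).
#' @export
hit_ratio <- function(hits, translated = TRUE) {
  units <- if (translated) floor(hits$qlen / 3) else hits$qlen
  ifelse(units > 0, hits$length * hits$pident / units, NA_real_)
}

#' Ratio filter for family-annotation hits
#'
#' A hit passes when its e-value is at most `evalue_max` and its
#' coverage-times-identity ratio is strictly greater than `threshold`
#' (default 30, i.e. the ratio must exceed 30%).
#'
#' @inheritParams hit_ratio
#' @param threshold Ratio threshold (strict `>`).
#' @param evalue_max E-value ceiling (default 1e-15).
#' @return Logical vector; hits with a zero-unit query length fail with a
#'   warning.
#' @export
ratio_filter <- function(hits, threshold = 30, evalue_max = 1e-15,
                         translated = TRUE) {
  r <- hit_ratio(hits, translated)
  if (anyNA(r)) {
    warning("query length under one unit for ",
            sum(is.na(r)), " hit(s); they fail the filter")
  }
  !is.na(r) & hits$evalue <= evalue_max & r > threshold
}

#' Best-hit CAZy family assignment
#'
#' Filters hits with [ratio_filter()] and keeps, per read, the hit with
#' the highest bitscore (ties: lower e-value, then lexicographically
#' smaller subject id). The family comes from the subject-to-family map;
#' the class (AA/CBM/CE/GH/GT/PL) is the family prefix.
#'
#' @param hits Parsed hit data.frame (see [parse_tabular_hits()]).
#' @param family_map data.frame with columns `subject_id` and `family`, or
#'   a named character vector.
#' @inheritParams ratio_filter
#' @return data.frame `read`, `family`, `class`, `bitscore`, `evalue`,
#'   `ratio`, `subject_id` — one row per assigned read.
#' @export
assign_best_family <- function(hits, family_map, threshold = 30,
                               evalue_max = 1e-15, translated = TRUE) {
  if (is.data.frame(family_map))
    family_map <- setNames(family_map$family, family_map$subject_id)
  keep <- ratio_filter(hits, threshold, evalue_max, translated)
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0) {
    return(data.frame(read = character(0), family = character(0),
                      class = character(0), bitscore = numeric(0),
                      evalue = numeric(0), ratio = numeric(0),
                      subject_id = character(0)))
  }
  miss <- setdiff(unique(h$sseqid), names(family_map))
  if (length(miss) > 0)
    stop("subject(s) missing from family map: ",
         paste(head(miss, 5), collapse = ", "))
  h$ratio <- hit_ratio(h, translated)
  o <- order(h$qseqid, -h$bitscore, h$evalue, h$sseqid, method = "radix")
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(h$qseqid), , drop = FALSE]
  fam <- unname(family_map[h$sseqid])
  data.frame(read = h$qseqid, family = fam, class = .cazy_class(fam),
             bitscore = h$bitscore, evalue = h$evalue, ratio = h$ratio,
             subject_id = h$sseqid, stringsAsFactors = FALSE)
}

#' General functional annotation filter
#'
#' The protein-level annotation thresholds for general (RefSeq/KEGG/SEED
#' style) searches: e-value at most 1e-15, alignment length at least 50
#' amino acids and identity at least 50%.
#'
#' @param hits data.frame with `evalue`, `length` (aa), `pident`.
#' @param evalue_max,min_len_aa,min_identity The three thresholds.
#' @return Logical vector.
#' @export
general_functional_filter <- function(hits, evalue_max = 1e-15,
                                      min_len_aa = 50, min_identity = 50) {
  hits$evalue <= evalue_max & hits$length >= min_len_aa &
    hits$pident >= min_identity
}

#' 16S rRNA read ratio
#'
#' Counts the distinct reads with at least one rRNA-reference hit passing
#' the nucleotide thresholds (e-value <= 1e-15, alignment >= 200 bp,
#' identity >= 90%) and reports the fraction of the sample's reads, plus
#' the conventional "1/N" form with `N = round(total / count)`.
#'
#' @param rrna_hits Parsed nucleotide-level hit data.frame.
#' @param total_reads Total reads in the sample (>= 1).
#' @param evalue_max,min_len,min_identity Pass thresholds.
#' @return List with `count`, `total`, `ratio` and `one_per`
#'   (`NA` when no read passes).
#' @export
rrna_ratio <- function(rrna_hits, total_reads, evalue_max = 1e-15,
                       min_len = 200, min_identity = 90) {
  stopifnot(total_reads >= 1)
  pass <- rrna_hits$evalue <= evalue_max & rrna_hits$length >= min_len &
    rrna_hits$pident >= min_identity
  count <- length(unique(rrna_hits$qseqid[pass]))
  list(count = count, total = total_reads, ratio = count / total_reads,
       one_per = if (count > 0) round(total_reads / count) else NA_real_)
}
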