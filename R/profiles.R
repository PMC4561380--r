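# Per-sample family/class profiles, relative abundances, log10 fold
# changes against the inoculum, profile correlation, sample G+C and the
# 16S-OTU-based metagenome coverage estimate.

#' Family profile of a sample
#'
#' Counts assigned reads per family and normalises by the total number of
#' matched reads (reads with at least one passing family hit), in percent.
#' Classes (AA/CBM/CE/GH/GT/PL) are rolled up by family prefix.
#'
#' @param assignments data.frame from [assign_best_family()] (columns
#'   `read`, `family`).
#' @param sample_id Sample label carried in the result.
#' @return An object of class `family_profile`: list with `sample_id`,
#'   `counts`, `total_matched`, `ra` (percent) and `class_ra`.
#' @export
relative_abundance <- function(assignments, sample_id = NA_character_) {
  if (nrow(assignments) == 0) {
    warning("no matched reads; empty profile for sample ", sample_id)
    return(structure(list(sample_id = sample_id, counts = integer(0),
                          total_matched = 0L, ra = numeric(0),
                          class_ra = numeric(0)),
                     class = "family_profile"))
  }
  counts <- table(assignments$family)
  counts <- setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  ra <- 100 * counts / total
  cls <- tapply(counts, .cazy_class(names(counts)), sum)
  class_ra <- 100 * setNames(as.numeric(cls), names(cls)) / total
  structure(list(sample_id = sample_id, counts = counts,
                 total_matched = total, ra = ra, class_ra = class_ra),
            class = "family_profile")
}

#' @export
print.family_profile <- function(x, ...) {
  cat(sprintf("<family_profile> %s: %d families, %d matched reads\n",
              x$sample_id, length(x$counts), x$total_matched))
  invisible(x)
}

#' Log10 fold change of relative abundances
#'
#' `log10(ra_sample / ra_reference)`. When either relative abundance is
#' zero the fold is undefined and reported as `NA` (no pseudocount is
#' added); reports print such entries as "n.d.".
#'
#' @param ra_sample,ra_reference Relative abundances in percent
#'   (vectorised).
#' @return Numeric vector of log10 folds (`NA` where undefined).
#' @examples
#' round(log_fold(4.806, 1.839), 3)  # 0.417
#' @export
log_fold <- function(ra_sample, ra_reference) {
  if (any(ra_sample < 0, na.rm = TRUE) ||
      any(ra_reference < 0, na.rm = TRUE))
    stop("relative abundances must be non-negative")
  out <- ifelse(ra_sample > 0 & ra_reference > 0,
                log10(ra_sample / ra_reference), NA_real_)
  out
}

#' Fold-change table of a profile against a reference profile
#'
#' @param profile,reference `family_profile` objects (the reference is
#'   typically the inoculum).
#' @return data.frame `family`, `ra_sample`, `ra_reference`,
#'   `log10_fold` over the union of families (absent family = RA 0).
#' @export
fold_change_table <- function(profile, reference) {
  fams <- sort(union(names(profile$ra), names(reference$ra)))
  rs <- setNames(numeric(length(fams)), fams)
  rr <- rs
  rs[names(profile$ra)] <- profile$ra
  rr[names(reference$ra)] <- reference$ra
  data.frame(family = fams, ra_sample = unname(rs),
             ra_reference = unname(rr),
             log10_fold = log_fold(unname(rs), unname(rr)),
             stringsAsFactors = FALSE)
}

#' Metagenome coverage estimate from 16S OTU counts
#'
#' `coverage = total_mb / (n_otus * genome_size_mb)`: the sequenced
#' megabases divided by the community genome complement implied by the
#' number of bacterial 16S OTUs at the 97% cut-off, at a reference genome
#' size of 4 Mb.
#'
#' @param total_mb Sequenced megabases (> 0; vectorised).
#' @param n_otus Number of 16S OTUs (>= 1).
#' @param genome_size_mb Reference genome size in Mb (default 4).
#' @param sample_id Optional sample labels.
#' @return data.frame with inputs, `coverage` (full precision) and
#'   `coverage_2dp`.
#' @examples
#' coverage_estimate(136.82, 338)$coverage_2dp  # 0.10
#' @export
coverage_estimate <- function(total_mb, n_otus, genome_size_mb = 4,
                              sample_id = NA_character_) {
  if (any(n_otus == 0)) stop("n_otus must be at least 1")
  stopifnot(all(total_mb > 0), all(n_otus >= 1))
  cov <- total_mb / (n_otus * genome_size_mb)
  data.frame(sample_id = sample_id, total_mb = total_mb, n_otus = n_otus,
             genome_size_mb = genome_size_mb, coverage = cov,
             coverage_2dp = round(cov, 2), stringsAsFactors = FALSE)
}

#' Squared Pearson correlation of two family profiles
#'
#' Profiles are compared over the union of their families (absent
#' families enter as zero).
#'
#' @param profile_a,profile_b `family_profile` objects or named RA
#'   vectors.
#' @return List with `r2` and `r` (the signed correlation); both `NA`
#'   when either vector has zero variance.
#' @export
profile_r2 <- function(profile_a, profile_b) {
  va <- if (inherits(profile_a, "family_profile")) profile_a$ra else
    profile_a
  vb <- if (inherits(profile_b, "family_profile")) profile_b$ra else
    profile_b
  fams <- sort(union(names(va), names(vb)))
  a <- setNames(numeric(length(fams)), fams); b <- a
  a[names(va)] <- va; b[names(vb)] <- vb
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero-variance profile; correlation undefined")
    return(list(r2 = NA_real_, r = NA_real_))
  }
  r <- cor(a, b)
  list(r2 = r^2, r = r)
}

#' G+C content of a sequence set
#'
#' `(G + C) / (A + C + G + T)`; ambiguous bases are excluded from both
#' numerator and denominator. Also reports the per-sequence mean and SD.
#'
#' @param sequences Character vector or `Biostrings::DNAStringSet`.
#' @return List with `fraction` (pooled), `per_read_mean`, `per_read_sd`.
#' @export
gc_content <- function(sequences) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(unlist(sequences))
  if (length(sequences) == 0) stop("no sequences")
  counts <- Biostrings::letterFrequency(sequences, c("A", "C", "G", "T"))
  gc <- counts[, "G"] + counts[, "C"]
  acgt <- rowSums(counts)
  if (sum(acgt) == 0) {
    warning("all bases ambiguous; G+C undefined")
    return(list(fraction = NA_real_, per_read_mean = NA_real_,
                per_read_sd = NA_real_))
  }
  per <- ifelse(acgt > 0, gc / acgt, NA_real_)
  list(fraction = sum(gc) / sum(acgt),
       per_read_mean = mean(per, na.rm = TRUE),
       per_read_sd = sd(per, na.rm = TRUE))
}

#' Top enriched families across samples
#'
#' Ranks families by their maximum log10 fold over the given samples,
#' descending; undefined folds rank last and ties break alphabetically by
#' family name.
#'
#' @param fold_matrix Numeric matrix of log10 folds, families in rows.
#' @param k Number of families to keep (default 60).
#' @return Character vector of family names, best first.
#' @export
top_enriched <- function(fold_matrix, k = 60) {
  if (is.null(dim(fold_matrix)))
    fold_matrix <- matrix(fold_matrix, ncol = 1,
                          dimnames = list(names(fold_matrix), NULL))
  mx <- apply(fold_matrix, 1, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  o <- order(-ifelse(is.na(mx), -Inf, mx), rownames(fold_matrix),
             method = "radix")
  head(rownames(fold_matrix)[o], k)
}
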