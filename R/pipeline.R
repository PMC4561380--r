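# End-to-end orchestration: configuration validation and the staged
# pipeline (assign -> profile -> enrich -> richness -> LCA -> coverage),
# writing plain-TSV artifacts so any stage can be re-driven externally.

.default_thresholds <- function() {
  list(ratio = 30, evalue = 1e-15, cluster_identity = 0.97,
       sig_p = 0.005, rrna_min_len = 200, rrna_min_identity = 90,
       genome_size_mb = 4, richness_max_reads = 150)
}

#' Validate a pipeline configuration
#'
#' Checks the run configuration (a list or a YAML file path): exactly one
#' inoculum sample, unique sample ids, resolvable paths, positive
#' thresholds. Errors are aggregated, not thrown.
#'
#' @param config List or YAML path.
#' @return Character vector of error messages (empty when valid), with
#'   attribute `warnings` for non-fatal notes.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character(0); warns <- character(0)
  smp <- config$samples
  if (is.null(smp) || length(smp) == 0) {
    errs <- c(errs, "no samples defined")
  } else {
    ids <- vapply(smp, function(s) s$sample_id %||% NA_character_,
                  character(1))
    if (anyNA(ids)) errs <- c(errs, "sample without sample_id")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup) > 0)
      errs <- c(errs, paste0("duplicate sample ids: ",
                             paste(dup, collapse = ", ")))
    roles <- vapply(smp, function(s) s$role %||% "consortium",
                    character(1))
    if (sum(roles == "inoculum") != 1)
      errs <- c(errs, "exactly one sample must have role 'inoculum'")
    for (s in smp) {
      for (f in c("reads", "family_hits", "rrna_hits")) {
        p <- s[[f]]
        if (!is.null(p) && !file.exists(p))
          errs <- c(errs, sprintf("sample %s: missing %s file '%s'",
                                  s$sample_id, f, p))
      }
    }
  }
  for (f in c("family_map", "taxonomy", "subject_taxa")) {
    p <- config$references[[f]]
    if (!is.null(p) && !file.exists(p))
      errs <- c(errs, sprintf("missing reference file '%s' (%s)", p, f))
  }
  thr <- utils::modifyList(.default_thresholds(),
                           config$thresholds %||% list())
  if (!is.numeric(thr$ratio) || thr$ratio <= 0)
    errs <- c(errs, "ratio threshold must be positive")
  if (thr$evalue <= 0) errs <- c(errs, "evalue cutoff must be positive")
  if (thr$cluster_identity <= 0 || thr$cluster_identity > 1)
    errs <- c(errs, "cluster identity must be in (0, 1]")
  nondefault <- names(config$thresholds %||% list())
  if (length(nondefault) > 0)
    warns <- c(warns, paste0("non-default thresholds: ",
                             paste(nondefault, collapse = ", ")))
  structure(errs, warnings = warns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count 16S OTUs from shotgun rRNA hits
#'
#' Shotgun fragments of one gene need not overlap each other, so OTUs are
#' counted over the reads spanning a fixed anchor window of their 16S
#' subject (emulating amplicon-region clustering): the window-aligned read
#' piece is extracted (in subject orientation) and the pieces are greedily
#' clustered at the identity threshold.
#'
#' @param reads Named character vector of read sequences.
#' @param rrna_hits Nucleotide-level hit table ([parse_tabular_hits()]
#'   columns; minus-strand hits have `sstart > send`).
#' @param window_start,window_len Anchor window on the 16S subject
#'   (1-based start, length; defaults 650/200).
#' @param threshold OTU identity cut-off (default 0.97).
#' @param evalue_max,min_len,min_identity rRNA hit pass thresholds.
#' @return List with `n_otus` and `n_anchored` (reads used).
#' @export
count_16s_otus <- function(reads, rrna_hits, window_start = 650,
                           window_len = 200, threshold = 0.97,
                           evalue_max = 1e-15, min_len = 200,
                           min_identity = 90) {
  pass <- rrna_hits$evalue <= evalue_max & rrna_hits$length >= min_len &
    rrna_hits$pident >= min_identity
  h <- rrna_hits[pass, , drop = FALSE]
  if (nrow(h) == 0) return(list(n_otus = 0L, n_anchored = 0L))
  o <- order(h$qseqid, -h$bitscore, method = "radix")
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(h$qseqid), , drop = FALSE]
  s_lo <- pmin(h$sstart, h$send)
  s_hi <- pmax(h$sstart, h$send)
  w_end <- window_start + window_len - 1
  keep <- s_lo <= window_start & s_hi >= w_end
  h <- h[keep, , drop = FALSE]
  if (nrow(h) == 0) return(list(n_otus = 0L, n_anchored = 0L))
  frags <- character(nrow(h))
  for (i in seq_len(nrow(h))) {
    r <- reads[[h$qseqid[i]]]
    if (h$sstart[i] <= h$send[i]) {
      off <- h$qstart[i] + (window_start - h$sstart[i])
      frags[i] <- substring(r, off, off + window_len - 1)
    } else {
      rr <- cpp_revcomp(r)
      qs <- nchar(r) - h$qend[i] + 1
      off <- qs + (window_start - h$send[i])
      frags[i] <- substring(rr, off, off + window_len - 1)
    }
  }
  ok <- nchar(frags) == window_len
  frags <- frags[ok]
  if (length(frags) == 0) return(list(n_otus = 0L, n_anchored = 0L))
  names(frags) <- h$qseqid[ok]
  cs <- greedy_cluster(frags, threshold = threshold, family = "16S")
  list(n_otus = length(cs$clusters), n_anchored = length(frags))
}

# orient family-assigned reads to subject strand using the translated
# table's qstart > qend convention for minus-strand hits
.oriented_family_reads <- function(reads, fam_hits, assignments, family,
                                   max_reads = 150) {
  a <- assignments[assignments$family == family, , drop = FALSE]
  if (nrow(a) == 0) return(character(0))
  a <- a[order(a$read), , drop = FALSE]
  a <- head(a, max_reads)
  key <- paste(fam_hits$qseqid, fam_hits$sseqid)
  sel <- match(paste(a$read, a$subject_id), key)
  out <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    r <- reads[[a$read[i]]]
    hi <- sel[i]
    if (!is.na(hi) && fam_hits$qstart[hi] > fam_hits$qend[hi])
      r <- cpp_revcomp(r)
    out[i] <- r
  }
  names(out) <- a$read
  out
}

#' Run the full profiling pipeline
#'
#' Sequences the stages — hit filtering and family assignment, relative
#' abundance profiles, fold changes and enrichment statistics against the
#' inoculum, per-family clustering richness, LCA taxonomy, 16S read
#' ratios, OTU-based coverage and sample G+C — and writes one TSV per
#' stage plus a parameter log under `out_dir`. Deterministic given the
#' configuration.
#'
#' @param config List or YAML path (see [validate_config()]).
#' @return (Invisibly) a list of the stage tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- validate_config(config)
  if (length(errs) > 0)
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  thr <- utils::modifyList(.default_thresholds(),
                           config$thresholds %||% list())
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fam_map <- read.table(config$references$family_map, header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
  tree <- if (!is.null(config$references$taxonomy))
    taxonomy_tree(config$references$taxonomy) else NULL
  subj_taxa <- if (!is.null(config$references$subject_taxa)) {
    st <- read.table(config$references$subject_taxa, header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
    setNames(st$taxon, st$subject_id)
  } else NULL

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  ids <- vapply(config$samples, `[[`, character(1), "sample_id")
  roles <- vapply(config$samples, function(s) s$role %||% "consortium",
                  character(1))
  inoc_id <- ids[roles == "inoculum"]

  per <- list()
  for (s in config$samples) {
    sid <- s$sample_id
    per[[sid]] <- stage(paste0("assign:", sid), {
      reads <- Biostrings::readDNAStringSet(s$reads)
      reads_chr <- setNames(as.character(reads), names(reads))
      fam <- parse_tabular_hits(s$family_hits)
      rrna <- parse_tabular_hits(s$rrna_hits)
      asg <- assign_best_family(fam, fam_map, threshold = thr$ratio,
                                evalue_max = thr$evalue)
      list(reads = reads_chr, fam = fam, rrna = rrna, asg = asg,
           profile = relative_abundance(asg, sid),
           gc = gc_content(reads)$fraction,
           rr = rrna_ratio(rrna, length(reads_chr),
                           evalue_max = thr$evalue,
                           min_len = thr$rrna_min_len,
                           min_identity = thr$rrna_min_identity))
    })
  }

  fams <- sort(unique(unlist(lapply(per, function(x) names(x$profile$ra)))))
  ra_matrix <- sapply(per, function(x) {
    v <- setNames(numeric(length(fams)), fams)
    v[names(x$profile$ra)] <- x$profile$ra
    v
  })
  ra_df <- data.frame(family = fams, ra_matrix, check.names = FALSE,
                      stringsAsFactors = FALSE)

  cons_ids <- setdiff(ids, inoc_id)
  folds <- stage("fold_change", {
    do.call(rbind, lapply(cons_ids, function(sid) {
      f <- fold_change_table(per[[sid]]$profile, per[[inoc_id]]$profile)
      cbind(sample_id = sid, f)
    }))
  })

  enrich <- stage("enrichment", {
    do.call(rbind, lapply(cons_ids, function(sid) {
      p1 <- per[[sid]]$profile; p0 <- per[[inoc_id]]$profile
      fam_u <- sort(union(names(p1$counts), names(p0$counts)))
      cnt <- data.frame(
        family = fam_u,
        x1 = as.integer(ifelse(fam_u %in% names(p1$counts),
                               p1$counts[fam_u], 0)),
        n1 = p1$total_matched,
        x2 = as.integer(ifelse(fam_u %in% names(p0$counts),
                               p0$counts[fam_u], 0)),
        n2 = p0$total_matched, stringsAsFactors = FALSE)
      cbind(sample_id = sid, enrichment_table(cnt, sig_p = thr$sig_p))
    }))
  })

  rich_fams <- config$richness_families %||% {
    fm <- tapply(folds$log10_fold, folds$family,
                 function(x) if (all(is.na(x))) NA_real_ else
                   max(x, na.rm = TRUE))
    head(top_enriched(as.matrix(fm)), 5)
  }
  rich <- stage("richness", {
    do.call(rbind, lapply(ids, function(sid) {
      do.call(rbind, lapply(rich_fams, function(f) {
        rd <- .oriented_family_reads(per[[sid]]$reads, per[[sid]]$fam,
                                     per[[sid]]$asg, f,
                                     thr$richness_max_reads)
        if (length(rd) == 0) return(NULL)
        rv <- richness(greedy_cluster(rd, thr$cluster_identity,
                                      family = f))
        data.frame(sample_id = sid, family = f,
                   n_clusters = rv$n_clusters, n_reads = rv$n_reads,
                   richness = rv$richness, stringsAsFactors = FALSE)
      }))
    }))
  })

  taxcounts <- if (!is.null(tree) && !is.null(subj_taxa)) {
    stage("lca", {
      do.call(rbind, lapply(ids, function(sid) {
        x <- per[[sid]]
        asg_reads <- x$asg$read
        h <- x$fam[x$fam$qseqid %in% asg_reads, , drop = FALSE]
        if (nrow(h) == 0) return(NULL)
        la <- lca_assign(h, subj_taxa, tree, lca_params(),
                         reads = x$reads)
        la <- apply_min_support(la, tree)
        tb <- table(la$node_id, useNA = "ifany")
        data.frame(sample_id = sid,
                   node_id = ifelse(is.na(names(tb)), "unassigned",
                                    names(tb)),
                   n_reads = as.integer(tb), stringsAsFactors = FALSE)
      }))
    })
  } else NULL

  coverage <- stage("coverage", {
    do.call(rbind, lapply(ids, function(sid) {
      x <- per[[sid]]
      ot <- count_16s_otus(x$reads, x$rrna, threshold =
                             thr$cluster_identity)
      total_mb <- sum(nchar(x$reads)) / 1e6
      cov <- if (ot$n_otus >= 1)
        coverage_estimate(total_mb, ot$n_otus, thr$genome_size_mb, sid)
      else
        data.frame(sample_id = sid, total_mb = total_mb, n_otus = 0L,
                   genome_size_mb = thr$genome_size_mb,
                   coverage = NA_real_, coverage_2dp = NA_real_)
      cov$n_anchored_reads <- ot$n_anchored
      cov
    }))
  })

  sample_stats <- data.frame(
    sample_id = ids, role = roles,
    n_reads = vapply(per, function(x) length(x$reads), numeric(1)),
    matched_reads = vapply(per, function(x) x$profile$total_matched,
                           numeric(1)),
    gc = vapply(per, function(x) x$gc, numeric(1)),
    rrna_reads = vapply(per, function(x) x$rr$count, numeric(1)),
    rrna_ratio = vapply(per, function(x) x$rr$ratio, numeric(1)),
    rrna_one_per = vapply(per, function(x) x$rr$one_per, numeric(1)),
    stringsAsFactors = FALSE)

  .write_tsv(ra_df, file.path(out_dir, "ra_matrix.tsv"))
  .write_tsv(folds, file.path(out_dir, "fold_changes.tsv"))
  .write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))
  if (!is.null(rich)) .write_tsv(rich, file.path(out_dir, "richness.tsv"))
  if (!is.null(taxcounts))
    .write_tsv(taxcounts, file.path(out_dir, "taxonomy_counts.tsv"))
  .write_tsv(coverage, file.path(out_dir, "coverage.tsv"))
  .write_tsv(sample_stats, file.path(out_dir, "sample_stats.tsv"))
  log <- c(sprintf("lignometa %s", as.character(utils::packageVersion("lignometa"))),
           sprintf("samples: %s", paste(ids, collapse = ", ")),
           sprintf("inoculum: %s", inoc_id),
           "parameters:",
           sprintf("  %s = %s", names(thr),
                   vapply(thr, format, character(1))))
  writeLines(log, file.path(out_dir, "run_log.txt"))

  invisible(list(ra_matrix = ra_df, fold_changes = folds,
                 enrichment = enrich, richness = rich,
                 taxonomy_counts = taxcounts, coverage = coverage,
                 sample_stats = sample_stats, thresholds = thr))
}
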