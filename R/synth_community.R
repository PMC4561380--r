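# Synthetic-community generator: genomes with planted gene cassettes,
# dilution-transfer abundance series, shotgun reads with known truth, and
# the alignment tables a translated/nucleotide database search would yield.

# Bundled per-family seed templates. Constant sequences: generated once per
# session from a fixed internal stream (independent of any user seed) and
# cached, so every generator call sees the same reference material.
.template_env <- new.env(parent = emptyenv())

#' Bundled gene-family template sequences
#'
#' One fixed nucleotide template per supported functional label. CAZy
#' family templates are 900 bp, accessory transport/sensing/sugar-metabolism
#' gene templates 900 bp, and the 16S rRNA template 1500 bp; all are
#' deterministic constants (same in every session).
#'
#' @return Named character vector of sequences.
#' @export
family_templates <- function() {
  if (!is.null(.template_env$templates)) return(.template_env$templates)
  fams <- c("GH1", "GH2", "GH3", "GH13", "GH20", "GH29", "GH31", "GH43",
            "GH92", "GH95", "GH117", "GT2", "GT4", "GT8", "CBM50", "PL17",
            "CE1", "TBR", "ABCT", "TCSP", "TKT", "XI", "XKN")
  out <- .with_seed(66043871L, {
    tpl <- vapply(fams, function(f) .rand_seq(900L, 0.5), character(1))
    c(tpl, rRNA16S = .rand_seq(1500L, 0.5))
  })
  .template_env$templates <- out
  out
}

#' Generate a synthetic genome with planted gene cassettes
#'
#' Intergenic bases are drawn i.i.d. with a G+C probability compensated for
#' the cassettes' own composition, so the realised genome G+C tracks
#' `gc_target`. Each cassette is filled with a genome-specific variant of
#' the bundled family template (substitution-mutated at
#' `variant_divergence`), reverse-complemented for minus-strand cassettes;
#' the forward variant is retained as that genome's reference subject so
#' alignment hits are recoverable.
#'
#' @param genome_id Identifier.
#' @param length_bp Genome length (>= 1000).
#' @param gc_target Target G+C fraction in (0, 1).
#' @param cassettes `NULL` or a data.frame with columns `start`, `end`
#'   (0-based half-open bp), `strand` (`"+"`/`"-"`) and `label` (e.g.
#'   `"GH43"`, `"TBR"`, `"rRNA16S"`).
#' @param seed Integer seed for the intergenic sequence.
#' @param taxon_path Optional character vector of taxonomy node names,
#'   root first.
#' @param variant_divergence Per-base substitution rate applied to the
#'   template when deriving this genome's cassette variants.
#' @return An object of class `genome_model`: list with `genome_id`,
#'   `taxon_path`, `length_bp`, `gc_target`, `cassettes`, `sequence` and
#'   `subjects` (data.frame `subject_id`, `label`, `sequence`).
#' @export
generate_genome <- function(genome_id, length_bp, gc_target,
                            cassettes = NULL, seed = 1L, taxon_path = NULL,
                            variant_divergence = 0.05) {
  stopifnot(length_bp >= 1000, gc_target > 0, gc_target < 1)
  if (is.null(cassettes)) {
    cassettes <- data.frame(start = integer(0), end = integer(0),
                            strand = character(0), label = character(0))
  }
  cassettes <- as.data.frame(cassettes)
  if (nrow(cassettes) > 0) {
    stopifnot(all(cassettes$end > cassettes$start),
              all(cassettes$start >= 0),
              all(cassettes$end <= length_bp))
    o <- order(cassettes$start)
    cassettes <- cassettes[o, , drop = FALSE]
    rownames(cassettes) <- NULL
    if (nrow(cassettes) > 1) {
      bad <- which(cassettes$start[-1] < cassettes$end[-nrow(cassettes)])
      if (length(bad) > 0) {
        stop(sprintf(
          "cassettes overlap in genome '%s': [%d,%d) '%s' and [%d,%d) '%s'",
          genome_id, cassettes$start[bad[1]], cassettes$end[bad[1]],
          cassettes$label[bad[1]], cassettes$start[bad[1] + 1],
          cassettes$end[bad[1] + 1], cassettes$label[bad[1] + 1]))
      }
    }
  }

  templates <- family_templates()
  unknown <- setdiff(cassettes$label, names(templates))
  if (length(unknown) > 0)
    stop("no template for label(s): ", paste(unknown, collapse = ", "))

  # per-(genome, label, copy) variant of the template, deterministic
  n_cas <- nrow(cassettes)
  variants <- character(n_cas)
  if (n_cas > 0) {
    copy_idx <- stats::ave(seq_len(n_cas), cassettes$label,
                           FUN = seq_along)
    for (i in seq_len(n_cas)) {
      lab <- cassettes$label[i]
      len <- cassettes$end[i] - cassettes$start[i]
      vseed <- (.string_seed(paste(genome_id, lab, copy_idx[i])) +
                  as.integer(seed) * 7L) %% 2147480009L
      variants[i] <- .with_seed(vseed, {
        v <- .mutate_seq(templates[[lab]], variant_divergence)
        if (nchar(v) < len) v <- strrep(v, ceiling(len / nchar(v)))
        substring(v, 1L, len)
      })
    }
    cassettes$copy <- copy_idx
  }

  cas_len <- sum(cassettes$end - cassettes$start)
  cas_gc <- if (cas_len > 0) {
    sum(vapply(variants, function(v) {
      b <- strsplit(v, "")[[1]]
      sum(b %in% c("G", "C", "g", "c"))
    }, numeric(1)))
  } else 0
  inter_len <- length_bp - cas_len
  gc_inter <- if (inter_len > 0) {
    min(0.98, max(0.02, (gc_target * length_bp - cas_gc) / inter_len))
  } else gc_target

  seq <- .with_seed(.stage_seed(seed, "genome") + .string_seed(genome_id), {
    pieces <- character(0)
    pos <- 0L
    for (i in seq_len(n_cas)) {
      if (cassettes$start[i] > pos)
        pieces <- c(pieces, .rand_seq(cassettes$start[i] - pos, gc_inter))
      v <- variants[i]
      if (identical(cassettes$strand[i], "-")) v <- cpp_revcomp(v)
      pieces <- c(pieces, v)
      pos <- cassettes$end[i]
    }
    if (pos < length_bp)
      pieces <- c(pieces, .rand_seq(length_bp - pos, gc_inter))
    paste(pieces, collapse = "")
  })

  subjects <- if (n_cas > 0) {
    data.frame(
      subject_id = sprintf("%s|%s|%d", genome_id, cassettes$label,
                           cassettes$copy),
      label = cassettes$label, sequence = variants,
      stringsAsFactors = FALSE)
  } else {
    data.frame(subject_id = character(0), label = character(0),
               sequence = character(0))
  }

  structure(list(genome_id = genome_id, taxon_path = taxon_path,
                 length_bp = length_bp, gc_target = gc_target,
                 cassettes = cassettes, sequence = seq,
                 subjects = subjects),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %s: %.0f bp, G+C target %.2f, %d cassettes\n",
              x$genome_id, x$length_bp, x$gc_target, nrow(x$cassettes)))
  invisible(x)
}

#' Deterministic dilution-transfer abundance series
#'
#' Transfer `t` abundances are proportional to
#' `inoculum * factor^t`, renormalised to sum to one — the multiplicative
#' selection model behind sequential substrate transfers.
#'
#' @param inoculum_profile Named non-negative weights summing to ~1.
#' @param fold_spec Named per-transfer multiplicative factors (genomes
#'   missing from the spec keep factor 1).
#' @param n_transfers Number of transfers to emit.
#' @return List of named weight vectors (one per transfer, names `"T1"`,
#'   `"T2"`, ...).
#' @export
build_series <- function(inoculum_profile, fold_spec, n_transfers) {
  stopifnot(n_transfers >= 1, all(inoculum_profile >= 0),
            abs(sum(inoculum_profile) - 1) < 1e-9)
  factors <- setNames(rep(1, length(inoculum_profile)),
                      names(inoculum_profile))
  factors[names(fold_spec)] <- fold_spec
  if (all(factors == 0)) stop("all fold factors are zero")
  out <- vector("list", n_transfers)
  names(out) <- paste0("T", seq_len(n_transfers))
  for (t in seq_len(n_transfers)) {
    w <- inoculum_profile * factors^t
    if (sum(w) == 0) stop("community extinct at transfer ", t)
    out[[t]] <- w / sum(w)
  }
  out
}

#' Simulate shotgun reads from a synthetic community
#'
#' Fixed-length reads with uniform start positions per genome, genomes
#' drawn by profile weight, random strand, and i.i.d. substitution errors.
#' A read inherits a cassette's functional label when at least 50% of the
#' read overlaps the cassette (ties broken by leftmost cassette).
#'
#' @param genomes List of [generate_genome()] objects.
#' @param profile Named relative weights (subset of genome ids).
#' @param n_reads Number of reads (>= 1).
#' @param read_length Read length in bp (default 272).
#' @param error_rate Per-base substitution probability in \[0, 0.2).
#' @param seed Integer seed.
#' @param id_prefix Prefix for read identifiers.
#' @return List with `reads` (named character vector), `truth` (data.frame
#'   `read_id`, `genome_id`, `start` (0-based), `strand`, `label`),
#'   `read_length` and `error_rate`.
#' @export
simulate_reads <- function(genomes, profile, n_reads, read_length = 272L,
                           error_rate = 0, seed = 1L, id_prefix = "read") {
  stopifnot(n_reads >= 1, error_rate >= 0, error_rate < 0.2)
  if (length(profile) == 0 || sum(profile) <= 0)
    stop("empty or zero-weight community profile")
  gids <- vapply(genomes, function(g) g$genome_id, character(1))
  names(genomes) <- gids
  if (!all(names(profile) %in% gids))
    stop("profile names not found among genomes: ",
         paste(setdiff(names(profile), gids), collapse = ", "))
  glens <- vapply(genomes, function(g) g$length_bp, numeric(1))
  if (any(glens[names(profile)] < read_length))
    stop("genome shorter than read length")

  w <- profile / sum(profile)
  draw <- .with_seed(.stage_seed(seed, "reads"), {
    gidx_prof <- sample.int(length(w), n_reads, replace = TRUE, prob = w)
    gsel <- match(names(w)[gidx_prof], gids)
    starts <- floor(runif(n_reads) * (glens[gsel] - read_length + 1))
    rc <- runif(n_reads) < 0.5
    n_err <- rbinom(n_reads, read_length, error_rate)
    tot <- sum(n_err)
    err_read <- rep.int(seq_len(n_reads), n_err)
    err_pos <- if (tot > 0) {
      unlist(lapply(n_err[n_err > 0L], function(k)
        sample.int(read_length, k)), use.names = FALSE)
    } else integer(0)
    err_shift <- if (tot > 0) sample.int(3L, tot, replace = TRUE) else
      integer(0)
    list(gsel = gsel, starts = as.integer(starts), rc = rc,
         err_read = err_read, err_pos = as.integer(err_pos),
         err_shift = as.integer(err_shift))
  })

  seqs <- cpp_build_reads(
    vapply(genomes, function(g) g$sequence, character(1)),
    draw$gsel, draw$starts, draw$rc, as.integer(read_length),
    draw$err_read, draw$err_pos - 1L, draw$err_shift)
  ids <- sprintf("%s_%06d", id_prefix, seq_len(n_reads))
  names(seqs) <- ids

  # truth labels via the >= 50% read-overlap rule
  labels <- rep(NA_character_, n_reads)
  min_ov <- as.integer(ceiling(read_length / 2))
  for (g in seq_along(genomes)) {
    cas <- genomes[[g]]$cassettes
    if (nrow(cas) == 0) next
    sel <- which(draw$gsel == g)
    if (length(sel) == 0) next
    rr <- IRanges::IRanges(start = draw$starts[sel] + 1L,
                           width = read_length)
    cc <- IRanges::IRanges(start = cas$start + 1L,
                           end = cas$end)
    ov <- IRanges::findOverlaps(rr, cc, minoverlap = min_ov)
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    # tie-break: widest overlap, then leftmost cassette
    ow <- IRanges::width(IRanges::pintersect(rr[qh], cc[sh]))
    o <- order(qh, -ow, sh)
    keep <- !duplicated(qh[o])
    labels[sel[qh[o][keep]]] <- cas$label[sh[o][keep]]
  }

  truth <- data.frame(
    read_id = ids, genome_id = gids[draw$gsel], start = draw$starts,
    strand = ifelse(draw$rc, "-", "+"), label = labels,
    stringsAsFactors = FALSE)
  list(reads = seqs, truth = truth, read_length = read_length,
       error_rate = error_rate)
}

# synthetic Karlin-Altschul-style e-value for an emitted hit
.synth_evalue <- function(qlen, db_len, score) {
  as.numeric(qlen) * as.numeric(db_len) * 2^(-score)
}

#' Emit tabular alignment files for a simulated read set
#'
#' Aligns every read (both orientations) against the community's CAZy
#' family reference (the genomes' cassette variants) and against the 16S
#' rRNA reference, with an exact k-mer seeded local aligner, and formats
#' the hits as 13-column blast-tab rows (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore qlen`). The
#' family table mimics a translated (protein-level) search: alignment
#' length, mismatches and subject coordinates are reported in amino acids
#' (nucleotides / 3) and minus-strand hits carry `qstart > qend`. The rRNA
#' table is nucleotide-level with `sstart > send` on the minus strand.
#' E-values follow a simple `qlen * db_len * 2^(-score)` model.
#'
#' @param sim Result of [simulate_reads()].
#' @param genomes The genome list the reads were simulated from.
#' @param k Seed word size for the aligner prefilter.
#' @param min_score Emission floor on the raw alignment score.
#' @param out_dir Optional directory; when given, writes `family_hits.tsv`,
#'   `rrna_hits.tsv` (headerless blast-tab), `family_map.tsv`,
#'   `subject_taxa.tsv`, `reads.fasta` and `truth.tsv`.
#' @return List with data.frames `family`, `rrna`, `family_map` and
#'   `subject_taxa` (taxon leaf name per subject, where known).
#' @export
emit_alignment_tables <- function(sim, genomes, k = 12L, min_score = 30L,
                                  out_dir = NULL) {
  gids <- vapply(genomes, function(g) g$genome_id, character(1))
  subj <- do.call(rbind, lapply(genomes, function(g) {
    if (nrow(g$subjects) == 0) return(NULL)
    cbind(g$subjects, genome_id = g$genome_id,
          taxon = if (!is.null(g$taxon_path))
            utils::tail(g$taxon_path, 1) else NA_character_)
  }))
  fam_subj <- subj[.is_cazy_label(subj$label), , drop = FALSE]
  rrna_subj <- subj[subj$label == "rRNA16S", , drop = FALSE]

  reads <- unname(sim$reads)
  qlen <- nchar(reads)

  format_table <- function(hits, sdf, translated) {
    if (nrow(hits) == 0) {
      return(data.frame(qseqid = character(0), sseqid = character(0),
                        pident = numeric(0), length = integer(0),
                        mismatch = integer(0), gapopen = integer(0),
                        qstart = integer(0), qend = integer(0),
                        sstart = integer(0), send = integer(0),
                        evalue = numeric(0), bitscore = numeric(0),
                        qlen = integer(0)))
    }
    db_len <- sum(nchar(sdf$sequence))
    pident <- round(100 * hits$identities / hits$aln_length, 2)
    if (translated) {
      len <- pmax(1L, hits$aln_length %/% 3L)
      mm <- hits$mismatches %/% 3L
      ss <- (hits$sstart - 1L) %/% 3L + 1L
      se <- pmax(ss, (hits$send - 1L) %/% 3L + 1L)
      qs <- ifelse(hits$strand < 0, hits$qend, hits$qstart)
      qe <- ifelse(hits$strand < 0, hits$qstart, hits$qend)
    } else {
      len <- hits$aln_length; mm <- hits$mismatches
      ss <- ifelse(hits$strand < 0, hits$send, hits$sstart)
      se <- ifelse(hits$strand < 0, hits$sstart, hits$send)
      qs <- hits$qstart; qe <- hits$qend
    }
    ql <- qlen[hits$query_idx]
    data.frame(
      qseqid = names(sim$reads)[hits$query_idx],
      sseqid = sdf$subject_id[hits$subject_idx],
      pident = pident, length = len, mismatch = mm,
      gapopen = hits$gapopens, qstart = qs, qend = qe,
      sstart = ss, send = se,
      evalue = .synth_evalue(ql, db_len, hits$score),
      bitscore = hits$score, qlen = ql, stringsAsFactors = FALSE)
  }

  fam_hits <- if (nrow(fam_subj) > 0) {
    cpp_batch_hits(reads, fam_subj$sequence, as.integer(k),
                   as.integer(min_score), 50L, 1L, -1L, -2L, -1L, TRUE, 16L)
  } else data.frame()
  rrna_hits <- if (nrow(rrna_subj) > 0) {
    cpp_batch_hits(reads, rrna_subj$sequence, as.integer(k),
                   as.integer(min_score), 50L, 1L, -1L, -2L, -1L, TRUE, 16L)
  } else data.frame()

  fam_tab <- format_table(fam_hits, fam_subj, translated = TRUE)
  rrna_tab <- format_table(rrna_hits, rrna_subj, translated = FALSE)
  fam_map <- data.frame(subject_id = fam_subj$subject_id,
                        family = fam_subj$label, stringsAsFactors = FALSE)
  subj_taxa <- data.frame(subject_id = subj$subject_id, taxon = subj$taxon,
                          stringsAsFactors = FALSE)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(fam_tab, file.path(out_dir, "family_hits.tsv"),
               col.names = FALSE)
    .write_tsv(rrna_tab, file.path(out_dir, "rrna_hits.tsv"),
               col.names = FALSE)
    .write_tsv(fam_map, file.path(out_dir, "family_map.tsv"))
    .write_tsv(subj_taxa, file.path(out_dir, "subject_taxa.tsv"))
    .write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
    writeLines(paste0(">", names(sim$reads), "\n", unname(sim$reads)),
               file.path(out_dir, "reads.fasta"))
  }
  list(family = fam_tab, rrna = rrna_tab, family_map = fam_map,
       subject_taxa = subj_taxa)
}

#' Expected relative abundances and planted log10 fold changes
#'
#' Computes, exactly from the genome models and community profiles, the
#' probability that a read carries each CAZy family label (the >= 50%
#' overlap geometry included), the implied family relative abundances
#' among CAZy-labelled reads, and the log10 fold of each transfer against
#' the inoculum. These are the planted truths the downstream profile
#' estimates are tested against.
#'
#' @param genomes List of genome models.
#' @param inoculum Named inoculum weights.
#' @param transfers List of named transfer weight vectors
#'   (from [build_series()]).
#' @param read_length Read length used in the simulation.
#' @return List with `ra` (family x sample matrix, percent) and
#'   `log10_fold` (family x transfer matrix).
#' @export
planted_family_folds <- function(genomes, inoculum, transfers,
                                 read_length = 272L) {
  gids <- vapply(genomes, function(g) g$genome_id, character(1))
  names(genomes) <- gids
  h <- as.integer(ceiling(read_length / 2))
  # label probability per genome
  probs <- lapply(genomes, function(g) {
    cas <- g$cassettes
    cas <- cas[.is_cazy_label(cas$label), , drop = FALSE]
    if (nrow(cas) == 0) return(numeric(0))
    nstart <- g$length_bp - read_length + 1
    cnt <- pmax(0, pmin(g$length_bp - read_length, cas$end - h) -
                  pmax(0, cas$start - (read_length - h)) + 1)
    tapply(cnt / nstart, cas$label, sum)
  })
  fams <- sort(unique(unlist(lapply(probs, names))))
  pmat <- sapply(gids, function(g) {
    v <- setNames(numeric(length(fams)), fams)
    v[names(probs[[g]])] <- probs[[g]]
    v
  })
  if (length(fams) == 1) pmat <- matrix(pmat, nrow = 1,
                                        dimnames = list(fams, gids))
  samples <- c(list(inoculum = inoculum), transfers)
  ra <- sapply(samples, function(w) {
    w <- w / sum(w)
    p <- as.vector(pmat[, names(w), drop = FALSE] %*% w)
    100 * p / sum(p)
  })
  rownames(ra) <- fams
  lf <- log10(ra[, -1, drop = FALSE] / ra[, 1])
  lf[!is.finite(lf)] <- NA_real_
  list(ra = ra, log10_fold = lf)
}

#' Taxonomy table for a set of genome models
#'
#' Builds a 4-column taxonomy (node_id, parent_id, rank, name) from the
#' genomes' `taxon_path`s. The root node is its own parent.
#'
#' @param genomes List of genome models carrying `taxon_path`.
#' @param ranks Rank names by depth (recycled with generic names beyond).
#' @return List with `taxonomy` (data.frame) and `leaf` (named vector
#'   genome_id -> leaf node name).
#' @export
make_taxonomy <- function(genomes,
                          ranks = c("root", "superkingdom", "phylum",
                                    "family", "genus", "species")) {
  paths <- lapply(genomes, function(g) g$taxon_path)
  if (any(vapply(paths, is.null, logical(1))))
    stop("every genome needs a taxon_path")
  nodes <- character(0); parents <- character(0); depth <- integer(0)
  for (p in paths) {
    for (i in seq_along(p)) {
      if (!(p[i] %in% nodes)) {
        nodes <- c(nodes, p[i])
        parents <- c(parents, if (i == 1) p[i] else p[i - 1])
        depth <- c(depth, i)
      }
    }
  }
  rk <- ifelse(depth <= length(ranks), ranks[depth],
               paste0("rank", depth))
  taxonomy <- data.frame(
    node_id = nodes, parent_id = parents, rank = rk, name = nodes,
    stringsAsFactors = FALSE)
  leaf <- vapply(genomes, function(g) utils::tail(g$taxon_path, 1),
                 character(1))
  names(leaf) <- vapply(genomes, function(g) g$genome_id, character(1))
  list(taxonomy = taxonomy, leaf = leaf)
}
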