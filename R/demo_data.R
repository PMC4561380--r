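# Canonical synthetic study: a soil-like inoculum plus a three-transfer
# enrichment series with planted CAZy-family folds and a G+C contrast
# (low-G+C taxa enriched), and a planted contig panel spanning the
# (hemi)cellulose utilization locus selection rules.

# lay cassettes head to tail with fixed spacers, alternating strands
.layout_cassettes <- function(labels, lengths, start = 1000L, gap = 500L) {
  n <- length(labels)
  starts <- integer(n); pos <- start
  for (i in seq_len(n)) {
    starts[i] <- pos
    pos <- pos + lengths[i] + gap
  }
  data.frame(start = starts, end = starts + lengths,
             strand = rep(c("+", "-"), length.out = n), label = labels,
             stringsAsFactors = FALSE)
}

#' Synthetic enrichment study community
#'
#' Five 30 kb genomes emulating the taxonomic and compositional structure
#' of a wheat-straw enrichment: two low-G+C Bacteroidetes (G+C targets
#' 0.38/0.42) and one Enterobacteriaceae genome (0.52) that are
#' progressively enriched (per-transfer factors 3.0, 2.2, 1.6), and two
#' high-G+C soil taxa (0.66/0.62) that are deselected (0.45, 0.30). Each
#' genome carries 900 bp CAZy-family cassettes (multiplicities chosen so
#' every family keeps a usable read depth in every sample at the default
#' 50,000 reads per sample), transport/sensing accessory genes and one
#' 1500 bp 16S cassette (per-genome variants 6% diverged so distinct
#' genomes separate at the 97% OTU cut-off). The abundance-weighted G+C
#' drops from ~0.59 in the inoculum to ~0.41 by transfer 3, mirroring the
#' enrichment of low-G+C degraders.
#'
#' @param seed Integer seed.
#' @param n_transfers Number of transfers (default 3).
#' @return List with `genomes`, `inoculum` (named weights), `fold_spec`,
#'   `transfers` (list of named weight vectors), `taxonomy`, `leaf_taxa`
#'   and `truth` (planted RA and log10 folds from
#'   [planted_family_folds()]).
#' @export
demo_community <- function(seed = 1L, n_transfers = 3L) {
  spec <- list(
    SphingoG1 = list(
      gc = 0.38, factor = 3.0,
      path = c("root", "Bacteria", "Bacteroidetes", "Sphingobacteriaceae",
               "Sphingobacterium", "Sphingobacterium sp. SG1"),
      labels = c("GH2", "GH2", "GH43", "GH92", "GH95", "CBM50", "PL17",
                 "PL17", "TBR", "ABCT", "rRNA16S")),
    PedoG1 = list(
      gc = 0.42, factor = 2.2,
      path = c("root", "Bacteria", "Bacteroidetes", "Sphingobacteriaceae",
               "Pedobacter", "Pedobacter sp. PD1"),
      labels = c("GH2", "GH43", "GH92", "GH95", "GH29", "GH29", "GH20",
                 "GH20", "TCSP", "TBR", "rRNA16S")),
    KlebsG1 = list(
      gc = 0.52, factor = 1.6,
      path = c("root", "Bacteria", "Proteobacteria", "Enterobacteriaceae",
               "Klebsiella", "Klebsiella sp. KB1"),
      labels = c("GH1", "GH1", "GH3", "GH31", "GH31", "GT2", "GH13",
                 "CBM50", "GT4", "ABCT", "rRNA16S")),
    StreptoG1 = list(
      gc = 0.66, factor = 0.45,
      path = c("root", "Bacteria", "Actinobacteria", "Streptomycetaceae",
               "Streptomyces", "Streptomyces sp. ST1"),
      labels = c("GH13", "GH13", "GT2", "GT4", "GH3", "XI", "rRNA16S")),
    AcidoG1 = list(
      gc = 0.62, factor = 0.30,
      path = c("root", "Bacteria", "Acidobacteria", "Acidobacteriaceae",
               "Acidobacterium", "Acidobacterium sp. AC1"),
      labels = c("GH13", "GT4", "GT4", "GT2", "TKT", "rRNA16S")))

  genomes <- lapply(names(spec), function(gid) {
    s <- spec[[gid]]
    lens <- ifelse(s$labels == "rRNA16S", 1500L, 900L)
    generate_genome(gid, 30000L, s$gc,
                    .layout_cassettes(s$labels, lens),
                    seed = seed, taxon_path = s$path,
                    variant_divergence = 0.06)
  })
  names(genomes) <- names(spec)

  inoculum <- c(SphingoG1 = 0.08, PedoG1 = 0.07, KlebsG1 = 0.10,
                StreptoG1 = 0.40, AcidoG1 = 0.35)
  fold_spec <- vapply(spec, function(s) s$factor, numeric(1))
  transfers <- build_series(inoculum, fold_spec, n_transfers)
  tax <- make_taxonomy(genomes)
  truth <- planted_family_folds(genomes, inoculum, transfers)

  list(genomes = genomes, inoculum = inoculum, fold_spec = fold_spec,
       transfers = transfers, taxonomy = tax$taxonomy,
       leaf_taxa = tax$leaf, truth = truth)
}

#' Planted contig panel for hotspot-rule evaluation
#'
#' Thirty contigs spanning the locus-selection rule boundaries: lengths
#' 9.9, 10, 12, 34.9, 35 and 40 kb crossed with 0-4 glycosyl hydrolase
#' genes, plus accessory (TBR/ABCT/TCSP/TKT/XI/XKN) and non-GH CAZy (GT2)
#' genes. Contigs are concatenated verbatim into three source "reference
#' genomes" (10 contigs each) so fragment-ANI against the true source is
#' 100 and unrelated references share no seed words.
#'
#' @param seed Integer seed.
#' @return List with `contigs` (named sequences), `annotations`
#'   (data.frame `contig_id`, `start`, `end`, `strand`, `label`), `truth`
#'   (per-contig length, GH count, hotspot flag, fired rules, source
#'   reference) and `references` (named sequences).
#' @export
simulate_contig_panel <- function(seed = 1L) {
  sizes <- c(9900L, 10000L, 12000L, 34900L, 35000L, 40000L)
  gh_pool <- c("GH2", "GH3", "GH29", "GH31", "GH43", "GH92", "GH95")
  acc_pool <- c("TBR", "ABCT", "TCSP", "TKT", "XI", "XKN", "GT2")
  grid <- expand.grid(size = sizes, n_gh = 0:4)
  grid <- grid[order(grid$size, grid$n_gh), ]
  n <- nrow(grid)  # 30

  contigs <- character(n); ann <- vector("list", n)
  truth <- data.frame(contig_id = sprintf("ctg%02d", seq_len(n)),
                      length = grid$size, n_gh = grid$n_gh,
                      hotspot = NA, rules = NA_character_,
                      source = rep(sprintf("ref%d", 1:3), length.out = n),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    n_gh <- grid$n_gh[i]
    gh <- if (n_gh > 0) gh_pool[((i + seq_len(n_gh)) %% length(gh_pool)) + 1]
          else character(0)
    acc <- acc_pool[((i + 0:1) %% length(acc_pool)) + 1]
    labels <- c(gh, acc)
    cas <- .layout_cassettes(labels, rep(900L, length(labels)))
    gc <- c(0.40, 0.45, 0.55)[((i - 1) %% 3) + 1]
    g <- generate_genome(truth$contig_id[i], grid$size[i], gc, cas,
                         seed = seed + i, variant_divergence = 0.04)
    contigs[i] <- g$sequence
    a <- g$cassettes
    ann[[i]] <- data.frame(contig_id = truth$contig_id[i],
                           start = a$start, end = a$end, strand = a$strand,
                           label = a$label, stringsAsFactors = FALSE)
  }
  names(contigs) <- truth$contig_id
  truth$hotspot <- (truth$length >= 10000 & truth$n_gh >= 2) |
    (truth$length >= 35000 & truth$n_gh >= 1)
  truth$rules <- vapply(seq_len(n), function(i) {
    r <- c(if (truth$length[i] >= 10000 && truth$n_gh[i] >= 2)
             "hotspot-10kb-2GH",
           if (truth$length[i] >= 35000 && truth$n_gh[i] >= 1)
             "hotspot-35kb-1GH")
    if (length(r) == 0) "" else paste(r, collapse = ",")
  }, character(1))

  references <- vapply(sprintf("ref%d", 1:3), function(r) {
    paste(contigs[truth$source == r], collapse = "")
  }, character(1))

  list(contigs = contigs,
       annotations = do.call(rbind, ann),
       truth = truth, references = references)
}
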