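#!/usr/bin/env Rscript
# Stage 3: within-family diversity (greedy 97% identity clustering
# richness), LCA taxonomic placement of family-assigned reads, 16S read
# ratios and the OTU-based coverage estimate.

suppressMessages(library(lignometa))

sim_dir <- "scratch/sim"
out <- "results/tables"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
samples <- c("FS1", "T1", "T2", "T3")
focus <- c("GH2", "GH43", "GH92", "GH95", "GH13")

fam_map <- read.table(file.path(sim_dir, "FS1", "family_map.tsv"),
                      header = TRUE, sep = "\t")
tree <- taxonomy_tree(file.path(sim_dir, "taxonomy.tsv"))
subj_taxa <- read.table(file.path(sim_dir, "FS1", "subject_taxa.tsv"),
                        header = TRUE, sep = "\t")
subj_taxa <- setNames(subj_taxa$taxon, subj_taxa$subject_id)

rich_rows <- NULL; tax_rows <- NULL; cov_rows <- NULL
for (s in samples) {
  reads <- Biostrings::readDNAStringSet(file.path(sim_dir, s,
                                                  "reads.fasta"))
  reads <- setNames(as.character(reads), names(reads))
  hits <- parse_tabular_hits(file.path(sim_dir, s, "family_hits.tsv"))
  rrna <- parse_tabular_hits(file.path(sim_dir, s, "rrna_hits.tsv"))
  asg <- assign_best_family(hits, fam_map)

  for (f in focus) {
    sel <- head(sort(asg$read[asg$family == f]), 80)
    if (length(sel) < 5) next
    rv <- richness(greedy_cluster(reads[sel], family = f))
    rich_rows <- rbind(rich_rows, data.frame(
      sample_id = s, family = f, n_reads = rv$n_reads,
      n_clusters = rv$n_clusters, richness = round(rv$richness, 3)))
  }

  la <- lca_assign(hits[hits$qseqid %in% asg$read, ], subj_taxa, tree,
                   lca_params(), reads = reads)
  la <- apply_min_support(la, tree)
  tb <- table(ifelse(is.na(la$node_id), "unassigned", la$node_id))
  tax_rows <- rbind(tax_rows, data.frame(
    sample_id = s, node = names(tb), rank = ifelse(
      names(tb) %in% names(tree$rank), tree$rank[names(tb)], ""),
    n_reads = as.integer(tb)))

  rr <- rrna_ratio(rrna, length(reads))
  ot <- count_16s_otus(reads, rrna)
  total_mb <- sum(nchar(reads)) / 1e6
  cov <- if (ot$n_otus >= 1)
    coverage_estimate(total_mb, ot$n_otus, sample_id = s)$coverage_2dp
  else NA_real_
  cov_rows <- rbind(cov_rows, data.frame(
    sample_id = s, rrna_one_per = rr$one_per, n_otus = ot$n_otus,
    total_mb = round(total_mb, 2), coverage = cov))
}

write.table(rich_rows, file.path(out, "richness.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tax_rows, file.path(out, "taxonomy_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cov_rows, file.path(out, "coverage.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("richness by family and sample:\n")
print(rich_rows, row.names = FALSE)
cat("\n16S ratios and OTU-based coverage:\n")
print(cov_rows, row.names = FALSE)
bacteroid <- tax_rows[tax_rows$node %in%
                        c("Sphingobacterium sp. SG1", "Pedobacter sp. PD1",
                          "Sphingobacteriaceae", "Bacteroidetes"), ]
cat("\nreads placed within Bacteroidetes lineages per sample:\n")
print(aggregate(n_reads ~ sample_id, bacteroid, sum), row.names = FALSE)
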