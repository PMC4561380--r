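test_that("generated genomes hit their G+C targets", {
  g <- generate_genome("t1", 10000, 0.5, seed = 3)
  gc <- gc_content(g$sequence)$fraction
  expect_gte(gc, 0.46)
  expect_lte(gc, 0.54)

  g2 <- generate_genome("t1", 10000, 0.5, seed = 3)
  expect_identical(g$sequence, g2$sequence)

  # law-of-large-numbers check at 100 kb by direct base counting
  g3 <- generate_genome("t2", 100000, 0.41, seed = 9)
  b <- strsplit(g3$sequence, "")[[1]]
  gc3 <- mean(b %in% c("G", "C"))
  expect_lt(abs(gc3 - 0.41), 0.02)
})

test_that("genomes with cassettes keep target G+C and reject overlaps", {
  cas <- data.frame(start = c(1000L, 3000L), end = c(1900L, 3900L),
                    strand = c("+", "-"), label = c("GH43", "GH2"))
  g <- generate_genome("t3", 60000, 0.41, cas, seed = 5)
  expect_lt(abs(gc_content(g$sequence)$fraction - 0.41), 0.02)
  # minus-strand cassette appears reverse-complemented in the genome
  v <- g$subjects$sequence[g$subjects$label == "GH2"]
  expect_equal(substring(g$sequence, 3001, 3900), revcomp(v))
  v43 <- g$subjects$sequence[g$subjects$label == "GH43"]
  expect_equal(substring(g$sequence, 1001, 1900), v43)

  bad <- data.frame(start = c(1000L, 1500L), end = c(1900L, 2400L),
                    strand = "+", label = c("GH43", "GH2"))
  expect_error(generate_genome("t4", 10000, 0.5, bad), "overlap")
})

test_that("dilution series follows the multiplicative model", {
  inoc <- c(a = 0.5, b = 0.5)
  same <- build_series(inoc, c(a = 1, b = 1), 3)
  for (tr in same) expect_equal(tr, inoc)

  one <- build_series(inoc, c(a = 10, b = 1), 1)
  expect_equal(unname(one$T1), c(10 / 11, 1 / 11))

  gone <- build_series(inoc, c(a = 0, b = 1), 2)
  expect_equal(unname(gone$T1["a"]), 0)
  expect_equal(unname(gone$T2["a"]), 0)

  expect_error(build_series(inoc, c(a = 0, b = 0), 1), "zero")
})

test_that("simulated reads are faithful substrings with complete truth", {
  g1 <- generate_genome("gA", 5000, 0.45, seed = 1)
  g2 <- generate_genome("gB", 5000, 0.55, seed = 2)
  sim <- simulate_reads(list(g1, g2), c(gA = 0.8, gB = 0.2), 400,
                        read_length = 100, error_rate = 0, seed = 5)
  expect_equal(length(sim$reads), nrow(sim$truth))  # conservation
  seqs <- list(gA = g1$sequence, gB = g2$sequence)
  for (i in seq_len(50)) {
    tr <- sim$truth[i, ]
    frag <- substring(seqs[[tr$genome_id]], tr$start + 1, tr$start + 100)
    if (tr$strand == "-") frag <- revcomp(frag)
    expect_equal(unname(sim$reads[tr$read_id]), frag)
  }
  # reproducibility
  sim2 <- simulate_reads(list(g1, g2), c(gA = 0.8, gB = 0.2), 400,
                         read_length = 100, error_rate = 0, seed = 5)
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$truth, sim2$truth)
})

test_that("read origins follow the community profile", {
  g1 <- generate_genome("gA", 5000, 0.45, seed = 1)
  g2 <- generate_genome("gB", 5000, 0.55, seed = 2)
  one <- simulate_reads(list(g1, g2), c(gA = 1), 500, read_length = 100,
                        seed = 1)
  expect_true(all(one$truth$genome_id == "gA"))

  sim <- simulate_reads(list(g1, g2), c(gA = 0.8, gB = 0.2), 10000,
                        read_length = 100, error_rate = 0, seed = 7)
  frac <- mean(sim$truth$genome_id == "gA")
  sd3 <- 3 * sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(frac - 0.8), sd3)
})

test_that("sample G+C tracks the abundance-weighted genome G+C", {
  g1 <- generate_genome("gA", 30000, 0.38, seed = 1)
  g2 <- generate_genome("gB", 30000, 0.62, seed = 2)
  w <- c(gA = 0.7, gB = 0.3)
  sim <- simulate_reads(list(g1, g2), w, 20000, error_rate = 0, seed = 3)
  expected <- 0.7 * gc_content(g1$sequence)$fraction +
    0.3 * gc_content(g2$sequence)$fraction
  expect_lt(abs(gc_content(sim$reads)$fraction - expected), 0.01)
})

test_that("truth labelling uses the 50% overlap rule", {
  cas <- data.frame(start = 2000L, end = 2900L, strand = "+",
                    label = "GH43")
  g <- generate_genome("gC", 6000, 0.5, cas, seed = 4)
  sim <- simulate_reads(list(g), c(gC = 1), 3000, read_length = 272,
                        error_rate = 0, seed = 8)
  tr <- sim$truth
  ov <- pmin(2900, tr$start + 272) - pmax(2000, tr$start)
  expect_equal(!is.na(tr$label), ov >= 136)
})

test_that("emitted alignment tables recover planted annotations", {
  cas <- data.frame(start = c(1000L, 3000L, 5000L),
                    end = c(1900L, 3900L, 6500L),
                    strand = c("+", "-", "+"),
                    label = c("GH43", "GH2", "rRNA16S"))
  g <- generate_genome("gD", 9000, 0.5, cas, seed = 6)
  sim <- simulate_reads(list(g), c(gD = 1), 1500, read_length = 272,
                        error_rate = 0, seed = 9)
  tabs <- emit_alignment_tables(sim, list(g))

  fam_reads <- sim$truth$read_id[!is.na(sim$truth$label) &
                                   sim$truth$label %in% c("GH43", "GH2")]
  # fully embedded GH43 reads: best family hit is the GH43 subject
  inside43 <- sim$truth$read_id[sim$truth$start >= 1000 &
                                  sim$truth$start + 272 <= 1900]
  asg <- assign_best_family(tabs$family, tabs$family_map)
  expect_true(all(inside43 %in% asg$read))
  expect_true(all(asg$family[asg$read %in% inside43] == "GH43"))

  # intergenic reads produce no family rows
  inter <- sim$truth$read_id[is.na(sim$truth$label) &
                               (sim$truth$start + 272 <= 1000 |
                                  sim$truth$start >= 6500)]
  expect_false(any(tabs$family$qseqid %in% inter))

  # fully embedded 16S reads: nucleotide row at identity 100, length 272
  in16 <- sim$truth$read_id[sim$truth$start >= 5000 &
                              sim$truth$start + 272 <= 6500]
  rr <- tabs$rrna[tabs$rrna$qseqid %in% in16, ]
  expect_true(all(rr$pident == 100))
  expect_true(all(rr$length == 272))
})

test_that("planted fold truth matches a hand-computed two-genome case", {
  # one family per genome, equal cassette footprints
  casA <- data.frame(start = 1000L, end = 1900L, strand = "+",
                     label = "GH2")
  casB <- data.frame(start = 1000L, end = 1900L, strand = "+",
                     label = "GH43")
  gA <- generate_genome("gA", 20000, 0.5, casA, seed = 1)
  gB <- generate_genome("gB", 20000, 0.5, casB, seed = 2)
  inoc <- c(gA = 0.5, gB = 0.5)
  tr <- build_series(inoc, c(gA = 4, gB = 1), 1)
  truth <- planted_family_folds(list(gA, gB), inoc, tr)
  # equal footprints: RA ratio equals the abundance ratio
  expect_equal(unname(truth$ra[, "inoculum"]), c(50, 50))
  expect_equal(unname(truth$ra["GH2", "T1"]), 80)
  expect_equal(unname(truth$log10_fold["GH2", "T1"]), log10(80 / 50))
})
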