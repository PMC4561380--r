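mk_ann <- function(contig_id, labels) {
  n <- length(labels)
  data.frame(contig_id = contig_id, start = seq(0, by = 1000,
                                                length.out = n),
             end = seq(900, by = 1000, length.out = n), strand = "+",
             label = labels, stringsAsFactors = FALSE)
}

test_that("GH contig selection applies length and family rules", {
  lens <- c(c1 = 6000, c2 = 6000, c3 = 4900)
  ann <- rbind(mk_ann("c1", "GH43"), mk_ann("c2", "GT2"),
               mk_ann("c3", c("GH2", "GH2", "GH2")))
  sel <- select_gh_contigs(lens, ann)
  expect_equal(sel, "c1")
  expect_error(select_gh_contigs(lens, mk_ann("ghost", "GH2")),
               "unknown contig")
})

test_that("hotspot rules fire on the documented boundaries", {
  lens <- c(h1 = 12000, h2 = 9900, h3 = 40000, h4 = 35000, h5 = 10000)
  ann <- rbind(mk_ann("h1", c("GH2", "GH43")),
               mk_ann("h2", c("GH2", "GH3", "GH29", "GH31")),
               mk_ann("h3", "GH92"),
               mk_ann("h4", "GH95"),
               mk_ann("h5", c("GH2", "TBR", "GH43")))
  hs <- select_hotspots(lens, ann)
  expect_setequal(hs$contig_id, c("h1", "h3", "h4", "h5"))
  expect_equal(hs$rules[hs$contig_id == "h1"], "hotspot-10kb-2GH")
  expect_equal(hs$rules[hs$contig_id == "h3"], "hotspot-35kb-1GH")
  expect_equal(hs$n_gh[hs$contig_id == "h5"], 2L)  # TBR not a GH
})

test_that("adding a GH gene never removes a hotspot (monotone)", {
  lens <- c(m1 = 15000)
  base <- mk_ann("m1", c("GH2", "GH43"))
  more <- rbind(base, data.frame(contig_id = "m1", start = 5000,
                                 end = 5900, strand = "+", label = "GH92"))
  expect_true("m1" %in% select_hotspots(lens, base)$contig_id)
  expect_true("m1" %in% select_hotspots(lens, more)$contig_id)
})

test_that("tetranucleotide vectors are normalised and strand-symmetric", {
  set.seed(2)
  s <- rand_dna(5000)
  v <- tnf_vector(s)
  expect_equal(sum(v), 1)
  expect_equal(v, tnf_vector(revcomp(s)))

  # hand tally for ACGTACGT (self reverse-complementary: counts double)
  v8 <- tnf_vector("ACGTACGT")
  expect_equal(unname(v8["ACGT"]), 0.4)
  expect_equal(unname(v8[c("CGTA", "GTAC", "TACG")]), rep(0.2, 3),
               ignore_attr = TRUE)
  expect_equal(sum(v8 > 0), 4)

  expect_error(tnf_vector("ACG"), "shorter")
})

test_that("TTNF correlation separates same-genome from contrasting G+C", {
  g_lo <- generate_genome("lo", 40000, 0.30, seed = 1)
  g_hi <- generate_genome("hi", 40000, 0.65, seed = 2)
  cut <- substring(g_lo$sequence, 10001, 30000)
  r_same <- ttnf_correlation(tnf_vector(cut), tnf_vector(g_lo$sequence))
  r_diff <- ttnf_correlation(tnf_vector(cut), tnf_vector(g_hi$sequence))
  expect_gte(r_same, 0.9)
  expect_lt(r_diff, r_same)
  expect_equal(ttnf_correlation(tnf_vector(cut), tnf_vector(cut)), 1)
})

test_that("fragment ANI scores verbatim, diverged and unrelated contigs", {
  ref <- generate_genome("ref", 30000, 0.45, seed = 3)$sequence
  contig <- substring(ref, 5001, 15000)
  a <- anib(contig, ref)
  expect_equal(a$ani, 100)
  expect_equal(a$aligned_fraction, 1)

  set.seed(12)
  div <- mutate_dna(contig, sample(10000, 1000))  # 10% substitutions
  a2 <- anib(div, ref)
  expect_equal(a2$ani, 90, tolerance = 0.012)     # ~90 +/- 1
  expect_equal(a2$aligned_fraction, 1)

  unrelated <- generate_genome("other", 12000, 0.45, seed = 99)$sequence
  a3 <- anib(substring(unrelated, 1, 5000), ref)
  expect_lte(a3$aligned_fraction, 0.2)

  expect_error(anib(rand_dna(300), ref), "shorter")
})

test_that("affiliation ranks the source genome first", {
  src <- generate_genome("src", 30000, 0.40, seed = 4)$sequence
  other <- generate_genome("oth", 30000, 0.60, seed = 5)$sequence
  contig <- substring(src, 8001, 20000)
  af <- affiliate(contig, c(source = src, unrelated = other))
  expect_equal(af$best, "source")
  expect_equal(af$anib, 100)

  single <- affiliate(contig, c(only = other))
  expect_equal(single$best, "only")

  # equal ANI (duplicate references): lexicographic tie-break
  dup <- affiliate(contig, c(bcopy = src, acopy = src))
  expect_equal(dup$best, "acopy")
})

test_that("contig read coverage sums aligned bases", {
  expect_equal(contig_read_coverage(1000, data.frame(start = integer(0),
                                                     end = integer(0))), 0)
  expect_equal(contig_read_coverage(1000, data.frame(start = 0, end = 1000)),
               1.0)
  pl <- data.frame(start = rep(0, 10), end = rep(272, 10))
  expect_equal(contig_read_coverage(1000, pl), 2.72)
})
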