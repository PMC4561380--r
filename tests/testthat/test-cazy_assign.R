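test_that("tabular hit parsing handles 12/13 columns and bad input", {
  d <- hit_row(qlen = 272)
  f13 <- tempfile(fileext = ".tsv")
  write.table(d, f13, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  h <- parse_tabular_hits(f13)
  expect_equal(h$qlen, 272)
  expect_equal(h$qseqid, "r1")

  fe <- tempfile(); file.create(fe)
  expect_equal(nrow(parse_tabular_hits(fe)), 0)

  f12 <- tempfile(fileext = ".tsv")
  write.table(d[, 1:12], f12, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(parse_tabular_hits(f12), "FASTA")
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">r1", rand_dna(300)), fa)
  h12 <- parse_tabular_hits(f12, fa)
  expect_equal(h12$qlen, 300)

  fbad <- tempfile()
  writeLines("only\tthree\tcolumns", fbad)
  expect_error(parse_tabular_hits(fbad), "malformed")
})

test_that("ratio filter applies the strict >30 boundary in aa units", {
  # full-length perfect translated hit: 90 aa x 100 / (270/3) = 100
  expect_true(ratio_filter(hit_row(length = 90, pident = 100, qlen = 270)))
  # exact boundary 27 x 100 / 90 = 30.0 fails the strict rule
  expect_equal(hit_ratio(hit_row(length = 27, pident = 100, qlen = 270)), 30)
  expect_false(ratio_filter(hit_row(length = 27, pident = 100,
                                    qlen = 270)))
  # 60 aa x 60% / 90 = 40 passes when the e-value allows
  expect_true(ratio_filter(hit_row(length = 60, pident = 60, qlen = 270,
                                   evalue = 1e-16)))
  expect_false(ratio_filter(hit_row(length = 60, pident = 60, qlen = 270,
                                    evalue = 1e-14)))
  # degenerate query length fails with a warning
  expect_warning(ok <- ratio_filter(hit_row(qlen = 2)), "unit")
  expect_false(ok)
})

test_that("filtering is idempotent and monotone in the threshold", {
  set.seed(123)
  n <- 1000
  panel <- hit_row(qseqid = sprintf("r%04d", 1:n))
  panel$length <- sample(10:95, n, replace = TRUE)
  panel$pident <- runif(n, 20, 100)
  panel$evalue <- 10^runif(n, -60, -5)
  panel$qlen <- sample(150:300, n, replace = TRUE)

  pass1 <- ratio_filter(panel)
  pass2 <- ratio_filter(panel[pass1, , drop = FALSE])
  expect_true(all(pass2))

  prev <- rep(TRUE, n)
  for (thr in c(10, 20, 30, 40, 60, 90)) {
    cur <- ratio_filter(panel, threshold = thr)
    expect_true(all(cur <= prev))  # passing set never grows
    prev <- cur
  }
})

test_that("best-hit family assignment follows the tie-break chain", {
  fmap <- data.frame(subject_id = c("a_GH2", "b_GH43"),
                     family = c("GH2", "GH43"))
  one <- assign_best_family(hit_row(sseqid = "a_GH2"), fmap)
  expect_equal(one$family, "GH2")
  expect_equal(one$class, "GH")

  two <- rbind(hit_row(sseqid = "a_GH2", bitscore = 80),
               hit_row(sseqid = "b_GH43", bitscore = 95))
  expect_equal(assign_best_family(two, fmap)$family, "GH43")

  tie <- rbind(hit_row(sseqid = "b_GH43", bitscore = 90),
               hit_row(sseqid = "a_GH2", bitscore = 90))
  expect_equal(assign_best_family(tie, fmap)$family, "GH2")

  expect_error(assign_best_family(hit_row(sseqid = "unknown"), fmap),
               "unknown")
})

test_that("general functional filter enforces all three thresholds", {
  expect_true(general_functional_filter(
    hit_row(evalue = 1e-20, length = 60, pident = 55)))
  expect_false(general_functional_filter(
    hit_row(evalue = 1e-20, length = 49, pident = 99)))
  expect_false(general_functional_filter(
    hit_row(evalue = 1e-14, length = 60, pident = 55)))
})

test_that("16S read ratio counts distinct passing reads", {
  h <- hit_row(qseqid = sprintf("r%d", 1:5), length = 250, pident = 95,
               qlen = 272)
  r <- rrna_ratio(h, 5000)
  expect_equal(r$ratio, 0.001)
  expect_equal(r$one_per, 1000)

  none <- rrna_ratio(hit_row(length = 150), 5000)
  expect_equal(none$ratio, 0)
  expect_true(is.na(none$one_per))

  # planted 272 bp perfect reads pass the 200 bp floor
  h40 <- hit_row(qseqid = sprintf("q%02d", 1:40), length = 272,
                 pident = 100, qlen = 272)
  r40 <- rrna_ratio(h40, 20000)
  expect_equal(r40$count, 40)
  expect_equal(r40$ratio, 0.002)
})
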