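mk_assign <- function(families) {
  data.frame(read = sprintf("r%04d", seq_along(families)),
             family = families,
             class = sub("^(GH|GT|CBM|CE|PL|AA).*$", "\\1", families),
             stringsAsFactors = FALSE)
}

test_that("relative abundances normalise to 100 with class rollup", {
  p <- relative_abundance(mk_assign(rep(c("GH2", "GH43"), each = 50)), "s")
  expect_equal(unname(p$ra[c("GH2", "GH43")]), c(50, 50))
  expect_equal(sum(p$ra), 100)
  expect_equal(p$total_matched, 100)

  single <- relative_abundance(mk_assign(rep("GH2", 7)))
  expect_equal(unname(single$ra["GH2"]), 100)

  mix <- relative_abundance(mk_assign(c(rep("GH2", 3), "GT2")))
  expect_equal(unname(mix$class_ra[c("GH", "GT")]), c(75, 25))

  expect_warning(relative_abundance(mk_assign(character(0))), "empty")
})

test_that("log fold change matches the published worked examples", {
  # printed RA pairs and their log10 folds (3 d.p.)
  expect_equal(round(log_fold(4.806, 1.839), 3), 0.417)
  expect_equal(round(log_fold(3.034, 0.656), 3), 0.665)
  expect_equal(log_fold(2.5, 2.5), 0)
  expect_true(is.na(log_fold(0, 1.5)))
  expect_true(is.na(log_fold(1.5, 0)))
  expect_error(log_fold(-1, 1), "non-negative")
})

test_that("coverage estimate reproduces its formula and guards", {
  expect_equal(coverage_estimate(136.82, 338)$coverage_2dp, 0.10)
  expect_equal(coverage_estimate(221.46, 45)$coverage_2dp, 1.23)
  expect_equal(coverage_estimate(4, 1)$coverage, 1)
  expect_error(coverage_estimate(10, 0), "at least 1")
})

test_that("profile correlation is scale-invariant and signed", {
  a <- c(GH2 = 1, GH3 = 2, GH43 = 3)
  expect_equal(profile_r2(a, a)$r2, 1)
  expect_equal(profile_r2(a, 2 * a)$r2, 1)
  rev <- profile_r2(a, c(GH2 = 3, GH3 = 2, GH43 = 1))
  expect_equal(rev$r2, 1)
  expect_equal(rev$r, -1)
  expect_warning(z <- profile_r2(a, c(GH2 = 1, GH3 = 1, GH43 = 1)),
                 "zero-variance")
  expect_true(is.na(z$r2))
})

test_that("G+C content excludes ambiguous bases", {
  expect_equal(gc_content("GCGC")$fraction, 1)
  expect_equal(gc_content("ATAT")$fraction, 0)
  expect_equal(gc_content("ACGTN")$fraction, 0.5)
  expect_warning(und <- gc_content("NNNN"), "ambiguous")
  expect_true(is.na(und$fraction))
})

test_that("top-enriched ranking puts undefined folds last, ties by name", {
  m <- matrix(c(1.0, 0.5, NA), ncol = 1,
              dimnames = list(c("GH2", "GH43", "PL17"), NULL))
  expect_equal(top_enriched(m), c("GH2", "GH43", "PL17"))
  expect_equal(top_enriched(m, k = 10), c("GH2", "GH43", "PL17"))
  ties <- matrix(c(0.5, 0.5, 0.5), ncol = 1,
                 dimnames = list(c("GH9", "GH2", "GH43"), NULL))
  expect_equal(top_enriched(ties), c("GH2", "GH43", "GH9"))
})

test_that("fold-change table covers the family union", {
  p1 <- relative_abundance(mk_assign(c("GH2", "GH2", "GH43", "GH92")))
  p0 <- relative_abundance(mk_assign(c("GH2", "GH43", "GH43", "GH13")))
  fc <- fold_change_table(p1, p0)
  expect_setequal(fc$family, c("GH2", "GH13", "GH43", "GH92"))
  gh2 <- fc[fc$family == "GH2", ]
  expect_equal(gh2$log10_fold, log10(50 / 25))
  expect_true(is.na(fc$log10_fold[fc$family == "GH13"]))  # absent sample
  # reference self-fold is zero
  self <- fold_change_table(p0, p0)
  expect_true(all(self$log10_fold == 0))
})
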