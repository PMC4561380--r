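test_that("greedy clustering honours the identity threshold", {
  reads <- setNames(rep(rand_dna(120), 5), sprintf("r%d", 1:5))
  cs <- greedy_cluster(reads)
  expect_equal(length(cs$clusters), 1)

  set.seed(5)
  a <- rand_dna(200)
  b <- mutate_dna(a, sample(200, 2))          # 99% to a
  c <- rand_dna(200)                           # unrelated
  cs2 <- greedy_cluster(c(A = a, B = b, C = c), threshold = 0.97)
  expect_equal(length(cs2$clusters), 2)

  distinct <- setNames(vapply(1:6, function(i) rand_dna(150),
                              character(1)), sprintf("d%d", 1:6))
  expect_equal(length(greedy_cluster(distinct, 1.0)$clusters), 6)
})

test_that("representatives are the longest members and ids break ties", {
  set.seed(9)
  long <- rand_dna(250)
  short <- substring(long, 1, 200)
  cs <- greedy_cluster(c(zz_long = long, aa_short = short), 0.9)
  expect_equal(length(cs$clusters), 1)
  expect_equal(cs$clusters[[1]]$representative, "zz_long")
})

test_that("cluster count is monotone in the threshold", {
  set.seed(21)
  base <- rand_dna(150)
  reads <- setNames(c(base,
                      vapply(1:8, function(i)
                        mutate_dna(base, sample(150, sample(1:30, 1))),
                        character(1))),
                    sprintf("m%d", 0:8))
  prev <- 0
  for (thr in c(0.5, 0.8, 0.9, 0.95, 0.99, 1.0)) {
    k <- length(greedy_cluster(reads, thr)$clusters)
    expect_gte(k, prev)
    prev <- k
  }
})

test_that("greedy clustering equals the brute-force oracle on small panels", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:12, 1)
    base <- rand_dna(80)
    reads <- vapply(seq_len(n), function(i) {
      if (runif(1) < 0.5) mutate_dna(base, sample(80, sample(0:6, 1)))
      else rand_dna(sample(60:90, 1))
    }, character(1))
    names(reads) <- sprintf("r%02d", seq_len(n))
    ours <- lapply(greedy_cluster(reads, 0.9)$clusters, `[[`, "members")
    oracle <- greedy_oracle(reads, 0.9)
    expect_equal(ours, oracle, info = paste("seed", seed))
  }
})

test_that("richness is clusters over reads", {
  set.seed(33)
  reads <- setNames(vapply(1:10, function(i) rand_dna(100), character(1)),
                    sprintf("r%d", 1:10))
  rv <- richness(greedy_cluster(reads, 1.0))
  expect_equal(rv$richness, 1.0)

  same <- setNames(rep(rand_dna(100), 10), sprintf("s%d", 1:10))
  expect_equal(richness(greedy_cluster(same))$richness, 0.1)
})

test_that("fewer template variants give lower richness", {
  make_family_reads <- function(n_variants, n_reads, seed) {
    set.seed(seed)
    variants <- vapply(seq_len(n_variants), function(i)
      mutate_dna(family_templates()[["GH2"]], sample(900, 90)),
      character(1))
    reads <- vapply(seq_len(n_reads), function(i) {
      v <- variants[[sample.int(n_variants, 1)]]
      frag <- substring(v, 100, 371)   # fixed window: comparable reads
      mutate_dna(frag, sample(272, 3)) # ~1% read error
    }, character(1))
    setNames(reads, sprintf("fr%03d", seq_len(n_reads)))
  }
  # anchor all reads to one template window so identities are comparable
  lo <- richness(greedy_cluster(make_family_reads(2, 40, 1)))$richness
  hi <- richness(greedy_cluster(make_family_reads(20, 40, 2)))$richness
  expect_lt(lo, hi)
})
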