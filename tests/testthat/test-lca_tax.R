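test_that("taxonomy parsing validates root, references and cycles", {
  tree <- toy_taxonomy()
  expect_equal(tree$root, "root")
  expect_equal(tax_path(tree, "s1"), c("root", "B1", "g1", "s1"))

  tworoots <- data.frame(node_id = c("a", "b"), parent_id = c("a", "b"),
                         rank = "root", name = c("a", "b"))
  expect_error(taxonomy_tree(tworoots), "exactly one root")

  dangling <- data.frame(node_id = c("root", "x"),
                         parent_id = c("root", "ghost"),
                         rank = c("root", "s"), name = c("root", "x"))
  expect_error(taxonomy_tree(dangling), "not in table")
})

test_that("sequence complexity spans homopolymers to de Bruijn mixes", {
  expect_equal(sequence_complexity("AAAAAAAAAA"), 0)
  # 2 distinct trimers in equal counts over 8 windows: 1 bit / 3 bits
  expect_equal(sequence_complexity("ACACACACAC"), 1 / 3, tolerance = 1e-12)

  # build a sequence containing all 64 trimers exactly once (de Bruijn
  # B(4,3) by greedy Eulerian walk), 66 bp -> 64 windows, entropy 6/6
  kmers <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             c("A", "C", "G", "T")), 1, paste, collapse = "")
  used <- character(0); cur <- "AAA"; seqs <- "AAA"
  while (length(used) < 63) {
    ext <- paste0(substring(cur, 2, 3), c("T", "G", "C", "A"))
    nxt <- ext[!(ext %in% c(used, "AAA"))][1]
    if (is.na(nxt)) break
    used <- c(used, nxt); seqs <- paste0(seqs, substring(nxt, 3, 3))
    cur <- nxt
  }
  expect_equal(nchar(seqs), 66)  # the greedy walk closes deterministically
  expect_equal(sequence_complexity(seqs), 1, tolerance = 1e-12)

  expect_warning(z <- sequence_complexity("AC"), "shorter")
  expect_equal(z, 0)
})

test_that("hit filtering applies score, top-percent and max-matches", {
  h <- hit_row(qseqid = "r", sseqid = sprintf("s%02d", 1:15),
               bitscore = c(100, seq(98, 72, length.out = 14)),
               evalue = 1e-20)
  p <- lca_params()
  kept <- filter_hits(h, p)
  expect_true(all(kept$bitscore >= 90))            # top 10 percent
  expect_lte(nrow(kept), 10)                       # max matches

  many <- hit_row(qseqid = "r", sseqid = sprintf("q%02d", 1:15),
                  bitscore = 95, evalue = 1e-20)
  expect_equal(nrow(filter_hits(many, p)), 10)

  weak <- hit_row(qseqid = "r", sseqid = "s", bitscore = 30,
                  evalue = 1e-20)
  expect_equal(nrow(filter_hits(weak, p)), 0)
})

test_that("LCA returns the deepest common node", {
  tree <- toy_taxonomy()
  expect_equal(lca("s1", tree), "s1")
  expect_equal(lca(c("s1", "s2"), tree), "g1")
  expect_equal(lca(c("s1", "g1"), tree), "g1")
  expect_equal(lca(c("s1", "s3"), tree), "B1")
  expect_true(is.na(lca(character(0), tree)))
})

test_that("LCA agrees with the path-intersection oracle on random trees", {
  for (seed in 1:20) {
    tree <- random_taxonomy(sample(5:25, 1), seed)
    ids <- tree$nodes$node_id
    for (j in 1:5) {
      pick <- sample(ids, sample(1:4, 1))
      expect_equal(lca(pick, tree), lca_oracle(pick, tree),
                   info = paste("seed", seed))
    }
  }
})

test_that("LCA is idempotent and associative over set union", {
  tree <- toy_taxonomy()
  for (x in tree$nodes$node_id) expect_equal(lca(x, tree), x)
  a <- c("s1", "s2"); b <- c("s3")
  expect_equal(lca(c(a, b), tree),
               lca(c(lca(a, tree), lca(b, tree)), tree))
  expect_equal(lca(c(a, b), tree), lca(c(b, a), tree))
})

test_that("min-support pushes weak nodes rootward without deepening", {
  tree <- toy_taxonomy()
  asg <- data.frame(read = sprintf("r%02d", 1:9),
                    node_id = c(rep("s1", 4), rep("s3", 5)),
                    n_hits_used = 1L, stringsAsFactors = FALSE)
  adj <- apply_min_support(asg, tree, min_support = 5)
  # 4 reads at s1 move to g1 (4 < 5), then to B1 (still 4 < 5), then root;
  # root has only 4 -> unassigned. 5 reads at s3 stay.
  expect_true(all(adj$node_id[asg$node_id == "s3"] == "s3"))
  expect_true(all(is.na(adj$node_id[asg$node_id == "s1"])))

  ok <- data.frame(read = sprintf("k%d", 1:5), node_id = "s2",
                   n_hits_used = 1L)
  expect_identical(apply_min_support(ok, tree)$node_id, rep("s2", 5))

  empty <- data.frame(read = character(0), node_id = character(0),
                      n_hits_used = integer(0))
  expect_equal(nrow(apply_min_support(empty, tree)), 0)

  # depth never increases
  set.seed(4)
  asg2 <- data.frame(read = sprintf("m%02d", 1:30),
                     node_id = sample(tree$nodes$node_id, 30, TRUE),
                     n_hits_used = 1L)
  adj2 <- apply_min_support(asg2, tree, 5)
  d <- function(x) if (is.na(x)) 0L else length(tax_path(tree, x))
  expect_true(all(mapply(function(a, b) d(b) <= d(a),
                         asg2$node_id, adj2$node_id)))
})

test_that("reads hitting two sibling species land at their genus", {
  tree <- toy_taxonomy()
  st <- c(sub1 = "s1", sub2 = "s2")
  hits <- rbind(
    hit_row(qseqid = "amb", sseqid = "sub1", bitscore = 100, evalue = 1e-20),
    hit_row(qseqid = "amb", sseqid = "sub2", bitscore = 97, evalue = 1e-20))
  asg <- lca_assign(hits, st, tree)
  expect_equal(asg$node_id, "g1")
  expect_equal(asg$n_hits_used, 2L)

  # low-complexity read is excluded when sequences are supplied
  reads <- c(amb = strrep("A", 50))
  asg2 <- lca_assign(hits, st, tree, reads = reads)
  expect_true(is.na(asg2$node_id))
})
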