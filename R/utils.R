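# Internal helpers shared across modules.

# Evaluate expr under a local RNG state so package simulations neither
# depend on nor disturb the caller's random stream.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# i.i.d. nucleotide sequence with P(G) + P(C) = gc (uses current RNG)
.rand_seq <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Substitution-only mutation at the given per-base rate (current RNG)
.mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  shift <- sample.int(3L, k, replace = TRUE)
  cpp_mutate_seq(seq, pos - 1L, shift)
}

# Deterministic small integer derived from a string (for per-entity seeds)
.string_seed <- function(x) {
  v <- utf8ToInt(x)
  s <- 0
  for (ch in v) s <- (s * 131 + ch) %% 2147480009
  as.integer(s)
}

.is_cazy_label <- function(label) {
  grepl("^(GH|GT|CBM|CE|PL|AA)[0-9]", label)
}

.cazy_class <- function(family) {
  sub("^(GH|GT|CBM|CE|PL|AA).*$", "\\1", family)
}

.write_tsv <- function(df, path, col.names = TRUE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
}
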