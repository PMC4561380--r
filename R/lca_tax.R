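# Taxonomic read placement: a parameterised lowest-common-ancestor rule
# over a provided taxonomy, with score, top-percent, complexity and
# min-support filtering.

#' LCA placement parameters
#'
#' The standard parameter set for LCA read binning: at most `max_matches`
#' hits per read, nodes need `min_support` reads, hits need bitscore
#' `min_score` and e-value at most `max_expected`, reads need sequence
#' complexity at least `min_complexity`, and only hits within
#' `top_percent` percent of the best retained bitscore are used.
#'
#' @param max_matches,min_support,min_score,max_expected,min_complexity,top_percent
#'   See description; defaults 10, 5, 35, 0.01, 0.3, 10.
#' @return List of class `lca_params`.
#' @export
lca_params <- function(max_matches = 10, min_support = 5, min_score = 35,
                       max_expected = 0.01, min_complexity = 0.3,
                       top_percent = 10) {
  stopifnot(max_matches >= 1, min_support >= 0, min_score >= 0,
            max_expected >= 0, min_complexity >= 0,
            top_percent >= 0, top_percent <= 100)
  structure(list(max_matches = max_matches, min_support = min_support,
                 min_score = min_score, max_expected = max_expected,
                 min_complexity = min_complexity,
                 top_percent = top_percent), class = "lca_params")
}

#' Read a 4-column taxonomy table
#'
#' Columns `node_id`, `parent_id`, `rank`, `name` (with header). The root
#' is the single node that is its own parent.
#'
#' @param x Path to a TSV file or a data.frame.
#' @return An object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(x) {
  df <- if (is.data.frame(x)) x else
    read.table(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               quote = "", comment.char = "")
  stopifnot(all(c("node_id", "parent_id", "rank", "name") %in% names(df)))
  df$node_id <- as.character(df$node_id)
  df$parent_id <- as.character(df$parent_id)
  if (anyDuplicated(df$node_id))
    stop("duplicate node ids: ",
         paste(head(df$node_id[duplicated(df$node_id)], 3), collapse = ", "))
  roots <- df$node_id[df$node_id == df$parent_id]
  if (length(roots) != 1)
    stop("taxonomy must have exactly one root (its own parent); found ",
         length(roots))
  parent <- setNames(df$parent_id, df$node_id)
  miss <- setdiff(df$parent_id, df$node_id)
  if (length(miss) > 0)
    stop("parent node(s) not in table: ", paste(head(miss, 3), collapse = ", "))
  # cycle check: every node must reach the root
  for (nd in df$node_id) {
    seen <- character(0); cur <- nd
    while (cur != roots) {
      if (cur %in% seen) stop("cycle in taxonomy at node ", nd)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      if (length(seen) > nrow(df)) stop("cycle in taxonomy at node ", nd)
    }
  }
  structure(list(nodes = df, parent = parent, root = roots,
                 rank = setNames(df$rank, df$node_id),
                 name = setNames(df$name, df$node_id)),
            class = "taxonomy_tree")
}

#' Root path of a taxonomy node
#' @param tree A [taxonomy_tree()].
#' @param node_id Node identifier.
#' @return Character vector of node ids, root first.
#' @export
tax_path <- function(tree, node_id) {
  node_id <- as.character(node_id)
  if (!(node_id %in% names(tree$parent)))
    stop("unknown node: ", node_id)
  path <- node_id
  while (node_id != tree$root) {
    node_id <- tree$parent[[node_id]]
    path <- c(node_id, path)
  }
  path
}

#' Lowest common ancestor of a set of nodes
#'
#' The deepest node lying on every node's root path.
#'
#' @param node_ids Character vector of node ids (empty -> `NA`).
#' @param tree A [taxonomy_tree()].
#' @return Node id, or `NA_character_` for an empty set.
#' @export
lca <- function(node_ids, tree) {
  node_ids <- unique(as.character(node_ids))
  if (length(node_ids) == 0) return(NA_character_)
  paths <- lapply(node_ids, function(x) tax_path(tree, x))
  common <- Reduce(intersect, paths)
  # intersect preserves the order of the first path (root first)
  common[length(common)]
}

#' Sequence complexity from trinucleotide composition
#'
#' Shannon entropy of the overlapping trinucleotide composition divided by
#' its maximum for the observed length,
#' `log2(min(64, n_windows))` — 0 for homopolymers, approaching 1 for
#' maximally mixed sequence.
#'
#' @param read Nucleotide string.
#' @return Value in \[0, 1\]; length < 3 gives 0 with a warning.
#' @export
sequence_complexity <- function(read) {
  n <- nchar(read)
  if (n < 3) {
    warning("read shorter than 3 bp; complexity 0")
    return(0)
  }
  tri <- substring(read, 1:(n - 2), 3:n)
  tri <- tri[!grepl("[^ACGTacgt]", tri)]
  if (length(tri) == 0) return(0)
  f <- table(tri) / length(tri)
  h <- -sum(f * log2(f))
  hmax <- log2(min(64, length(tri)))
  if (hmax == 0) return(0)
  min(1, h / hmax)
}

#' Filter hits for LCA placement
#'
#' Drops hits below `min_score` bitscore or above `max_expected` e-value,
#' keeps hits whose bitscore is within `top_percent` percent of the best
#' retained bitscore, and truncates to the `max_matches` best (ties by
#' e-value, then subject id).
#'
#' @param hits data.frame with `bitscore`, `evalue`, `sseqid`.
#' @param params An [lca_params()] list.
#' @return The retained rows.
#' @export
filter_hits <- function(hits, params = lca_params()) {
  h <- hits[hits$bitscore >= params$min_score &
              hits$evalue <= params$max_expected, , drop = FALSE]
  if (nrow(h) == 0) return(h)
  best <- max(h$bitscore)
  h <- h[h$bitscore >= best * (100 - params$top_percent) / 100, ,
         drop = FALSE]
  o <- order(-h$bitscore, h$evalue, h$sseqid, method = "radix")
  head(h[o, , drop = FALSE], params$max_matches)
}

#' LCA taxonomic assignment of reads
#'
#' Per read: filter its hits ([filter_hits()]), map the retained subjects
#' to taxa, and assign the lowest common ancestor. Reads whose sequence
#' complexity is below `min_complexity` (when sequences are supplied) or
#' with no retained hits stay unassigned.
#'
#' @param hits data.frame with `qseqid`, `sseqid`, `bitscore`, `evalue`.
#' @param subject_taxa Named vector subject_id -> taxon node id, or a
#'   data.frame with columns `subject_id`, `taxon`.
#' @param tree A [taxonomy_tree()].
#' @param params An [lca_params()] list.
#' @param reads Optional named character vector of read sequences for the
#'   complexity filter.
#' @return data.frame `read`, `node_id` (`NA` = unassigned),
#'   `n_hits_used`.
#' @export
lca_assign <- function(hits, subject_taxa, tree, params = lca_params(),
                       reads = NULL) {
  if (is.data.frame(subject_taxa))
    subject_taxa <- setNames(subject_taxa$taxon, subject_taxa$subject_id)
  ids <- unique(hits$qseqid)
  res <- lapply(ids, function(q) {
    if (!is.null(reads) && q %in% names(reads) &&
        sequence_complexity(reads[[q]]) < params$min_complexity)
      return(data.frame(read = q, node_id = NA_character_,
                        n_hits_used = 0L))
    h <- filter_hits(hits[hits$qseqid == q, , drop = FALSE], params)
    if (nrow(h) == 0)
      return(data.frame(read = q, node_id = NA_character_,
                        n_hits_used = 0L))
    taxa <- subject_taxa[h$sseqid]
    miss <- h$sseqid[is.na(taxa)]
    if (length(miss) > 0)
      stop("subject(s) missing from taxon map: ",
           paste(head(miss, 3), collapse = ", "))
    data.frame(read = q, node_id = lca(taxa, tree),
               n_hits_used = nrow(h))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Min-support adjustment of LCA assignments
#'
#' Iteratively moves the reads of any node whose own read count (excluding
#' descendants) is below `min_support` up to its parent, until stable;
#' reads that reach the root without support become unassigned. This
#' conserves read counts, which per-rank relative-abundance summaries
#' require.
#'
#' @param assignments data.frame from [lca_assign()].
#' @param tree A [taxonomy_tree()].
#' @param min_support Minimum reads per node (default 5).
#' @return The adjusted assignments.
#' @export
apply_min_support <- function(assignments, tree, min_support = 5) {
  if (nrow(assignments) == 0) return(assignments)
  node <- assignments$node_id
  depth <- vapply(names(tree$parent), function(x)
    length(tax_path(tree, x)), integer(1))
  repeat {
    assigned <- node[!is.na(node)]
    if (length(assigned) == 0) break
    cnt <- table(assigned)
    weak <- names(cnt)[cnt < min_support]
    weak <- setdiff(weak, tree$root)
    if (length(weak) == 0) break
    # deepest-first for a deterministic fixed point
    weak <- weak[order(-depth[weak], weak)]
    w <- weak[1]
    node[!is.na(node) & node == w] <- tree$parent[[w]]
  }
  at_root <- !is.na(node) & node == tree$root
  if (any(at_root) && sum(at_root) < min_support)
    node[at_root] <- NA_character_
  assignments$node_id <- node
  assignments
}
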