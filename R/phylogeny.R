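#' Pairwise p-distance matrix from an alignment
#'
#' Proportion of mismatching sites per pair, with gap-containing
#' columns deleted pairwise ('-' or 'N' in either sequence).
#'
#' @param aln list of equal-length aligned records, or a named
#'   character vector of aligned sequences.
#' @return list with \code{labels} and \code{d} (symmetric matrix,
#'   zero diagonal).
#' @export
p_distance <- function(aln) {
  if (is.list(aln)) {
    labels <- vapply(aln, `[[`, "", "id")
    seqs <- toupper(vapply(aln, `[[`, "", "sequence"))
  } else {
    labels <- names(aln)
    seqs <- toupper(aln)
  }
  if (length(unique(nchar(seqs))) != 1) stop("sequences must be aligned (equal length)")
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !(mat[i, ] %in% c("-", "N")) & !(mat[j, ] %in% c("-", "N"))
    if (!any(ok)) stop("no comparable positions for pair ", labels[i], "/", labels[j])
    d[i, j] <- d[j, i] <- mean(mat[i, ok] != mat[j, ok])
  }
  list(labels = labels, d = d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (exact on additive matrices). Negative
#' branch lengths are clamped to zero with the deficit moved to the
#' sister edge, preserving leaf-to-leaf path lengths through the
#' parent.
#'
#' @param dm distance matrix object from [p_distance()], or a plain
#'   symmetric matrix with dimnames.
#' @return an \code{ape::phylo} tree (unrooted).
#' @export
neighbor_joining <- function(dm) {
  d <- if (is.list(dm)) dm$d else dm
  if (nrow(d) < 3) stop("need >= 3 taxa")
  tree <- ape::nj(d)
  # clamp negatives, moving the deficit to a sister edge
  for (pass in 1:10) {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sibs)) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' p-distance NJ tree per replicate, and reports for each internal
#' edge of the original tree the percentage of replicates containing
#' the same bipartition. Deterministic for a fixed seed.
#'
#' @param aln alignment as in [p_distance()].
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with \code{tree} (phylo, node labels = support
#'   percentages), \code{support} (numeric per internal node),
#'   \code{newick} (Newick string with supports as internal labels)
#'   and \code{degenerate} (TRUE when all input sequences are
#'   identical, making the topology arbitrary).
#' @export
bootstrap_support <- function(aln, replicates = 1000, seed = 1) {
  stopifnot(replicates >= 1)
  if (is.list(aln)) {
    seqs <- toupper(vapply(aln, `[[`, "", "sequence"))
    names(seqs) <- vapply(aln, `[[`, "", "id")
  } else {
    seqs <- toupper(aln)
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  build <- function(m) {
    sq <- apply(m, 1, paste, collapse = "")
    neighbor_joining(p_distance(setNames(sq, rownames(m))))
  }
  orig <- build(mat)
  set.seed(seed)
  reps <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample(ncol(mat), ncol(mat), replace = TRUE)
    reps[[b]] <- build(mat[, cols, drop = FALSE])
  }
  counts <- ape::prop.clades(orig, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / replicates
  orig$node.label <- formatC(support, format = "f", digits = 0)
  list(tree = orig, support = support,
       newick = ape::write.tree(orig),
       degenerate = length(unique(seqs)) == 1)
}
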