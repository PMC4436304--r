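# Distance matrices, neighbour joining, and bootstrap supports.

#' Pairwise p-distance matrix of an alignment
#'
#' d(i,j) = mismatches / columns where both rows carry residues (pairwise
#' gap deletion).  A pair with zero comparable columns is an error.
#'
#' @param aln a `gf_alignment` with >= 2 rows.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stopf("p_distance needs at least 2 rows")
  res <- m != "-" & m != "X" & m != "N"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    ok <- res[i, ] & res[j, ]
    if (!any(ok))
      stopf("rows '%s' and '%s' share no comparable columns",
            rownames(m)[i], rownames(m)[j])
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei NJ (via `ape::nj`); negative branch-length estimates are
#' clamped to zero and the clamped total is recorded in the
#' `"clamp_deficit"` attribute.
#'
#' @param d symmetric distance matrix with labels, n >= 3.
#' @return an unrooted `ape::phylo`.
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3) stopf("neighbour joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamp_deficit") <- deficit
  tr
}

# Canonical keys for the unrooted bipartitions induced by internal edges.
# Key = sorted labels of the side not containing the alphabetically first
# leaf, joined by "|"; invariant to rooting and leaf order.
bipartition_keys <- function(tree) {
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- character(0)
  nodes <- integer(0)
  ntip <- length(tips)
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (ref %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, ntip + k)
  }
  data.frame(node = nodes, key = keys, stringsAsFactors = FALSE)
}

#' Bootstrap supports on a point-estimate tree
#'
#' Alignment columns are resampled with replacement `reps` times; the
#' support of a bipartition is the percentage of replicate trees containing
#' it, attached to the point-estimate tree's internal nodes.
#'
#' @param aln a `gf_alignment`.
#' @param builder function alignment -> phylo; default p-distance + NJ.
#' @param reps number of replicates (>= 1).
#' @param seed RNG seed (required for reproducibility).
#' @return a list of class `"gf_supported_tree"`: `tree` (node labels =
#'   integer supports), `support` (named vector, bipartition key ->
#'   percentage), `reps`.
#' @export
bootstrap_support <- function(aln, builder = NULL, reps = 1000, seed = 1) {
  if (reps < 1) stopf("reps must be >= 1")
  point <- if (is.null(builder)) nj_tree(p_distance(aln)) else builder(aln)
  bp <- bipartition_keys(point)
  counts <- stats::setNames(numeric(nrow(bp)), bp$key)
  m <- aln_matrix(aln)
  L <- ncol(m)
  with_seed(seed, {
    if (is.null(builder)) {
      # fast path: precompute per-pair mismatch/validity over columns
      n <- nrow(m)
      pair_i <- unlist(lapply(seq_len(n - 1), function(i) rep(i, n - i)))
      pair_j <- unlist(lapply(seq_len(n - 1), function(i) seq.int(i + 1, n)))
      res <- m != "-" & m != "X" & m != "N"
      mm <- (m[pair_i, , drop = FALSE] != m[pair_j, , drop = FALSE]) &
        res[pair_i, , drop = FALSE] & res[pair_j, , drop = FALSE]
      vv <- res[pair_i, , drop = FALSE] & res[pair_j, , drop = FALSE]
      for (r in seq_len(reps)) {
        cols <- sample.int(L, L, replace = TRUE)
        num <- rowSums(mm[, cols, drop = FALSE])
        den <- rowSums(vv[, cols, drop = FALSE])
        den[den == 0] <- 1L
        d <- matrix(0, n, n, dimnames = dimnames(m)[c(1, 1)])
        d[cbind(pair_i, pair_j)] <- num / den
        d[cbind(pair_j, pair_i)] <- d[cbind(pair_i, pair_j)]
        rownames(d) <- colnames(d) <- rownames(m)
        keys <- bipartition_keys(nj_tree(d))$key
        hit <- names(counts) %in% keys
        counts[hit] <- counts[hit] + 1
      }
    } else {
      for (r in seq_len(reps)) {
        cols <- sample.int(L, L, replace = TRUE)
        rep_aln <- new_alignment(rownames(m),
                                 apply(m[, cols, drop = FALSE], 1, c2s))
        keys <- bipartition_keys(builder(rep_aln))$key
        hit <- names(counts) %in% keys
        counts[hit] <- counts[hit] + 1
      }
    }
  })
  support <- 100 * counts / reps
  ntip <- length(point$tip.label)
  nlab <- rep("", point$Nnode)
  nlab[bp$node - ntip] <- as.character(round(support[bp$key]))
  point$node.label <- nlab
  structure(list(tree = point, support = support, reps = reps),
            class = "gf_supported_tree")
}

#' @export
print.gf_supported_tree <- function(x, ...) {
  cat(sprintf("NJ tree with bootstrap supports (%d leaves, %d replicates)\n",
              length(x$tree$tip.label), x$reps))
  invisible(x)
}
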