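# Maximum parsimony: Fitch scoring and tree search.

# Encode alignment rows as bitmask matrices (one bit per amino acid);
# gaps/X are fully ambiguous (missing data never costs a change).
fitch_masks <- function(aln) {
  m <- aln_matrix(aln)
  idx <- matrix(match(m, AA_LETTERS), nrow(m))
  masks <- matrix(bitwShiftL(1L, idx - 1L), nrow(m))
  masks[is.na(masks)] <- bitwShiftL(1L, 20L) - 1L   # ambiguous
  rownames(masks) <- rownames(m)
  masks
}

#' Fitch parsimony score of a tree given an alignment
#'
#' Minimum number of substitutions over all ancestral labellings, summed
#' over columns; gaps are treated as missing.
#'
#' @param tree `ape::phylo` whose tips match the alignment rows.
#' @param aln a `gf_alignment`.
#' @param weights optional per-column weights (pattern compression).
#' @return integer (or weighted numeric) score.
#' @export
fitch_score <- function(tree, aln, weights = NULL) {
  masks <- if (inherits(aln, "gf_alignment")) fitch_masks(aln) else aln
  if (!setequal(tree$tip.label, rownames(masks)))
    stopf("tree leaves and alignment rows do not match")
  L <- ncol(masks)
  if (is.null(weights)) weights <- rep(1, L)
  rt <- tree
  if (!ape::is.rooted(rt)) rt <- ape::root(rt, outgroup = rt$tip.label[1],
                                           resolve.root = TRUE)
  attr(rt, "order") <- NULL       # stale order attrs mislead reorder()
  rt <- stats::reorder(rt, "postorder")
  ntip <- length(rt$tip.label)
  node_mask <- matrix(0L, ntip + rt$Nnode, L)
  node_mask[seq_len(ntip), ] <- masks[rt$tip.label, , drop = FALSE]
  filled <- c(rep(TRUE, ntip), rep(FALSE, rt$Nnode))
  changes <- numeric(L)
  for (e in seq_len(nrow(rt$edge))) {
    parent <- rt$edge[e, 1]; child <- rt$edge[e, 2]
    if (!filled[parent]) {
      node_mask[parent, ] <- node_mask[child, ]
      filled[parent] <- TRUE
    } else {
      inter <- bitwAnd(node_mask[parent, ], node_mask[child, ])
      zero <- inter == 0L
      changes[zero] <- changes[zero] + 1
      inter[zero] <- bitwOr(node_mask[parent, zero], node_mask[child, zero])
      node_mask[parent, ] <- inter
    }
  }
  sum(changes * weights)
}

# canonical Newick for tie-breaking: sorted-rotation string
canonical_newick <- function(tree) {
  tr <- ape::root(ape::unroot(tree), outgroup = sort(tree$tip.label)[1],
                  resolve.root = TRUE)
  tr$edge.length <- NULL
  ape::write.tree(ape::rotateConstr(tr, sort(tr$tip.label)))
}

#' Maximum-parsimony tree search
#'
#' Exhaustive enumeration of all unrooted topologies for up to 8 taxa;
#' above that, NNI hill-climbing from the NJ tree with seeded random
#' restarts.  Score ties are broken by the lexicographically smallest
#' canonical Newick string.
#'
#' @param aln a `gf_alignment` with >= 4 rows.
#' @param restarts random restarts for the hill-climb (> 8 taxa).
#' @param seed RNG seed for the restarts.
#' @return best-scoring unrooted `ape::phylo` (attribute `"pscore"`).
#' @export
mp_tree <- function(aln, restarts = 10, seed = 1) {
  n <- length(aln$ids)
  if (n < 4) stopf("parsimony search needs at least 4 taxa")
  masks <- fitch_masks(aln)
  # pattern compression
  key <- apply(masks, 2, paste, collapse = ",")
  uniq <- !duplicated(key)
  w <- as.numeric(table(key)[key[uniq]])
  cmasks <- masks[, uniq, drop = FALSE]
  if (n <= 8) {
    cand <- phangorn::allTrees(n, rooted = FALSE, tip.label = aln$ids)
    scores <- vapply(cand, fitch_score, 0, aln = cmasks, weights = w)
    best <- which(scores == min(scores))
    if (length(best) > 1) {
      nwk <- vapply(cand[best], canonical_newick, "")
      best <- best[order(nwk)[1]]
    }
    out <- cand[[best]]
    attr(out, "pscore") <- min(scores)
    return(out)
  }
  start <- nj_tree(p_distance(aln))
  decompress <- function(mphy) lapply(seq_along(mphy), function(k) mphy[[k]])
  climb <- function(tr) {
    sc <- fitch_score(tr, cmasks, w)
    repeat {
      nbrs <- decompress(phangorn::nni(tr))
      nsc <- vapply(nbrs, fitch_score, 0, aln = cmasks, weights = w)
      if (min(nsc) < sc) {
        sc <- min(nsc)
        tr <- nbrs[[which.min(nsc)]]
      } else break
    }
    list(tree = tr, score = sc)
  }
  best <- climb(start)
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      tr <- start
      for (k in seq_len(3)) {          # random NNI perturbation
        nbrs <- decompress(phangorn::nni(tr))
        tr <- nbrs[[sample.int(length(nbrs), 1)]]
      }
      res <- climb(tr)
      if (res$score < best$score ||
          (res$score == best$score &&
           canonical_newick(res$tree) < canonical_newick(best$tree)))
        best <- res
    }
  })
  out <- ape::unroot(best$tree)
  out$edge.length <- NULL
  attr(out, "pscore") <- best$score
  out
}
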