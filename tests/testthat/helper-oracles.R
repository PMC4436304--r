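# Independent oracles and shared fixtures.  Everything here is built by a
# different route than the implementation it checks.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# Brute-force optimal local alignment score: enumerate every monotone set
# of aligned residue pairs between the two sequences; unaligned residues
# between consecutive pairs are charged as affine gaps, ends are free.
brute_local_score <- function(q, s, mat, gap_open = 11, gap_extend = 1) {
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  n <- length(qv); m <- length(sv)
  best <- 0
  gap_cost <- function(g) if (g > 0) gap_open + g * gap_extend else 0
  for (k in seq_len(min(n, m))) {
    qi <- utils::combn(n, k); sj <- utils::combn(m, k)
    for (a in seq_len(ncol(qi))) for (b in seq_len(ncol(sj))) {
      iq <- qi[, a]; js <- sj[, b]
      sc <- sum(mat[cbind(qv[iq], sv[js])])
      if (k > 1) {
        sc <- sc - sum(vapply(diff(iq) - 1L, gap_cost, 0)) -
          sum(vapply(diff(js) - 1L, gap_cost, 0))
      }
      if (sc > best) best <- sc
    }
  }
  best
}

# All 15 unrooted binary 5-taxon topologies, enumerated by their two
# cherries, as Newick strings.
all_5taxon_newicks <- function(tips) {
  stopifnot(length(tips) == 5)
  out <- character()
  pairs <- utils::combn(5, 2)
  for (a in seq_len(ncol(pairs))) {
    rest <- setdiff(1:5, pairs[, a])
    second <- utils::combn(rest, 2)
    for (b in seq_len(ncol(second))) {
      e <- setdiff(rest, second[, b])
      out <- c(out, sprintf("((%s,%s),(%s,%s),%s);",
                            tips[pairs[1, a]], tips[pairs[2, a]],
                            tips[second[1, b]], tips[second[2, b]],
                            tips[e]))
    }
  }
  # each topology appears twice (cherry roles swapped); dedupe by
  # unrooted topological distance
  trees <- lapply(out, function(x) ape::read.tree(text = x))
  keep <- rep(TRUE, length(trees))
  for (i in seq_along(trees)) {
    if (!keep[i]) next
    for (j in seq_along(trees)) {
      if (j <= i || !keep[j]) next
      if (ape::dist.topo(trees[[i]], trees[[j]]) == 0) keep[j] <- FALSE
    }
  }
  trees[keep]
}

# Exhaustive parsimony score of a tree: per column, minimise changes over
# every assignment of observed states to the internal nodes.
sankoff_brute <- function(tree, aln_seqs) {
  rt <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  ntip <- length(rt$tip.label)
  nint <- rt$Nnode
  m <- do.call(rbind, strsplit(aln_seqs[rt$tip.label], ""))
  total <- 0
  for (col in seq_len(ncol(m))) {
    obs <- m[, col]
    states <- unique(obs[obs != "-"])
    if (length(states) <= 1) next
    grid <- as.matrix(expand.grid(rep(list(states), nint),
                                  stringsAsFactors = FALSE))
    lab <- function(node, g) {
      if (node <= ntip) obs[node] else g[node - ntip]
    }
    costs <- apply(grid, 1, function(g) {
      sum(vapply(seq_len(nrow(rt$edge)), function(e) {
        a <- lab(rt$edge[e, 1], g); b <- lab(rt$edge[e, 2], g)
        if (a == "-" || b == "-") 0L else as.integer(a != b)
      }, 0L))
    })
    total <- total + min(costs)
  }
  total
}

# Concordant zero-noise fixture: `nclan` clans of `per` leaves; clans are
# separated by long diagnostic blocks, leaves inside a clan by a few
# private sites, so all three methods agree and clan supports saturate.
make_clan_alignment <- function(nclan = 3, per = 3, block = 20, seed = 2) {
  set.seed(seed)
  bases <- replicate(nclan, paste(sample(AA20, nclan * block, TRUE),
                                  collapse = ""))
  ids <- character(); seqs <- character()
  for (k in seq_len(nclan)) {
    for (i in seq_len(per)) {
      ch <- strsplit(bases[k], "")[[1]]
      idx <- sample(length(ch), 4)
      ch[idx] <- sample(AA20, 4, TRUE)
      ids <- c(ids, sprintf("%s%d", letters[k], i))
      seqs <- c(seqs, paste(ch, collapse = ""))
    }
  }
  new_alignment(ids, seqs)
}

# Robinson-Foulds distance as a bare number (dist.topo returns a classed
# "dist" object that trips strict equality checks).
rf <- function(a, b) as.numeric(ape::dist.topo(a, b))

# Adjusted Rand index between two labelings (contingency-table formula).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ <- si * sj / n
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# Partition produced by the reference builder as a labeling over ids.
groups_as_labels <- function(groups) {
  lab <- integer(); ids <- character()
  for (k in seq_along(groups)) {
    lab <- c(lab, rep(k, length(groups[[k]]$members)))
    ids <- c(ids, groups[[k]]$members)
  }
  stats::setNames(lab, ids)
}
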