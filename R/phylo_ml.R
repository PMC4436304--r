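# Maximum likelihood under the Poisson amino-acid model.
#
# Equal exchange rates, uniform stationary frequencies: the transition
# probability after t expected substitutions per site is
#   P(same)  = 1/20 + (19/20) exp(-20 t / 19)
#   P(diff)  = 1/20 - (1/20) exp(-20 t / 19).
# This keeps the likelihood closed-form-checkable (the two-taxon MLE
# inverts p = (19/20)(1 - exp(-20 t/19))) while providing exactly what the
# classification rule needs from ML: topology concordance.  Branch lengths
# are optimised with inside/outside partials: conditional on the rest of
# the tree, each branch's per-site likelihood is A_s + B_s exp(-20 t/19),
# so the 1-D search costs O(sites), not a full tree traversal per step.

ml_encode <- function(aln) {
  m <- aln_matrix(aln)
  idx <- matrix(match(m, AA_LETTERS), nrow(m), dimnames = dimnames(m))
  allgap <- colSums(!is.na(idx)) == 0
  if (any(allgap)) {
    warnf("dropping %d all-gap column(s)", sum(allgap))
    idx <- idx[, !allgap, drop = FALSE]
  }
  key <- apply(idx, 2, paste, collapse = ",")
  uniq <- which(!duplicated(key))
  w <- as.numeric(table(key)[key[uniq]])
  list(states = idx[, uniq, drop = FALSE], weights = w)
}

# conditional-likelihood propagation along one branch (column sums are
# preserved, so normalised partials stay normalised)
ml_prop <- function(partial, t) {
  e <- exp(-20 * t / 19)
  ps <- 1 / 20 + (19 / 20) * e
  pd <- 1 / 20 - e / 20
  cs <- colSums(partial)
  (ps - pd) * partial + pd * rep(cs, each = 20L)
}

ml_leaf_partials <- function(rt, enc) {
  states <- enc$states
  npat <- ncol(states)
  ord <- match(rt$tip.label, rownames(states))
  lapply(seq_along(ord), function(i) {
    p <- matrix(0, 20, npat)
    s <- states[ord[i], ]
    known <- !is.na(s)
    p[cbind(s[known], which(known))] <- 1
    p[, !known] <- 1
    p
  })
}

ml_postorder <- function(tree) {
  attr(tree, "order") <- NULL     # stale order attrs mislead reorder()
  stats::reorder(tree, "postorder")
}

# inside (down) pass: normalised subtree partials + per-site log scales
ml_down <- function(rt, leafp, enc) {
  npat <- ncol(enc$states)
  ntip <- length(rt$tip.label)
  nn <- ntip + rt$Nnode
  down <- vector("list", nn)
  dscale <- matrix(0, nn, npat)
  down[seq_len(ntip)] <- leafp
  acc <- vector("list", nn)
  normalise <- function(v) {
    cs <- colSums(acc[[v]])
    down[[v]] <<- acc[[v]] / rep(cs, each = 20L)
    dscale[v, ] <<- dscale[v, ] + log(cs)
  }
  for (e in seq_len(nrow(rt$edge))) {
    par <- rt$edge[e, 1]; ch <- rt$edge[e, 2]
    if (is.null(down[[ch]])) normalise(ch)   # internal child complete now
    msg <- ml_prop(down[[ch]], rt$edge.length[e])
    if (is.null(acc[[par]])) {
      acc[[par]] <- msg
      dscale[par, ] <- dscale[ch, ]
    } else {
      acc[[par]] <- acc[[par]] * msg
      dscale[par, ] <- dscale[par, ] + dscale[ch, ]
    }
  }
  root <- rt$edge[nrow(rt$edge), 1]
  if (is.null(down[[root]])) normalise(root)
  list(down = down, dscale = dscale)
}

# log-likelihood of a tree from the inside pass alone
ml_loglik <- function(tree, enc, leafp = NULL) {
  rt <- ml_postorder(tree)
  if (is.null(leafp)) leafp <- ml_leaf_partials(rt, enc)
  dn <- ml_down(rt, leafp, enc)
  root <- rt$edge[nrow(rt$edge), 1]
  site <- colSums(dn$down[[root]]) / 20
  sum(enc$weights * (log(site) + dn$dscale[root, ]))
}

# optimise every branch length; each edge update is exact given the rest
# of the tree, so the log-likelihood never decreases
optimise_branches <- function(tree, enc, tol = 1e-8, max_rounds = 5) {
  rt <- ml_postorder(tree)
  leafp <- ml_leaf_partials(rt, enc)
  npat <- ncol(enc$states)
  ntip <- length(rt$tip.label)
  w <- enc$weights
  ll <- -Inf
  for (round in seq_len(max_rounds)) {
    prev <- ll
    for (e in seq_len(nrow(rt$edge))) {
      dn <- ml_down(rt, leafp, enc)
      # outside partial of edge e: prior at the root, propagated down to
      # the edge's parent, times the sibling subtree messages
      up <- vector("list", ntip + rt$Nnode)
      uscale <- matrix(0, ntip + rt$Nnode, npat)
      root <- rt$edge[nrow(rt$edge), 1]
      up[[root]] <- matrix(1 / 20, 20, npat)
      for (k in rev(seq_len(nrow(rt$edge)))) {
        par <- rt$edge[k, 1]; ch <- rt$edge[k, 2]
        if (is.null(up[[par]])) next
        sib <- which(rt$edge[, 1] == par & rt$edge[, 2] != ch)
        out <- up[[par]]
        osc <- uscale[par, ]
        for (s in sib) {
          out <- out * ml_prop(dn$down[[rt$edge[s, 2]]],
                               rt$edge.length[s])
          osc <- osc + dn$dscale[rt$edge[s, 2], ]
        }
        cs <- colSums(out)
        out <- out / rep(cs, each = 20L)
        osc <- osc + log(cs)
        if (k == e) {
          D <- dn$down[[ch]]
          sU <- colSums(out); sD <- colSums(D)
          A <- sU * sD / 20
          B <- colSums(out * D) - A
          sc <- osc + dn$dscale[ch, ]
          g <- function(t) {
            ee <- exp(-20 * t / 19)
            sum(w * (log(A + B * ee) + sc))
          }
          opt <- stats::optimize(g, c(1e-9, 10), maximum = TRUE, tol = tol)
          if (opt$objective >= g(rt$edge.length[e]))
            rt$edge.length[e] <- opt$maximum
          ll <- max(opt$objective, g(rt$edge.length[e]))
          break
        }
        up[[ch]] <- ml_prop(out, rt$edge.length[k])
        uscale[ch, ] <- osc
      }
    }
    if (ll - prev < 1e-6) break
  }
  list(tree = rt, loglik = ll)
}

#' Maximum-likelihood tree under the Poisson amino-acid model
#'
#' Felsenstein pruning likelihood; branch lengths optimised one at a time
#' by bounded 1-D search (each update exact conditional on the rest of the
#' tree, so the log-likelihood never decreases); NNI rearrangements
#' (screened at the current branch lengths, then re-optimised) accepted
#' when the log-likelihood improves by more than 1e-8.  With two taxa the
#' single branch length is optimised directly (its MLE has the closed
#' form above).
#'
#' @param aln a `gf_alignment` with >= 2 rows.
#' @param start optional starting tree (default: NJ on p-distances).
#' @param nni_sweeps maximum NNI sweeps.
#' @return list of class `"gf_ml_tree"`: `tree` (phylo with optimised
#'   branch lengths), `loglik`.
#' @export
ml_tree_poisson <- function(aln, start = NULL, nni_sweeps = 3) {
  enc <- ml_encode(aln)
  n <- length(aln$ids)
  if (n < 2) stopf("ML needs at least 2 rows")
  if (n == 2) {
    mk2 <- function(t) {
      tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 tip.label = aln$ids, Nnode = 1L,
                 edge.length = c(t / 2, t / 2))
      class(tr) <- "phylo"
      tr
    }
    opt <- stats::optimize(function(t) ml_loglik(mk2(t), enc),
                           c(1e-9, 10), maximum = TRUE, tol = 1e-9)
    return(structure(list(tree = mk2(opt$maximum), loglik = opt$objective),
                     class = "gf_ml_tree"))
  }
  tree <- if (is.null(start)) nj_tree(p_distance(aln)) else start
  tree <- ape::unroot(tree)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length[tree$edge.length < 1e-9] <- 1e-9
  fit <- optimise_branches(tree, enc)
  if (n >= 4) {
    for (sweep in seq_len(nni_sweeps)) {
      improved <- FALSE
      nbrs <- phangorn::nni(fit$tree)
      for (k in seq_along(nbrs)) {
        nb <- nbrs[[k]]   # [[ decompresses multiPhylo tip labels
        if (is.null(nb$edge.length)) next
        nb$edge.length[nb$edge.length < 1e-9] <- 1e-9
        if (ml_loglik(nb, enc) > fit$loglik + 1e-8) {
          cand <- optimise_branches(nb, enc)
          if (cand$loglik > fit$loglik + 1e-8) {
            fit <- cand
            improved <- TRUE
            break
          }
        }
      }
      if (!improved) break
    }
  }
  structure(fit, class = "gf_ml_tree")
}

#' @export
print.gf_ml_tree <- function(x, ...) {
  cat(sprintf("Poisson ML tree: %d leaves, log-likelihood %.4f\n",
              length(x$tree$tip.label), x$loglik))
  invisible(x)
}
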