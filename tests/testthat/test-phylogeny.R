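# Distances, NJ, bootstrap, parsimony, Poisson ML, and subfamily calling.

test_that("p-distances use pairwise gap deletion", {
  aln <- new_alignment(c("a", "b"), c("A-CG", "ATCG"))
  expect_equal(p_distance(aln)["a", "b"], 0)          # 3 compared, 0 diff
  aln2 <- new_alignment(c("a", "b"),
                        c(strrep("A", 30),
                          paste0(strrep("R", 3), strrep("A", 27))))
  expect_equal(p_distance(aln2)["a", "b"], 0.1)
  expect_error(p_distance(new_alignment(c("a", "b"), c("A--", "-AA"))),
               "no comparable")
  same <- new_alignment(c("a", "b"), c("MKL", "MKL"))
  expect_equal(p_distance(same)["a", "b"], 0)
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  ids <- c("A", "B", "C")
  d <- matrix(c(0, .3, .5, .3, 0, .6, .5, .6, 0), 3, 3,
              dimnames = list(ids, ids))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-12)
  expect_equal(unname(bl["B"]), (0.3 + 0.6 - 0.5) / 2, tolerance = 1e-12)
  expect_equal(unname(bl["C"]), (0.5 + 0.6 - 0.3) / 2, tolerance = 1e-12)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ is exact on additive matrices and label-order invariant", {
  set.seed(31)
  for (rep in 1:5) {
    tr <- ape::rtree(6)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.4)
    d <- ape::cophenetic.phylo(tr)
    out <- nj_tree(d)
    expect_equal(rf(ape::unroot(tr), out), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(out)[rownames(d), colnames(d)] -
                        d)), 1e-9)
    perm <- sample(rownames(d))
    out2 <- nj_tree(d[perm, perm])
    expect_equal(rf(out, out2), 0)
  }
})

test_that("bootstrap supports saturate on clean signal and are reproducible", {
  aln <- make_clan_alignment(nclan = 2, per = 4, block = 20, seed = 12)
  bs1 <- bootstrap_support(aln, reps = 200, seed = 99)
  bs2 <- bootstrap_support(aln, reps = 200, seed = 99)
  expect_identical(bs1$support, bs2$support)
  expect_true(all(bs1$support >= 0 & bs1$support <= 100))
  # the clan bipartition is saturated
  clan_key <- paste(sort(c("b1", "b2", "b3", "b4")), collapse = "|")
  expect_equal(unname(bs1$support[clan_key]), 100)
  one <- bootstrap_support(aln, reps = 1, seed = 5)
  expect_true(all(one$support %in% c(0, 100)))
})

test_that("Fitch scores match both an exhaustive Sankoff enumeration and phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(17)
  for (rep in 1:4) {
    seqs <- replicate(5, paste(sample(c("A", "R", "N", "D"), 6, TRUE),
                               collapse = ""))
    aln <- new_alignment(paste0("t", 1:5), seqs)
    tr <- ape::unroot(ape::rtree(5, tip.label = aln$ids))
    mine <- fitch_score(tr, aln)
    expect_equal(mine, sankoff_brute(tr, aln$seqs))
    pd <- phangorn::phyDat(stats::setNames(strsplit(unname(aln$seqs), ""),
                                           aln$ids), type = "AA")
    expect_equal(mine, phangorn::parsimony(tr, pd))
  }
  # invariant alignment scores zero; a single A/A/C/C column scores one
  inv <- new_alignment(paste0("t", 1:4), rep("AAAA", 4))
  tr4 <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  expect_equal(fitch_score(tr4, inv), 0)
  col <- new_alignment(paste0("t", 1:4), c("A", "A", "C", "C"))
  expect_equal(fitch_score(tr4, col), 1)
})

test_that("MP search equals exhaustive scoring over hand-enumerated topologies", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  tips <- paste0("t", 1:5)
  cand <- all_5taxon_newicks(tips)
  expect_length(cand, 15L)
  for (rep in 1:5) {
    seqs <- replicate(5, paste(sample(c("A", "R", "N", "D", "K"), 20, TRUE),
                               collapse = ""))
    aln <- new_alignment(tips, seqs)
    pd <- phangorn::phyDat(stats::setNames(strsplit(unname(aln$seqs), ""),
                                           aln$ids), type = "AA")
    oracle <- min(vapply(cand, phangorn::parsimony, 0, data = pd))
    best <- mp_tree(aln)
    expect_equal(unname(attr(best, "pscore")), unname(oracle))
  }
  expect_error(mp_tree(new_alignment(c("a", "b", "c"),
                                     c("AA", "AR", "RR"))), "at least 4")
})

test_that("an alignment with one dominant split yields that split in MP", {
  aln <- make_clan_alignment(nclan = 2, per = 3, block = 15, seed = 4)
  mp <- mp_tree(aln)
  keys <- gofamcat:::bipartition_keys(mp)$key
  expect_true(paste(sort(c("b1", "b2", "b3")), collapse = "|") %in% keys)
})

test_that("two-taxon Poisson ML matches the analytic inversion", {
  L <- 400
  for (p in seq(0.05, 0.60, by = 0.05)) {
    nd <- round(p * L)
    aln <- new_alignment(c("x", "y"),
                         c(strrep("A", L),
                           paste0(strrep("R", nd), strrep("A", L - nd))))
    fit <- ml_tree_poisson(aln)
    t_true <- -(19 / 20) * log(1 - 20 * (nd / L) / 19)
    expect_lt(abs(sum(fit$tree$edge.length) - t_true), 1e-5)
  }
  # identical sequences: MLE at the lower bound (t -> 0)
  same <- ml_tree_poisson(new_alignment(c("x", "y"),
                                        c(strrep("A", 50), strrep("A", 50))))
  expect_lt(sum(same$tree$edge.length), 1e-4)
})

test_that("NJ, MP and ML agree on clean four-taxon signal", {
  aln <- make_clan_alignment(nclan = 2, per = 2, block = 20, seed = 7)
  njt <- nj_tree(p_distance(aln))
  mpt <- mp_tree(aln)
  mlt <- ml_tree_poisson(aln)
  expect_equal(rf(ape::unroot(njt), mpt), 0)
  expect_equal(rf(ape::unroot(njt), ape::unroot(mlt$tree)), 0)
})

test_that("ML log-likelihood agrees with phangorn's equal-rates model", {
  skip_if_not_installed("phangorn")
  set.seed(3)
  seqs <- replicate(6, paste(sample(AA20, 40, TRUE), collapse = ""))
  aln <- new_alignment(paste0("t", 1:6), seqs)
  tr <- nj_tree(p_distance(aln))
  tr$edge.length[tr$edge.length < 1e-6] <- 0.05
  mine <- gofamcat:::ml_loglik(tr, gofamcat:::ml_encode(aln))
  pd <- phangorn::phyDat(stats::setNames(strsplit(unname(aln$seqs), ""),
                                         aln$ids),
                         type = "USER", levels = AA20)
  expect_equal(mine, phangorn::pml(tr, pd, bf = rep(1 / 20, 20))$logLik,
               tolerance = 1e-8)
})

test_that("subfamily calling honours the two-method rule and anchors", {
  aln <- make_clan_alignment(nclan = 3, per = 3, seed = 2)
  njs <- bootstrap_support(aln, reps = 100, seed = 42)
  mp <- mp_tree(aln, seed = 1)
  ml <- ml_tree_poisson(aln)
  anchors <- c(a1 = "S1", b1 = "S2", c1 = "S3")
  cl <- call_subfamilies(njs, mp, ml, anchors)
  for (k in c("a", "b", "c")) {
    nm <- anchors[[paste0(k, "1")]]
    expect_true(all(cl$assignment[paste0(k, 1:3)] == nm))
  }
  # leaf-order permutation of the MP/ML trees changes nothing
  perm <- sample(length(mp$tip.label))
  mp2 <- ape::rotateConstr(mp, mp$tip.label[perm])
  cl2 <- call_subfamilies(njs, mp2, ml, anchors)
  expect_equal(cl2$assignment[names(cl$assignment)], cl$assignment)
  expect_error(call_subfamilies(njs, mp, ml, c(zz = "S9")), "missing")
})

test_that("support exactly at the threshold is rejected (strict >88)", {
  aln <- make_clan_alignment(nclan = 2, per = 3, seed = 5)
  njs <- bootstrap_support(aln, reps = 100, seed = 1)
  mp <- mp_tree(aln, seed = 1)
  ml <- ml_tree_poisson(aln)
  clan_b <- paste(sort(c("b1", "b2", "b3")), collapse = "|")
  njs$support[clan_b] <- 88
  cl <- call_subfamilies(njs, mp, ml, c(a1 = "S1", b1 = "S2"))
  expect_false("S2" %in% cl$assignment[c("b2", "b3")])
  njs$support[clan_b] <- 88.1
  cl2 <- call_subfamilies(njs, mp, ml, c(a1 = "S1", b1 = "S2"))
  expect_true(all(cl2$assignment[c("b1", "b2", "b3")] == "S2"))
})

test_that("a clade present only in NJ is not a subfamily candidate", {
  aln <- make_clan_alignment(nclan = 2, per = 3, seed = 9)
  njs <- bootstrap_support(aln, reps = 100, seed = 1)
  mp <- mp_tree(aln, seed = 1)
  ml <- ml_tree_poisson(aln)
  cl <- call_subfamilies(njs, mp, ml, c(a1 = "S1", b1 = "S2"))
  # fabricate MP/ML trees lacking the S2 clan: swap one b leaf into clan a
  alt <- ape::read.tree(text = "(((a1,b1),(a2,a3)),(b2,b3));")
  cl2 <- call_subfamilies(njs, alt, alt, c(a1 = "S1", b1 = "S2"))
  expect_false(any(cl2$assignment[c("b2", "b3")] == "S2"))
})
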