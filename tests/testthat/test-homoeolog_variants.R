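# Gene-model mapping, genome origin, indels, SSR tracts, insertions.

test_that("CDS-to-genome mapping recovers planted exon chains exactly", {
  # intronless gene: one exon spanning everything
  g0 <- make_gene(cds_length = 300, n_introns = 0, seed = 2)
  m0 <- map_cds_to_genome(g0$cds, g0$genomic)
  expect_equal(nrow(m0$exons), 1L)
  expect_equal(unname(m0$exons[1, ]), c(0L, 300L))

  # multi-exon genes over several seeds
  for (s in 1:5) {
    g <- make_gene(cds_length = 600, n_introns = 4,
                   intron_lengths = c(80, 120, 60, 200), seed = s)
    m <- map_cds_to_genome(g$cds, g$genomic)
    expect_equal(m$exons, g$model$exons, info = paste("seed", s))
  }
  expect_error(make_gene(cds_length = 300, n_introns = 1,
                         intron_lengths = 39), "min_intron")
})

test_that("short or non-canonical introns are rejected by the model invariant", {
  g <- make_gene(cds_length = 300, n_introns = 1, intron_lengths = 60,
                 seed = 3)
  ex <- g$model$exons
  expect_error(gene_model("x", g$genomic, ex, g$cds, min_intron = 100),
               "min_intron")
  # corrupt the donor site: invariant must catch it
  broken <- paste0(substr(g$genomic, 1, ex[1, 2]), "CC",
                   substr(g$genomic, ex[1, 2] + 3L, nchar(g$genomic)))
  expect_error(gene_model("x", broken, ex, g$cds), "GT..AG")
  expect_error(map_cds_to_genome(substr(g$cds, 1, 20), g$genomic),
               "at least 30")
})

test_that("genome origin follows the nearer diploid ortholog", {
  set.seed(4)
  anc <- paste(sample(AA20, 200, TRUE), collapse = "")
  A <- mutate_seq(anc, 0.025, seed = 1)
  D <- mutate_seq(anc, 0.025, seed = 2)
  qA <- mutate_seq(A, 0.01, seed = 3)
  res <- assign_genome_origin(qA, A, D)
  expect_equal(res$origin, "A")
  expect_false(res$ambiguous)
  expect_equal(assign_genome_origin(A, A, D)$margin,
               assign_genome_origin(A, A, D)$dD)
  tie <- assign_genome_origin(A, A, A)
  expect_true(tie$ambiguous)
})

test_that("indel detection reports coordinates, frame, and polarity", {
  g <- make_gene(cds_length = 900, n_introns = 6,
                 intron_lengths = c(120, 90, 150, 600, 80, 110),
                 min_exon = 70, seed = 7)
  pv <- plant_variants(g, deletion = list(exon = 6, offset = 30, length = 15))
  ind <- detect_indels(pv$a$cds, pv$b$cds, pv$a$model)
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$coord, pv$truth$deletion$cds_coord)
  expect_equal(ind$length, 15L)
  expect_true(ind$in_frame)
  expect_equal(ind$exon, 6L)
  expect_equal(ind$deleted_in, "b")
  # anti-symmetry: swapped inputs flip the polarity, same length
  rev <- detect_indels(pv$b$cds, pv$a$cds)
  expect_equal(rev$length, 15L)
  expect_equal(rev$deleted_in, "a")
  # a 4-nt deletion breaks the frame
  pv4 <- plant_variants(g, deletion = list(exon = 2, offset = 3, length = 4))
  expect_false(detect_indels(pv4$a$cds, pv4$b$cds)$in_frame)
  expect_equal(nrow(detect_indels(g$cds, g$cds)), 0L)
})

test_that("SSR runs are maximal, phase-robust, and compared in nucleotides", {
  r <- find_ssr(paste0("AA", strrep("GAA", 7), "TT"), "GAA")
  expect_equal(nrow(r), 1L)
  expect_equal(r$copies, 7L)
  expect_equal(r$start, 2L)
  expect_equal(nrow(find_ssr("GAAGAA", "GAA", min_copies = 4)), 0L)
  expect_error(find_ssr("GAA", ""), "non-empty")
  a <- paste0("ATG", strrep("GAA", 13), "CCC")
  b <- paste0("ATG", strrep("GAA", 9), "CCC")
  expect_equal(ssr_difference(a, b, "GAA")$diff_nt, 12L)
})

test_that("intron insertions and their terminal repeats are recovered", {
  g <- make_gene(cds_length = 600, n_introns = 4,
                 intron_lengths = c(100, 80, 700, 90), seed = 13)
  pv <- plant_variants(g, insertion = list(intron = 3, length = 2000,
                                           tr_length = 300), seed = 5)
  ia <- gofamcat:::model_introns(pv$a$model)
  ib <- gofamcat:::model_introns(pv$b$model)
  hit <- detect_ltr_insertion(ia[3], ib[3])
  expect_equal(hit$in_seq, "b")
  expect_equal(hit$length, 2000L)
  expect_equal(hit$terminal_repeat$length, 300L)
  expect_equal(hit$terminal_repeat$identity, 1.0)
  # insertion without repeats: reported, but no terminal-repeat evidence
  pv2 <- plant_variants(g, insertion = list(intron = 2, length = 800,
                                            tr_length = 0), seed = 6)
  ib2 <- gofamcat:::model_introns(pv2$b$model)
  hit2 <- detect_ltr_insertion(gofamcat:::model_introns(pv2$a$model)[2],
                               ib2[2])
  expect_equal(hit2$length, 800L)
  expect_null(hit2$terminal_repeat)
  expect_null(detect_ltr_insertion(ia[1], ia[1]))
})

test_that("structure comparison flags lost introns via exon fusion", {
  g <- make_gene(cds_length = 700, n_introns = 6,
                 intron_lengths = 80, seed = 21)
  m <- g$model
  # fuse exons 4 and 5 of a copy: intron 4 lost
  ex <- m$exons
  lens <- ex[, 2] - ex[, 1]
  fused_lens <- c(lens[1:3], lens[4] + lens[5], lens[6:7])
  cds <- m$cds
  spans <- cbind(c(0, cumsum(fused_lens))[1:6], cumsum(fused_lens))
  # rebuild a genomic for the fused gene with fresh introns
  nt <- c("A", "C", "G", "T")
  set.seed(1)
  introns <- replicate(5, paste(c("G", "T", sample(nt, 56, TRUE), "A", "G"),
                                collapse = ""))
  pieces <- character(); g2 <- 0L; spans2 <- matrix(0L, 6, 2); p <- 0L
  for (k in 1:6) {
    exseq <- substr(cds, p + 1L, p + fused_lens[k]); p <- p + fused_lens[k]
    pieces <- c(pieces, exseq)
    spans2[k, ] <- c(g2, g2 + nchar(exseq)); g2 <- g2 + nchar(exseq)
    if (k < 6) { pieces <- c(pieces, introns[k]); g2 <- g2 + 60L }
  }
  fused <- gene_model("fused", paste(pieces, collapse = ""), spans2, cds)
  diff <- compare_structures(list(m, fused), tol = 5)
  expect_equal(diff$intron_loss$gene, "fused")
  expect_equal(diff$intron_loss$intron, 4L)
  expect_equal(nrow(compare_structures(list(m, m))$intron_loss), 0L)
  expect_error(compare_structures(list(m)), "at least two")
})

test_that("the consolidated variant report mirrors each planted feature", {
  g <- make_gene(cds_length = 900, n_introns = 6,
                 intron_lengths = c(120, 90, 150, 600, 80, 110),
                 min_exon = 70, seed = 7)
  pv <- plant_variants(
    g,
    deletion = list(exon = 6, offset = 30, length = 15),
    ssr = list(unit = "GAA", copies_a = 13, copies_b = 9, exon = 6,
               offset = 60),
    insertion = list(intron = 4, length = 2000, tr_length = 300), seed = 11)
  vr <- variant_report(pv$a$model, pv$b$model)
  expect_equal(vr$ssr$diff_nt, 12L)
  expect_true(any(vr$indels$length == 15 & vr$indels$in_frame &
                    vr$indels$exon == 6))
  expect_length(vr$insertions, 1L)
  expect_equal(vr$insertions[[1]]$intron, 4L)
  expect_equal(vr$insertions[[1]]$length, 2000L)
})
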