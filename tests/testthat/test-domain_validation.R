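# Consensus-profile construction and the two-rule domain verdict.

spans10 <- list(basic = c(0L, 3L), helix1 = c(3L, 6L), loop = c(6L, 8L),
                helix2 = c(8L, 10L))

test_that("profile columns follow the 60/80 frequency tiers", {
  # 10 identical rows: unanimity, tier 80 everywhere
  aln <- new_alignment(paste0("r", 1:10), rep(strrep("K", 10), 10))
  prof <- build_profile(aln, spans10)
  expect_true(all(vapply(prof$consensus, identical, TRUE, "K")))
  expect_true(all(prof$tier == 80))

  # K x6 / R x4 in one column -> consensus {K}, tier 60
  seqs <- c(rep(strrep("K", 10), 6), rep(paste0("R", strrep("K", 9)), 4))
  prof2 <- build_profile(new_alignment(paste0("r", 1:10), seqs), spans10)
  expect_equal(prof2$consensus[[1]], "K")
  expect_equal(prof2$tier[1], 60)
  expect_equal(prof2$tier[2], 80)

  # 10 distinct residues -> empty consensus, excluded from the rule
  div <- vapply(AA20[1:10], function(a) paste0(a, strrep("K", 9)), "")
  prof3 <- build_profile(new_alignment(paste0("r", 1:10), unname(div)),
                         spans10)
  expect_length(prof3$consensus[[1]], 0)
  expect_true(is.na(prof3$tier[1]))

  bad <- list(basic = c(0L, 3L), helix1 = c(3L, 6L), loop = c(6L, 8L),
              helix2 = c(8L, 12L))
  expect_error(build_profile(aln, bad), "out of range")
})

test_that("candidate mapping reproduces identity and planted deletions", {
  prof <- default_profile()
  mapped <- map_candidate(prof$consensus_seq, prof)
  expect_equal(paste(mapped, collapse = ""), prof$consensus_seq)

  # 2-residue internal deletion -> exactly 2 gap columns
  del <- paste0(substr(prof$consensus_seq, 1, 19),
                substr(prof$consensus_seq, 22, prof$ncols))
  mapped2 <- map_candidate(del, prof)
  expect_equal(sum(mapped2 == "-"), 2L)
  expect_error(map_candidate("", prof), "empty candidate")
})

test_that("the two-rule verdict matches hand counts at the 60% boundary", {
  prof <- default_profile()
  cons_cols <- which(lengths(prof$consensus) > 0)
  expect_length(cons_cols, 22L)

  call <- validate_domain(prof$consensus_seq, prof)
  expect_equal(call$consensus_fraction, 1.0)
  expect_setequal(call$subregions_present, c("basic", "helix1", "helix2"))
  expect_true(call$verdict)

  # candidate matching exactly 13 of 22 consensus columns: 13/22 < 0.60
  ch <- strsplit(prof$consensus_seq, "")[[1]]
  for (j in cons_cols[1:9])
    ch[j] <- setdiff(AA20, prof$consensus[[j]])[1]
  call13 <- validate_domain(paste(ch, collapse = ""), prof)
  expect_equal(call13$consensus_fraction, 13 / 22)
  expect_false(call13$verdict)

  # one fewer miss crosses the strict boundary: 14/22 > 0.60
  ch14 <- strsplit(prof$consensus_seq, "")[[1]]
  for (j in cons_cols[1:8])
    ch14[j] <- setdiff(AA20, prof$consensus[[j]])[1]
  expect_true(validate_domain(paste(ch14, collapse = ""), prof)$verdict)
})

test_that("a candidate covering a single sub-region fails rule 1", {
  prof <- default_profile()
  h2 <- substr(prof$consensus_seq, prof$subregions$helix2[1] + 1L,
               prof$subregions$helix2[2])
  call <- validate_domain(h2, prof)
  expect_lte(length(call$subregions_present), 1L)
  expect_false(call$verdict)
})

test_that("the consensus fraction is monotone under consensus-column mutation", {
  prof <- default_profile()
  cons_cols <- which(lengths(prof$consensus) > 0)
  base <- validate_domain(prof$consensus_seq, prof)$consensus_fraction
  set.seed(3)
  frac <- base
  ch <- strsplit(prof$consensus_seq, "")[[1]]
  for (j in sample(cons_cols, 10)) {
    ch[j] <- setdiff(AA20, prof$consensus[[j]])[1]
    f <- validate_domain(paste(ch, collapse = ""), prof)$consensus_fraction
    expect_lte(f, frac)
    frac <- f
  }
})

test_that("the verdict ignores metadata and honours candidate rows", {
  prof <- default_profile()
  fam <- make_family(n_subfam = 2, genes_per_subfam = 2, seed = 6)
  span <- fam$domain_span
  doms <- substr(fam$records$residues, span[1] + 1L, span[2])
  verdicts <- vapply(doms, function(d) validate_domain(d, prof)$verdict,
                     TRUE)
  expect_true(all(verdicts))   # planted domains keep every consensus column
  row <- data.frame(residues = doms[1], source = "GrJGI",
                    description = "anything")
  expect_equal(validate_domain(row, prof)$verdict,
               validate_domain(doms[1], prof)$verdict)
})
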