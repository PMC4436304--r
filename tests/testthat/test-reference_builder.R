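# Guide-tree construction, BL-threshold grouping, coding, and overlap.

test_that("identical tandem copies merge within a source only", {
  rec <- seq_records(c("t1", "t2", "t3", "o1"),
                     c("MKLV", "MKLV", "MKIV", "MKLV"),
                     source = c("GaCGP", "GaCGP", "GaCGP", "GrJGI"))
  out <- collapse_identical_tandem(rec)
  expect_equal(nrow(out), 3L)            # t1+t2 merge; o1 kept (other source)
  expect_match(out$description[out$id == "t1"], "tandem_identical:t2")
  expect_true(all(c("t3", "o1") %in% out$id))
  distinct <- seq_records(c("a", "b", "c"), c("MK", "ML", "MV"))
  expect_equal(nrow(collapse_identical_tandem(distinct)), 3L)
})

test_that("guide-tree BL reflects sequence divergence", {
  set.seed(5)
  base <- paste(sample(AA20, 500, TRUE), collapse = "")
  # differ at exactly 10% of sites
  ch <- strsplit(base, "")[[1]]
  flip <- seq_len(50)
  ch[flip] <- vapply(ch[flip], function(a) setdiff(AA20, a)[1], "")
  g <- build_guide_tree(seq_records(c("a", "b"),
                                    c(base, paste(ch, collapse = ""))))
  expect_equal(g$bl["a", "b"], g$bl["b", "a"])
  expect_lt(abs(g$bl["a", "b"] - 0.10), 0.02)
  same <- build_guide_tree(seq_records(c("a", "b"), c(base, base)))
  expect_equal(same$bl["a", "b"], 0)
  expect_error(build_guide_tree(seq_records("a", base)), "at least 2")
})

fake_guide <- function(bl) {
  structure(list(tree = NULL, bl = bl, pdist = bl), class = "gf_guidetree")
}

test_that("threshold grouping is single linkage with labelled bands", {
  ids <- c("A", "B", "C", "D")
  bl <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  diag(bl) <- 0
  bl["A", "B"] <- bl["B", "A"] <- 0.01
  bl["A", "C"] <- bl["C", "A"] <- 0.10
  bl["B", "C"] <- bl["C", "B"] <- 0.10
  groups <- group_by_thresholds(fake_guide(bl))
  members <- lapply(groups, `[[`, "members")
  expect_true(any(vapply(members, identical, TRUE, c("A", "B", "C"))))
  expect_true(any(vapply(members, identical, TRUE, "D")))
  abc <- groups[[which(vapply(members, length, 0L) == 3)]]
  lab <- with(abc$pair_labels, stats::setNames(label, paste(id_a, id_b)))
  expect_equal(unname(lab["A B"]), "allele")
  expect_equal(unname(lab["A C"]), "ortholog")
  expect_equal(unname(lab["B C"]), "ortholog")
})

test_that("all-distant records give singleton groups; chaining is flagged", {
  ids <- paste0("g", 1:5)
  bl <- matrix(0.4, 5, 5, dimnames = list(ids, ids)); diag(bl) <- 0
  expect_length(group_by_thresholds(fake_guide(bl)), 5L)

  ids3 <- c("A", "B", "C")
  bl3 <- matrix(c(0, 0.14, 0.20, 0.14, 0, 0.14, 0.20, 0.14, 0), 3, 3,
                dimnames = list(ids3, ids3))
  expect_warning(groups <- group_by_thresholds(fake_guide(bl3)), "chaining")
  expect_length(groups, 1L)
  lab <- groups[[1]]$pair_labels
  expect_equal(lab$label[lab$id_a == "A" & lab$id_b == "C"], "chained")
  expect_error(group_by_thresholds(fake_guide(bl3), allele_thr = 0.2,
                                   ortholog_thr = 0.1), "thresholds")
})

test_that("representative choice follows source priority then smallest id", {
  rec <- seq_records(c("x2", "x1", "y9"), c("MK", "ML", "MV"),
                     source = c("GaCGP", "GrJGI", "GaCGP"))
  g <- list(members = c("x1", "x2", "y9"))
  expect_equal(select_representative(g, rec), "x1")       # GrJGI wins
  rec2 <- seq_records(c("m2", "m1"), c("MK", "ML"), source = "mRNA")
  expect_equal(select_representative(list(members = c("m2", "m1")), rec2),
               "m1")                                      # tie -> smaller id
})

test_that("codes follow natural sort of representatives, from 001", {
  groups <- lapply(c("zzz", "aaa", "mmm"), function(r)
    list(members = r, representative = r, code = NA))
  coded <- assign_codes(groups)
  expect_equal(vapply(coded, `[[`, "", "code"),
               c("GobHLH001", "GobHLH002", "GobHLH003"))
  expect_equal(vapply(coded, `[[`, "", "representative"),
               c("aaa", "mmm", "zzz"))
  # natural sort: g2 before g10
  g2 <- lapply(c("g10", "g2"), function(r)
    list(members = r, representative = r, code = NA))
  expect_equal(vapply(assign_codes(g2), `[[`, "", "representative"),
               c("g2", "g10"))
  expect_length(assign_codes(list()), 0L)
})

test_that("the overlap matrix counts shared groups symmetrically", {
  rec <- seq_records(c("r1", "r2", "a1"), c("MK", "ML", "MV"),
                     source = c("GrJGI", "GrJGI", "GaCGP"))
  groups <- list(list(members = c("r1", "a1")), list(members = "r2"))
  m <- overlap_matrix(groups, rec)
  expect_equal(m["GrJGI", "GrJGI"], 2L)
  expect_equal(m["GaCGP", "GaCGP"], 1L)
  expect_equal(m["GrJGI", "GaCGP"], 1L)
  expect_equal(m, t(m))
  single <- overlap_matrix(list(list(members = "r1")), rec)
  expect_true(all(single[upper.tri(single)] == 0))
})

test_that("grouping recovers the planted partition and ignores input order", {
  fam <- make_family(n_subfam = 3, genes_per_subfam = 3, seed = 8)
  ref <- build_reference(fam$records)
  lab <- groups_as_labels(ref$groups)
  truth <- fam$truth$gene[match(names(lab), fam$truth$id)]
  expect_equal(ari(lab, truth), 1.0)
  expect_length(ref$groups, length(unique(fam$truth$gene)))
  # permuting the record order leaves the partition unchanged
  perm <- fam$records[rev(seq_len(nrow(fam$records))), ]
  ref2 <- build_reference(perm)
  lab2 <- groups_as_labels(ref2$groups)
  expect_equal(ari(lab[names(lab2)], lab2), 1.0)
  # every record belongs to exactly one group (true partition)
  expect_setequal(names(lab), fam$records$id)
  expect_equal(anyDuplicated(names(lab)), 0L)
})
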