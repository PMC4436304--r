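# Collapsing multi-source redundancy into a coded reference gene set.
#
# Validated proteins from all annotation sources are placed on a guide
# tree; leaf-to-leaf branch-length (patristic) distances BL partition them:
# BL < 0.03 allele copies, 0.03-0.15 orthologs of different genomes,
# > 0.15 distinct paralogs.  Single-linkage clusters at the 0.15 cut are
# the orthologous groups; one representative per group (source-priority,
# diploid D-genome project first) is coded GobHLHnnn.

#' Merge identical tandem copies within a source
#'
#' Within one source, records with byte-identical protein sequences are
#' merged into a single record (absorbed ids recorded in the description).
#' Identical records from different sources are never merged here.
#'
#' @param records sequence records tagged with `source`.
#' @return collapsed record `data.frame`.
#' @export
collapse_identical_tandem <- function(records) {
  keep <- rep(TRUE, nrow(records))
  desc <- records$description
  key <- paste(records$source, records$residues, sep = "\r")
  first <- !duplicated(key)
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    absorbed <- records$id[idx[-1]]
    desc[idx[1]] <- trimws(paste(desc[idx[1]],
                                 paste0("tandem_identical:",
                                        paste(absorbed, collapse = ","))))
    keep[idx[-1]] <- FALSE
  }
  out <- records[keep & first, , drop = FALSE]
  out$description <- desc[keep & first]
  rownames(out) <- NULL
  out
}

#' Build an alignment guide tree and its branch-length matrix
#'
#' Pairwise p-distances (from global alignments; an exact Hamming fast
#' path is used when all sequences have equal length, where the gapless
#' alignment is the global optimum for substitution-only divergence) feed
#' neighbour joining; BL(i,j) is the patristic distance on that tree.
#'
#' @param records >= 2 sequence records.
#' @return a list of class `"gf_guidetree"`: `tree` (phylo), `bl`
#'   (symmetric patristic matrix), `pdist` (the input distance matrix).
#' @export
build_guide_tree <- function(records) {
  n <- nrow(records)
  if (n < 2) stopf("guide tree requires at least 2 records")
  d <- pdist_matrix(records$residues, records$id,
                    moltype = records$moltype[1])
  if (n == 2) {
    tree <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);", records$id[1],
                                          d[1, 2] / 2, records$id[2],
                                          d[1, 2] / 2))
    bl <- d
  } else {
    tree <- nj_tree(d)
    bl <- ape::cophenetic.phylo(tree)[records$id, records$id]
  }
  structure(list(tree = tree, bl = bl, pdist = d), class = "gf_guidetree")
}

# pairwise p-distance matrix over sequence strings
pdist_matrix <- function(seqs, ids, moltype = "protein") {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (length(unique(nchar(seqs))) == 1L) {
    # equal lengths: vectorised Hamming via one-hot crossproduct
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    L <- ncol(m)
    lev <- sort(unique(as.vector(m)))
    oh <- matrix(0L, n, L * length(lev))
    for (k in seq_along(lev))
      oh[, (k - 1L) * L + seq_len(L)] <- (m == lev[k]) + 0L
    shared <- tcrossprod(oh)
    d <- 1 - shared / L
    dimnames(d) <- list(ids, ids)
    diag(d) <- 0
  } else {
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      d[i, j] <- d[j, i] <- pairwise_pdist(seqs[i], seqs[j], moltype)
    }
  }
  d
}

#' Partition records into orthologous groups by BL thresholds
#'
#' Single-linkage clustering of the guide-tree BL matrix cut at
#' `ortholog_thr` (pairs at BL <= 0.15 connect; closed boundary).  Within a
#' group every pair is labelled `allele` (BL < 0.03), `ortholog`
#' (0.03 <= BL <= 0.15), or `chained` (BL > 0.15, joined only through
#' linkage chaining; kept but flagged).
#'
#' @param guide a `gf_guidetree`.
#' @param allele_thr,ortholog_thr the BL band boundaries.
#' @return list of groups; each has `members` (ids), `pair_labels`
#'   (data.frame id_a, id_b, bl, label), and placeholders for
#'   `representative` and `code`.
#' @export
group_by_thresholds <- function(guide, allele_thr = 0.03,
                                ortholog_thr = 0.15) {
  if (!(allele_thr > 0 && allele_thr < ortholog_thr))
    stopf("thresholds must satisfy 0 < allele_thr < ortholog_thr")
  bl <- guide$bl
  ids <- rownames(bl)
  if (length(ids) == 1L) {
    cl <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(bl), method = "single")
    cl <- stats::cutree(hc, h = ortholog_thr)
  }
  groups <- lapply(sort(unique(cl)), function(g) {
    mem <- sort(ids[cl == g])
    pairs <- if (length(mem) > 1) {
      cmb <- utils::combn(mem, 2)
      data.frame(id_a = cmb[1, ], id_b = cmb[2, ],
                 bl = bl[cbind(cmb[1, ], cmb[2, ])],
                 stringsAsFactors = FALSE)
    } else data.frame(id_a = character(), id_b = character(), bl = numeric())
    pairs$label <- ifelse(pairs$bl < allele_thr, "allele",
                          ifelse(pairs$bl <= ortholog_thr, "ortholog",
                                 "chained"))
    if (any(pairs$label == "chained"))
      warnf("group {%s} contains pair(s) beyond ortholog_thr joined by linkage chaining",
            paste(mem, collapse = ","))
    list(members = mem, pair_labels = pairs,
         representative = NA_character_, code = NA_character_)
  })
  groups
}

#' Pick a group representative by source priority
#'
#' @param group one group from [group_by_thresholds()].
#' @param records the record table (for source lookup).
#' @param priority source preference order, best first.
#' @return the chosen member id.
#' @export
select_representative <- function(group, records,
                                  priority = c("GrJGI", "GrCGP", "GaCGP",
                                               "GhUni", "GoCon", "mRNA",
                                               "user")) {
  src <- records$source[match(group$members, records$id)]
  rank <- match(src, priority)
  if (anyNA(rank)) stopf("member source outside the priority list")
  best <- group$members[rank == min(rank)]
  sort(best)[1]
}

#' Assign reference codes to groups
#'
#' Groups are ordered by natural sort of their representative ids and coded
#' `<prefix><nnn>` with a zero-padded index from 001.
#'
#' @param groups groups with representatives selected.
#' @param prefix code prefix (default `"GobHLH"`).
#' @param width zero-pad width.
#' @return the groups, reordered, with `code` filled in.
#' @export
assign_codes <- function(groups, prefix = "GobHLH", width = 3) {
  if (!length(groups)) return(groups)
  reps <- vapply(groups, function(g) g$representative, "")
  if (anyNA(reps)) stopf("representatives must be selected before coding")
  groups <- groups[natural_order(reps)]
  for (i in seq_along(groups))
    groups[[i]]$code <- sprintf("%s%0*d", prefix, width, i)
  groups
}

#' Source-overlap matrix of a grouped reference set
#'
#' Diagonal: number of groups with at least one member of that source.
#' Off-diagonal (s, t): groups containing members of both s and t.
#'
#' @param groups coded groups.
#' @param records the record table.
#' @param sources source order for the matrix rows/columns.
#' @return an integer matrix.
#' @export
overlap_matrix <- function(groups, records,
                           sources = intersect(SOURCE_LEVELS,
                                               unique(records$source))) {
  m <- matrix(0L, length(sources), length(sources),
              dimnames = list(sources, sources))
  for (g in groups) {
    src <- unique(records$source[match(g$members, records$id)])
    src <- intersect(sources, src)
    for (s in src) for (t in src) m[s, t] <- m[s, t] + 1L
  }
  m
}

#' Build a coded reference set from multi-source records
#'
#' Convenience wrapper: collapse identical tandems, build the guide tree,
#' group by BL thresholds, select representatives, assign codes.
#'
#' @inheritParams group_by_thresholds
#' @param records validated protein records from all sources.
#' @param prefix reference code prefix.
#' @return list of class `"gf_refset"`: `groups`, `records`, `guide`,
#'   `overlap`.
#' @export
build_reference <- function(records, allele_thr = 0.03, ortholog_thr = 0.15,
                            prefix = "GobHLH") {
  records <- collapse_identical_tandem(records)
  guide <- build_guide_tree(records)
  groups <- group_by_thresholds(guide, allele_thr, ortholog_thr)
  for (i in seq_along(groups))
    groups[[i]]$representative <- select_representative(groups[[i]], records)
  groups <- assign_codes(groups, prefix)
  structure(list(groups = groups, records = records, guide = guide,
                 overlap = overlap_matrix(groups, records)),
            class = "gf_refset")
}

#' @export
print.gf_refset <- function(x, ...) {
  cat(sprintf("Reference set: %d groups from %d records (%d sources)\n",
              length(x$groups), nrow(x$records),
              length(unique(x$records$source))))
  invisible(x)
}
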