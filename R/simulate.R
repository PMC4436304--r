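# Synthetic families, genes, variants and Ct tables with planted truth.
#
# The generator emulates the study conditions the pipeline was built for:
# subfamily-structured protein families whose copy layers diverge inside
# the branch-length bands (allele < 0.03, A/D ortholog 0.03-0.15, paralog
# > 0.15), fragmented annotation sources with dropout, exon-intron gene
# structures with planted in-frame deletions, (GAA)n tract differences and
# terminal-repeat-flanked insertions, and dual-reference Ct tables.
# Divergence is controlled through substitution rates and verified post
# hoc against the bands, so threshold tests stay honest.

#' Mutate a sequence by i.i.d. substitutions
#'
#' Each site is substituted with probability `rate`, uniformly over the
#' alternative residues.  Deterministic per seed.
#'
#' @param seq sequence string.
#' @param rate per-site substitution probability in \[0, 1).
#' @param seed RNG seed (NULL = current stream).
#' @param alphabet residue alphabet (default the 20 amino acids).
#' @param protect 1-based positions never mutated.
#' @return the mutated sequence string.
#' @export
mutate_seq <- function(seq, rate, seed = NULL, alphabet = AA_LETTERS,
                       protect = integer()) {
  if (rate < 0 || rate >= 1) stopf("rate must be in [0, 1)")
  with_seed(seed, {
    ch <- s2c(seq)
    idx <- setdiff(seq_along(ch), protect)
    hit <- idx[stats::runif(length(idx)) < rate]
    for (i in hit) ch[i] <- sample(setdiff(alphabet, ch[i]), 1)
    c2s(ch)
  })
}

# expected p-distance between two copies each mutated from one ancestor at
# per-site rate r (uniform over 19 alternatives)
two_branch_p <- function(r) 2 * r * (1 - r) + r^2 * 18 / 19

# per-site rate realising a target p-distance over the mutable fraction
rate_for <- function(target, mutable_frac, branches = 2) {
  q <- target / mutable_frac
  if (q >= 0.9) stopf("divergence target too large for the sequence design")
  if (branches == 1) return(q)
  stats::uniroot(function(r) two_branch_p(r) - q, c(0, 0.6))$root
}

#' Generate a subfamily-structured protein family with planted truth
#'
#' Subfamily founders share the consensus profile's conserved columns (so
#' every planted domain validates) and diverge freely elsewhere; gene
#' founders diverge at `paralog_div`, A/D genome copies at `ortholog_div`,
#' and allele copies at `allele_div`.  Realised class-mean divergences are
#' checked post hoc against the requested targets (within +/-30%).
#'
#' @param n_subfam number of subfamilies.
#' @param genes_per_subfam genes per subfamily.
#' @param allele_div,ortholog_div,paralog_div target p-distances; must
#'   respect `allele_div < 0.03 < ortholog_div < 0.15 < paralog_div`.
#' @param profile a `gf_profile` defining the domain layout (default
#'   [default_profile()]).
#' @param flanks lengths of the N- and C-terminal flanks around the domain.
#' @param seed RNG seed.
#' @return list of class `"gf_family"`: `records` (all gene copies),
#'   `truth` (per copy: id, gene, subfamily, genome, copy), `anchors`
#'   (one founder record per subfamily, named `anchor_<subfamily>`),
#'   `anchor_map` (anchor id -> subfamily), `domain_span` (0-based span of
#'   the planted domain in every protein), `realized` (class-mean
#'   divergences).
#' @export
make_family <- function(n_subfam = 6, genes_per_subfam = 4,
                        allele_div = 0.01, ortholog_div = 0.08,
                        paralog_div = 0.45, profile = default_profile(),
                        flanks = c(100, 145), seed = 1) {
  if (!(allele_div < 0.03 && 0.03 < ortholog_div && ortholog_div < 0.15 &&
        0.15 < paralog_div))
    stopf("divergence targets must respect the bands allele < 0.03 < ortholog < 0.15 < paralog")
  with_seed(seed, {
    dom <- profile$consensus_seq
    dom_len <- nchar(dom)
    L <- flanks[1] + dom_len + flanks[2]
    dom_cols <- flanks[1] + seq_len(dom_len)
    cons_cols <- flanks[1] + which(lengths(profile$consensus) > 0)
    sig_cols <- setdiff(dom_cols, cons_cols)  # subfamily signature columns
    mut_frac <- (L - length(dom_cols)) / L    # band divergence: flanks only
    r_sub <- 0.55                             # deep subfamily flank split
    r_sig <- 0.05                             # slow domain drift per gene
    r_gene <- rate_for(paralog_div, mut_frac, 2)
    r_orth <- rate_for(ortholog_div, mut_frac, 2)
    r_alle <- rate_for(allele_div, mut_frac, 1)
    base <- c2s(c(sample(AA_LETTERS, flanks[1], TRUE), s2c(dom),
                  sample(AA_LETTERS, flanks[2], TRUE)))
    ids <- character(); seqs <- character()
    gene_lab <- character(); sub_lab <- character()
    genome_lab <- character(); copy_lab <- character()
    anchor_ids <- character(); anchor_seqs <- character()
    for (s in seq_len(n_subfam)) {
      # subfamily founder: fresh signature in the domain's variable
      # columns (conserved within the subfamily, distinct between), plus
      # deep flank divergence
      sfc <- s2c(mutate_seq(base, r_sub, protect = dom_cols))
      sfc[sig_cols] <- sample(AA_LETTERS, length(sig_cols), TRUE)
      sf <- c2s(sfc)
      snm <- sprintf("S%d", s)
      anchor_ids <- c(anchor_ids, sprintf("anchor_%s", snm))
      anchor_seqs <- c(anchor_seqs, sf)
      for (g in seq_len(genes_per_subfam)) {
        gf <- mutate_seq(sf, r_gene, protect = dom_cols)
        gf <- mutate_seq(gf, r_sig,
                         protect = setdiff(seq_len(L), sig_cols))
        gnm <- sprintf("%sg%02d", snm, g)
        copies <- list(A1 = NULL, A2 = NULL, D1 = NULL, D2 = NULL)
        copies$A1 <- mutate_seq(gf, r_orth, protect = dom_cols)
        copies$D1 <- mutate_seq(gf, r_orth, protect = dom_cols)
        copies$A2 <- mutate_seq(copies$A1, r_alle, protect = dom_cols)
        copies$D2 <- mutate_seq(copies$D1, r_alle, protect = dom_cols)
        for (cp in names(copies)) {
          ids <- c(ids, paste0(gnm, cp))
          seqs <- c(seqs, copies[[cp]])
          gene_lab <- c(gene_lab, gnm); sub_lab <- c(sub_lab, snm)
          genome_lab <- c(genome_lab, substr(cp, 1, 1))
          copy_lab <- c(copy_lab, cp)
        }
      }
    }
    truth <- data.frame(id = ids, gene = gene_lab, subfamily = sub_lab,
                        genome = genome_lab, copy = copy_lab,
                        stringsAsFactors = FALSE)
    records <- seq_records(ids, seqs)
    realized <- family_band_check(records, truth,
                                  c(allele = allele_div,
                                    ortholog = ortholog_div,
                                    paralog = paralog_div))
    anchors <- seq_records(anchor_ids, anchor_seqs)
    structure(list(records = records, truth = truth, anchors = anchors,
                   anchor_map = stats::setNames(
                     sprintf("S%d", seq_len(n_subfam)), anchor_ids),
                   domain_span = c(flanks[1], flanks[1] + nchar(dom)),
                   realized = realized),
              class = "gf_family")
  })
}

# verify realised class-mean divergences against targets (+/- 30%)
family_band_check <- function(records, truth, targets) {
  seqs <- stats::setNames(records$residues, records$id)
  ham <- function(a, b) {
    x <- s2c(seqs[[a]]); y <- s2c(seqs[[b]])
    mean(x != y)
  }
  allele <- ortholog <- paralog <- numeric()
  for (g in unique(truth$gene)) {
    ids <- truth$id[truth$gene == g]
    cp <- truth$copy[truth$gene == g]
    allele <- c(allele,
                ham(ids[cp == "A1"], ids[cp == "A2"]),
                ham(ids[cp == "D1"], ids[cp == "D2"]))
    ortholog <- c(ortholog, ham(ids[cp == "A1"], ids[cp == "D1"]))
  }
  for (s in unique(truth$subfamily)) {
    genes <- unique(truth$gene[truth$subfamily == s])
    if (length(genes) < 2) next
    cmb <- utils::combn(genes, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- truth$id[truth$gene == cmb[1, k] & truth$copy == "A1"]
      b <- truth$id[truth$gene == cmb[2, k] & truth$copy == "A1"]
      paralog <- c(paralog, ham(a, b))
    }
  }
  realized <- c(allele = mean(allele), ortholog = mean(ortholog),
                paralog = if (length(paralog)) mean(paralog) else NA)
  npairs <- c(allele = length(allele), ortholog = length(ortholog),
              paralog = length(paralog))
  L <- nchar(seqs[[1]])
  for (nm in names(targets)) {
    if (is.na(realized[nm])) next
    # tolerance: 30% of the target, or 3 standard errors of the class
    # mean under binomial site sampling, whichever is wider
    se <- sqrt(targets[nm] * (1 - targets[nm]) / (L * npairs[nm]))
    tol <- max(0.30 * targets[nm], 3 * se)
    if (abs(realized[nm] - targets[nm]) > tol)
      stopf("realized %s divergence %.4f misses the requested %.3f by more than the calibration tolerance",
            nm, realized[nm], targets[nm])
  }
  realized
}

#' Distribute family copies over emulated annotation sources
#'
#' Mimics fragmented, partially redundant annotation sources: the two
#' D-genome annotations carry the two D alleles, the A-genome annotation
#' an A allele, and the tetraploid-derived sources carry copies of both
#' genomes.  Per source and gene, the gene is included with probability
#' `1 - dropout`; every gene is guaranteed to survive in at least one
#' source (redrawn otherwise).  Ids are suffixed `@source`.
#'
#' @param family a `gf_family`.
#' @param dropout per-(source, gene) omission probability in \[0, 1).
#' @param seed RNG seed.
#' @return named list of per-source record `data.frame`s.
#' @export
emulate_sources <- function(family, dropout = 0.1, seed = 1) {
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  plan <- list(GrJGI = "D1", GrCGP = "D2", GaCGP = "A1",
               GhUni = c("A2", "D2"), GoCon = c("A1", "D1"), mRNA = "A2")
  truth <- family$truth
  genes <- unique(truth$gene)
  with_seed(seed, {
    keep <- matrix(FALSE, length(genes), length(plan),
                   dimnames = list(genes, names(plan)))
    for (g in seq_along(genes)) {
      repeat {
        keep[g, ] <- stats::runif(length(plan)) >= dropout
        if (any(keep[g, ])) break
      }
    }
    out <- list()
    for (src in names(plan)) {
      rows <- truth[truth$copy %in% plan[[src]] &
                      keep[truth$gene, src], , drop = FALSE]
      if (!nrow(rows)) {
        out[[src]] <- seq_records(character(0), character(0))[0, ]
        next
      }
      rec <- family$records[match(rows$id, family$records$id), , drop = FALSE]
      out[[src]] <- seq_records(paste0(rec$id, "@", src), rec$residues,
                                source = src,
                                description = paste("copy of", rec$id))
    }
    out
  })
}

#' Generate a synthetic gene with known exon-intron structure
#'
#' Builds a random CDS and inserts introns with GT..AG ends at random
#' internal exon boundaries; the true gene model is returned alongside.
#' Insertion points are chosen so that exon-boundary placement is
#' unambiguous for exact-match mapping.
#'
#' @param cds_length CDS length in nt (multiple of 3 recommended).
#' @param n_introns number of introns.
#' @param intron_lengths vector of intron lengths (recycled), all >=
#'   `min_intron`.
#' @param min_intron minimum intron length.
#' @param min_exon minimum exon length (every exon, including the first
#'   and last, is at least this long).
#' @param seed RNG seed.
#' @param gene_id identifier for the generated gene.
#' @return list of class `"gf_synth_gene"`: `cds`, `genomic`, `model`
#'   (the true `gf_gene_model`).
#' @export
make_gene <- function(cds_length = 900, n_introns = 6,
                      intron_lengths = 120, min_intron = 40,
                      min_exon = 20, seed = 1, gene_id = "synth_gene") {
  intron_lengths <- rep_len(intron_lengths, max(n_introns, 1))
  if (n_introns > 0 && any(intron_lengths < min_intron))
    stopf("intron lengths must be >= min_intron (%d)", min_intron)
  with_seed(seed, {
    nt <- c("A", "C", "G", "T")
    cds <- c2s(c("A", "T", "G", sample(nt, cds_length - 3, TRUE)))
    if (n_introns == 0) {
      model <- gene_model(gene_id, cds, cbind(0L, nchar(cds)), cds,
                          min_intron)
      return(structure(list(cds = cds, genomic = cds, model = model),
                       class = "gf_synth_gene"))
    }
    if ((n_introns + 1L) * min_exon > cds_length)
      stopf("cds_length too short for %d exons of >= %d nt",
            n_introns + 1L, min_exon)
    cv <- s2c(cds)
    slack <- cds_length - (n_introns + 1L) * min_exon
    bnd <- NULL
    repeat {
      x <- sort(sample.int(slack + 1L, n_introns, replace = TRUE) - 1L)
      bnd <- x + min_exon * seq_len(n_introns)
      # the base after each boundary must not be G, so that exact-match
      # exon extension cannot run into the intron's GT donor
      bad <- which(cv[bnd + 1L] == "G")
      for (i in bad) {
        lo <- if (i == 1) min_exon else bnd[i - 1] + min_exon
        hi <- if (i == n_introns) cds_length - min_exon else
          bnd[i + 1] - min_exon
        for (d in c(1L, -1L, 2L, -2L, 3L, -3L)) {
          nb <- bnd[i] + d
          if (nb >= lo && nb <= hi && cv[nb + 1L] != "G") {
            bnd[i] <- nb
            break
          }
        }
      }
      if (all(cv[bnd + 1L] != "G")) break
    }
    introns <- vapply(intron_lengths[seq_len(n_introns)], function(L)
      c2s(c("G", "T", sample(nt, L - 4, TRUE), "A", "G")), "")
    pieces <- character(); exons <- matrix(0L, n_introns + 1, 2)
    prev <- 0L; gpos <- 0L
    for (i in seq_len(n_introns)) {
      ex <- substr(cds, prev + 1L, bnd[i])
      pieces <- c(pieces, ex, introns[i])
      exons[i, ] <- c(gpos, gpos + nchar(ex))
      gpos <- gpos + nchar(ex) + nchar(introns[i])
      prev <- bnd[i]
    }
    ex <- substr(cds, prev + 1L, cds_length)
    pieces <- c(pieces, ex)
    exons[n_introns + 1, ] <- c(gpos, gpos + nchar(ex))
    genomic <- paste(pieces, collapse = "")
    model <- gene_model(gene_id, genomic, exons, cds, min_intron)
    structure(list(cds = cds, genomic = genomic, model = model),
              class = "gf_synth_gene")
  })
}

#' Plant homoeolog variants into an orthologous gene pair
#'
#' Starting from one synthetic gene, builds an orthologous pair where the
#' second copy carries the requested variants: an exonic deletion, an SSR
#' copy-number difference (the tract is planted in both copies), and/or an
#' intronic insertion flanked by identical direct terminal repeats.
#'
#' @param gene a `gf_synth_gene`.
#' @param deletion `NULL` or list(exon, offset, length) -- removed from
#'   copy B.
#' @param ssr `NULL` or list(unit, copies_a, copies_b, exon, offset).
#' @param insertion `NULL` or list(intron, length, tr_length) -- inserted
#'   into copy B's intron at its midpoint.
#' @param seed RNG seed (for the insertion's random core/repeat content).
#' @return list of class `"gf_variant_pair"`: `a`, `b` (each `cds`,
#'   `genomic`, `model`), `truth` (realised coordinates: deletion CDS
#'   coordinate on copy A, SSR copy numbers, insertion length and TR
#'   length).
#' @export
plant_variants <- function(gene, deletion = NULL, ssr = NULL,
                           insertion = NULL, seed = 1) {
  model <- gene$model
  nex <- nrow(model$exons)
  exon_seq <- function(m, i) substring(m$genomic, m$exons[i, 1] + 1L,
                                       m$exons[i, 2])
  ex_a <- vapply(seq_len(nex), function(i) exon_seq(model, i), "")
  intr_a <- model_introns(model)
  ex_b <- ex_a; intr_b <- intr_a
  truth <- list()
  if (!is.null(ssr)) {
    tract_a <- strrep(ssr$unit, ssr$copies_a)
    tract_b <- strrep(ssr$unit, ssr$copies_b)
    e <- ssr$exon; o <- ssr$offset
    if (e > nex || o > nchar(ex_a[e])) stopf("SSR feature outside the gene")
    ex_a[e] <- paste0(substr(ex_a[e], 1, o), tract_a,
                      substr(ex_a[e], o + 1L, nchar(ex_a[e])))
    ex_b[e] <- paste0(substr(ex_b[e], 1, o), tract_b,
                      substr(ex_b[e], o + 1L, nchar(ex_b[e])))
    truth$ssr <- list(unit = ssr$unit, copies_a = ssr$copies_a,
                      copies_b = ssr$copies_b,
                      diff_nt = (ssr$copies_a - ssr$copies_b) *
                        nchar(ssr$unit))
  }
  if (!is.null(deletion)) {
    e <- deletion$exon; o <- deletion$offset; L <- deletion$length
    lens_b <- nchar(ex_b)
    if (e > nex || o + L > lens_b[e])
      stopf("deletion outside exon %d", e)
    if (!is.null(ssr) && ssr$exon == e && o + L > ssr$offset)
      stopf("planted features overlap (deletion must precede the SSR tract)")
    # a deleted segment whose edge bases repeat the flanking context can be
    # represented by a slid alignment gap; nudge the offset until the
    # planted coordinate is the only representation
    pre <- s2c(paste(ex_b, collapse = ""))
    base <- sum(lens_b[seq_len(e - 1)])
    n <- length(pre)
    unambiguous <- function(o) {
      c0 <- base + o
      (c0 + L >= n || pre[c0 + 1L] != pre[c0 + L + 1L]) &&
        (c0 == 0 || pre[c0 + L] != pre[c0])
    }
    hi <- if (!is.null(ssr) && ssr$exon == e) ssr$offset else lens_b[e]
    for (d in c(0L, as.vector(rbind(1:10, -(1:10))))) {
      oo <- o + d
      if (oo >= 0 && oo + L <= hi && unambiguous(oo)) {
        o <- oo
        break
      }
    }
    ex_b[e] <- paste0(substr(ex_b[e], 1, o),
                      substr(ex_b[e], o + L + 1L, lens_b[e]))
    lens_a <- nchar(ex_a)
    truth$deletion <- list(exon = e, offset = o, length = L,
                           in_frame = L %% 3L == 0L,
                           cds_coord = sum(lens_a[seq_len(e - 1)]) + o)
  }
  if (!is.null(insertion)) {
    i <- insertion$intron
    if (i > length(intr_b)) stopf("insertion names a missing intron")
    with_seed(seed, {
      tr <- c2s(sample(c("A", "C", "G", "T"), insertion$tr_length, TRUE))
      core_len <- insertion$length - 2L * insertion$tr_length
      if (core_len < 0) stopf("tr_length too large for insertion length")
      core <- c2s(sample(c("A", "C", "G", "T"), core_len, TRUE))
      seg <- paste0(tr, core, tr)
      iv <- s2c(intr_b[i])
      ni <- length(iv)
      first <- substr(seg, 1, 1)
      last <- substr(seg, insertion$length, insertion$length)
      # pick an insertion point where the segment edges differ from the
      # flanking bases, so the alignment gap cannot slide off the truth
      mid <- ni %/% 2L
      for (d in c(0L, as.vector(rbind(1:10, -(1:10))))) {
        mm <- mid + d
        if (mm >= 3L && mm <= ni - 3L &&
            iv[mm + 1L] != first && iv[mm] != last) {
          mid <- mm
          break
        }
      }
      intr_b[i] <- paste0(substr(intr_b[i], 1, mid), seg,
                          substr(intr_b[i], mid + 1L, ni))
    })
    truth$insertion <- list(intron = i, length = insertion$length,
                            tr_length = insertion$tr_length)
  }
  assemble <- function(ex, intr, id) {
    pieces <- character(); spans <- matrix(0L, length(ex), 2); g <- 0L
    for (k in seq_along(ex)) {
      pieces <- c(pieces, ex[k])
      spans[k, ] <- c(g, g + nchar(ex[k]))
      g <- g + nchar(ex[k])
      if (k <= length(intr)) {
        pieces <- c(pieces, intr[k])
        g <- g + nchar(intr[k])
      }
    }
    genomic <- paste(pieces, collapse = "")
    cds <- paste(ex, collapse = "")
    list(cds = cds, genomic = genomic,
         model = gene_model(id, genomic, spans, cds))
  }
  structure(list(a = assemble(ex_a, intr_a, paste0(model$gene_id, "A")),
                 b = assemble(ex_b, intr_b, paste0(model$gene_id, "B")),
                 truth = truth),
            class = "gf_variant_pair")
}

#' Simulate a Ct table from true expression levels
#'
#' Ct(gene, sample, rep) = refCt - log2(level) + N(0, noise_sd); the two
#' reference genes get refCt plus the same noise.  `NA` levels become
#' undetected reactions in every replicate.
#'
#' @param levels genes x samples matrix of true relative levels (NA =
#'   undetectable).
#' @param ref_ct reference-gene Ct (default 20).
#' @param noise_sd technical noise SD in cycles.
#' @param replicates technical replicates.
#' @param refs names of the two reference genes.
#' @param seed RNG seed.
#' @return a Ct `data.frame` (`gene`, `sample`, `replicate`, `ct`).
#' @export
simulate_ct <- function(levels, ref_ct = 20, noise_sd = 0.15,
                        replicates = 3, refs = c("histone3", "UBQ14"),
                        seed = 1) {
  if (any(levels[!is.na(levels)] < 0)) stopf("levels must be >= 0")
  with_seed(seed, {
    rows <- list()
    for (s in colnames(levels)) for (r in seq_len(replicates)) {
      for (ref in refs)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = ref, sample = s, replicate = r,
          ct = ref_ct + stats::rnorm(1, 0, noise_sd))
      for (g in rownames(levels)) {
        lv <- levels[g, s]
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, sample = s, replicate = r,
          ct = if (is.na(lv)) NA_real_ else
            ref_ct - log2(lv) + stats::rnorm(1, 0, noise_sd))
      }
    }
    do.call(rbind, rows)
  })
}
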