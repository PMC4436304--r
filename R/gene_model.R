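# Gene models: mapping a CDS onto its genomic sequence.
#
# Exon boundaries are found by chaining exact matches between the CDS and
# the genomic sequence under the canonical GT..AG splice constraint and a
# minimum intron length.  The search is leftmost-longest deterministic:
# exons are extended maximally, then shortened (small backtrack) only when
# no legal intron can open at the maximal point.

#' Construct / validate a gene model
#'
#' @param gene_id gene identifier.
#' @param genomic genomic sequence string (forward strand).
#' @param exons integer matrix with columns `start`, `end` (0-based,
#'   half-open genomic spans), ordered and non-overlapping.
#' @param cds the coding sequence the exons must concatenate to.
#' @param min_intron minimum legal intron length.
#' @param check_splice enforce GT..AG intron ends.
#' @return a list of class `"gf_gene_model"`.
#' @export
gene_model <- function(gene_id, genomic, exons, cds, min_intron = 40,
                       check_splice = TRUE) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (any(diff(as.vector(t(exons))) < 0))
    stopf("exons must be ordered and non-overlapping")
  cat_exons <- paste(substring(genomic, exons[, 1] + 1L, exons[, 2]),
                     collapse = "")
  if (cat_exons != cds)
    stopf("concatenated exons do not reproduce the CDS for '%s'", gene_id)
  if (nrow(exons) > 1) {
    for (i in seq_len(nrow(exons) - 1)) {
      is_ <- exons[i, 2]; ie <- exons[i + 1, 1]
      if (ie - is_ < min_intron)
        stopf("intron %d of '%s' is shorter than min_intron", i, gene_id)
      if (check_splice) {
        don <- substr(genomic, is_ + 1L, is_ + 2L)
        acc <- substr(genomic, ie - 1L, ie)
        if (don != "GT" || acc != "AG")
          stopf("intron %d of '%s' violates GT..AG", i, gene_id)
      }
    }
  }
  structure(list(gene_id = gene_id, genomic = genomic, exons = exons,
                 cds = cds), class = "gf_gene_model")
}

#' @export
print.gf_gene_model <- function(x, ...) {
  cat(sprintf("Gene model '%s': %d exon(s), CDS %d nt, genomic %d nt\n",
              x$gene_id, nrow(x$exons), nchar(x$cds), nchar(x$genomic)))
  invisible(x)
}

#' Map a CDS onto a genomic sequence
#'
#' Finds the collinear exon chain that covers the entire CDS with exact
#' matches, introns obeying GT..AG and `min_intron`.  Deterministic:
#' leftmost-longest exons, shortest legal intron first, first full-coverage
#' chain wins.
#'
#' @param cds coding sequence (>= 30 nt).
#' @param genomic genomic sequence containing the gene on the forward
#'   strand, starting at the first CDS base and ending at the last.
#' @param min_intron minimum intron length (default 40).
#' @param relax_splice accept non-GT..AG introns.
#' @param gene_id identifier for the resulting model.
#' @return a `gf_gene_model`.
#' @export
map_cds_to_genome <- function(cds, genomic, min_intron = 40,
                              relax_splice = FALSE, gene_id = "gene") {
  if (nchar(cds) < 30) stopf("CDS must be at least 30 nt")
  cv <- s2c(cds); gv <- s2c(genomic)
  nc <- length(cv); ng <- length(gv)
  best_partial <- 0L
  backtrack <- 3L
  chain <- function(ci, gi) {
    # ci, gi: 1-based next positions to match in cds / genomic
    len <- min(nc - ci + 1L, ng - gi + 1L)
    run <- 0L
    if (len > 0) {
      cmp <- cv[ci:(ci + len - 1L)] != gv[gi:(gi + len - 1L)]
      run <- if (any(cmp)) which(cmp)[1] - 1L else len
    }
    if (ci + run - 1L == nc && gi + run - 1L == ng)
      return(list(c(gi - 1L, gi + run - 1L)))   # final exon, 0-based span
    best_partial <<- max(best_partial, ci + run - 1L)
    for (b in seq(gi + run, by = -1L,
                  length.out = min(backtrack + 1L, run))) {
      # exon = genomic [gi, b); intron opens at b
      if (!relax_splice &&
          !(b + 1L <= ng && gv[b] == "G" && gv[b + 1L] == "T")) next
      cb <- ci + (b - gi)                       # next CDS base to place
      if (cb > nc) next                         # no trailing intron
      js <- seq.int(b + min_intron, ng)
      for (j in js) {
        if (!relax_splice && !(gv[j - 2L] == "A" && gv[j - 1L] == "G")) next
        # short anchor only: the recursion verifies the rest (next exon may
        # be nearly as short as the anchor itself)
        anchor <- min(4L, nc - cb + 1L)
        if (j + anchor - 1L > ng) next
        if (!all(gv[j:(j + anchor - 1L)] == cv[cb:(cb + anchor - 1L)])) next
        rest <- chain(cb, j)
        if (!is.null(rest)) return(c(list(c(gi - 1L, b - 1L)), rest))
      }
    }
    NULL
  }
  spans <- chain(1L, 1L)
  if (is.null(spans))
    stopf("no full-coverage exon chain for '%s' (best partial: %d of %d CDS bases)",
          gene_id, best_partial, nc)
  exons <- do.call(rbind, spans)
  gene_model(gene_id, genomic, exons, cds, min_intron = min_intron,
             check_splice = !relax_splice)
}

# intron sequences of a model
model_introns <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2) return(character())
  vapply(seq_len(nrow(ex) - 1), function(i)
    substr(model$genomic, ex[i, 2] + 1L, ex[i + 1, 1]), "")
}

# exon index (1-based) containing a 0-based CDS coordinate
cds_coord_exon <- function(model, coord) {
  lens <- model$exons[, 2] - model$exons[, 1]
  ends <- cumsum(lens)
  findInterval(coord, c(0, ends), rightmost.closed = FALSE,
               left.open = TRUE) |> pmax(1) |> pmin(length(lens))
}

#' Compare exon-intron structures of orthologous gene models
#'
#' Reports per-gene exon counts and lengths, and introns present in some
#' orthologs but absent in others (detected as exon fusion: one exon of a
#' gene matching the sum of consecutive exons of the template, the model
#' with the most exons).
#'
#' @param models list of >= 2 `gf_gene_model`s over orthologous genes.
#' @param tol tolerance (nt) when matching exon lengths across orthologs.
#' @return list: `table` (per-gene exon counts/lengths), `intron_loss`
#'   (data.frame gene, intron -- 1-based consensus intron index).
#' @export
compare_structures <- function(models, tol = 30) {
  if (length(models) < 2)
    stopf("structure comparison needs at least two gene models")
  lens <- lapply(models, function(m) m$exons[, 2] - m$exons[, 1])
  ids <- vapply(models, function(m) m$gene_id, "")
  tmpl <- which.max(lengths(lens))
  tl <- lens[[tmpl]]
  losses <- list()
  for (k in seq_along(models)) {
    if (k == tmpl || length(lens[[k]]) == length(tl)) next
    fl <- lens[[k]]
    i <- 1L
    for (j in seq_along(fl)) {
      acc <- tl[i]; used <- i
      while (abs(acc - fl[j]) > tol && used < length(tl) &&
             acc < fl[j] + tol) {
        used <- used + 1L
        acc <- acc + tl[used]
      }
      if (used > i)   # exons i..used of template fused: introns i..used-1 lost
        losses[[length(losses) + 1L]] <-
          data.frame(gene = ids[k], intron = seq.int(i, used - 1L))
      i <- used + 1L
    }
  }
  tab <- data.frame(gene = ids, n_exons = lengths(lens),
                    exon_lengths = vapply(lens, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  loss <- if (length(losses)) do.call(rbind, losses) else
    data.frame(gene = character(), intron = integer())
  list(table = tab, intron_loss = loss)
}
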