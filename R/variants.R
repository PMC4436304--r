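# Homoeolog sequence variants: genome origin, indels, SSR tracts, and
# LTR-retrotransposon insertions.

#' Assign the genome of origin of a tetraploid gene copy
#'
#' The copy is assigned to the progenitor genome (A or D) whose diploid
#' ortholog it is closer to (p-distance after global alignment); a margin
#' below `ambiguous_margin` flags the call ambiguous.
#'
#' @param query,ortholog_A,ortholog_D sequence strings of one molecule type.
#' @param moltype `"protein"` or `"dna"`.
#' @param ambiguous_margin minimum |dA - dD| for a confident call.
#' @return list: `origin` ("A"/"D"), `dA`, `dD`, `margin`, `ambiguous`.
#' @export
assign_genome_origin <- function(query, ortholog_A, ortholog_D,
                                 moltype = "protein",
                                 ambiguous_margin = 0.005) {
  dA <- pairwise_pdist(query, ortholog_A, moltype)
  dD <- pairwise_pdist(query, ortholog_D, moltype)
  margin <- abs(dA - dD)
  list(origin = if (dA <= dD) "A" else "D", dA = dA, dD = dD,
       margin = margin, ambiguous = margin < ambiguous_margin)
}

#' Detect indels between two orthologous coding sequences
#'
#' Global nucleotide alignment (match 2, mismatch -3, gap open 10,
#' extend 0.5); every maximal gap run is reported with its coordinate on
#' the first (reference) CDS, its length, reading-frame flag
#' (`in_frame` iff length %% 3 == 0), which sequence carries the deletion,
#' and the containing exon of the reference model when given.
#'
#' @param cds_a,cds_b coding sequences; coordinates are reported on `cds_a`.
#' @param model_a optional `gf_gene_model` of the reference gene (for exon
#'   indices).
#' @return data.frame: `coord` (0-based on cds_a), `length`, `in_frame`,
#'   `deleted_in` ("a"/"b"), `exon` (1-based or NA).
#' @export
detect_indels <- function(cds_a, cds_b, model_a = NULL) {
  al <- align_dna_global(cds_a, cds_b)
  x <- s2c(al$a_aln); y <- s2c(al$b_aln)
  out <- list()
  for (row in c("a", "b")) {
    g <- if (row == "a") x == "-" else y == "-"
    r <- rle(g)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (k in which(r$values)) {
      coord <- sum(x[seq_len(starts[k] - 1L)] != "-")  # bases of A before run
      len <- r$lengths[k]
      out[[length(out) + 1L]] <- data.frame(
        coord = coord, length = len, in_frame = len %% 3L == 0L,
        deleted_in = row, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(coord = integer(), length = integer(), in_frame = logical(),
               deleted_in = character(), stringsAsFactors = FALSE)
  res <- res[order(res$coord), , drop = FALSE]
  res$exon <- if (!is.null(model_a) && nrow(res))
    cds_coord_exon(model_a, res$coord) else rep(NA_integer_, nrow(res))
  rownames(res) <- NULL
  res
}

#' Find perfect SSR tandem runs
#'
#' Maximal perfect tandem repeats of `unit` with at least `min_copies`
#' copies, reported left to right.
#'
#' @param seq nucleotide sequence string.
#' @param unit repeat unit (e.g. `"GAA"`).
#' @param min_copies minimum copy number to report.
#' @return data.frame: `start` (0-based), `copies`.
#' @export
find_ssr <- function(seq, unit, min_copies = 4) {
  if (!nzchar(unit)) stopf("SSR unit must be non-empty")
  pat <- sprintf("(?:%s){%d,}", unit, min_copies)
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(), copies = integer()))
  data.frame(start = as.integer(m) - 1L,
             copies = as.integer(attr(m, "match.length") %/% nchar(unit)))
}

#' SSR tract-length difference between two orthologs
#'
#' Compares the longest run of `unit` in each sequence and returns the
#' copy numbers and the length difference in nucleotides
#' (`(copies_a - copies_b) * nchar(unit)`).
#'
#' @inheritParams find_ssr
#' @param seq_a,seq_b orthologous sequences.
#' @return list: `copies_a`, `copies_b`, `diff_nt`.
#' @export
ssr_difference <- function(seq_a, seq_b, unit, min_copies = 4) {
  ra <- find_ssr(seq_a, unit, min_copies)
  rb <- find_ssr(seq_b, unit, min_copies)
  ca <- if (nrow(ra)) max(ra$copies) else 0L
  cb <- if (nrow(rb)) max(rb$copies) else 0L
  list(copies_a = ca, copies_b = cb,
       diff_nt = (ca - cb) * nchar(unit))
}

#' Detect a large insertion (possible LTR retrotransposon) in an intron
#'
#' Globally aligns two orthologous introns; a single gap run of at least
#' `min_insert` nt is reported as an insertion in the longer sequence.
#' Within the inserted segment the best (prefix, suffix) window pair with
#' identity >= `min_tr_identity` and length >= `min_tr_len` is attached as
#' direct terminal-repeat evidence (the LTR hallmark).  The window length
#' maximises matches - 3 x mismatches, so perfect repeats are recovered at
#' their exact length.
#'
#' @param intron_a,intron_b orthologous intron sequences.
#' @param min_insert minimum gap-run length to call an insertion (nt).
#' @param min_tr_len,min_tr_identity terminal-repeat thresholds.
#' @return `NULL` when no insertion; else list: `in_seq` ("a"/"b"),
#'   `start` (0-based on the carrier intron), `length`, `terminal_repeat`
#'   (`NULL` or list(length, identity)).
#' @export
detect_ltr_insertion <- function(intron_a, intron_b, min_insert = 500,
                                 min_tr_len = 100, min_tr_identity = 0.85) {
  if (intron_a == intron_b) return(NULL)
  al <- align_dna_global(intron_a, intron_b)
  x <- s2c(al$a_aln); y <- s2c(al$b_aln)
  best <- NULL
  for (row in c("a", "b")) {
    g <- if (row == "a") x == "-" else y == "-"
    r <- rle(g)
    k <- which(r$values & r$lengths >= min_insert)
    if (!length(k)) next
    k <- k[which.max(r$lengths[k])]
    if (!is.null(best) && r$lengths[k] <= best$length) next
    stop_ <- cumsum(r$lengths)[k]
    start_ <- stop_ - r$lengths[k] + 1L
    carrier <- if (row == "a") y else x
    seg <- carrier[start_:stop_]
    offset <- sum(carrier[seq_len(start_ - 1L)] != "-")
    best <- list(in_seq = if (row == "a") "b" else "a",
                 start = offset, length = r$lengths[k], segment = seg)
  }
  if (is.null(best)) return(NULL)
  seg <- best$segment
  n <- length(seg)
  tr <- NULL
  best_score <- 0
  for (L in seq.int(min_tr_len, n %/% 2)) {
    matches <- sum(seg[seq_len(L)] == seg[seq.int(n - L + 1L, n)])
    ident <- matches / L
    score <- matches - 3 * (L - matches)
    if (ident >= min_tr_identity && score > best_score) {
      best_score <- score
      tr <- list(length = L, identity = ident)
    }
  }
  best$segment <- NULL
  best$terminal_repeat <- tr
  best
}

#' Full variant report for an orthologous gene pair
#'
#' Runs indel, SSR, and intron-insertion detection between two gene models
#' and returns one consolidated report.
#'
#' @param model_a,model_b `gf_gene_model`s of the orthologous pair
#'   (coordinates reported on `model_a`).
#' @param ssr_unit SSR unit to scan (default `"GAA"`).
#' @param ... passed to [detect_ltr_insertion()].
#' @return list of class `"gf_variant_report"`: `pair`, `indels`, `ssr`,
#'   `insertions` (per-intron list).
#' @export
variant_report <- function(model_a, model_b, ssr_unit = "GAA", ...) {
  indels <- detect_indels(model_a$cds, model_b$cds, model_a)
  ia <- model_introns(model_a); ib <- model_introns(model_b)
  ins <- list()
  for (i in seq_len(min(length(ia), length(ib)))) {
    hit <- detect_ltr_insertion(ia[i], ib[i], ...)
    if (!is.null(hit)) {
      hit$intron <- i
      ins[[length(ins) + 1L]] <- hit
    }
  }
  ssr <- ssr_difference(model_a$cds, model_b$cds, ssr_unit)
  structure(list(pair = c(model_a$gene_id, model_b$gene_id),
                 indels = indels, ssr = ssr, insertions = ins),
            class = "gf_variant_report")
}

#' @export
print.gf_variant_report <- function(x, ...) {
  cat(sprintf("Variants %s vs %s: %d indel(s), SSR %d vs %d copies, %d intron insertion(s)\n",
              x$pair[1], x$pair[2], nrow(x$indels),
              x$ssr$copies_a, x$ssr$copies_b, length(x$insertions)))
  invisible(x)
}
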