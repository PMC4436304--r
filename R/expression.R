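# qRT-PCR relative quantification with two internal-standard genes.
#
# Per replicate, the reference Ct is the arithmetic mean of the reference
# genes' Ct values (equivalent to the geometric mean of their expression
# quantities); the gene's relative level is 2^-(Ct - refCt).  Reported
# levels are means over technical replicates with SEM; a gene is
# "undetectable" in a sample only when every replicate is undetected.

#' Read a Ct table
#'
#' Input TSV columns: `gene`, `sample`, `replicate`, `ct`.  Undetected
#' reactions may be encoded as empty, `NA`, `ND`, or a Ct above
#' `undetected_above`.
#'
#' @param path TSV path.
#' @param undetected_above Ct cutoff above which a reaction counts as
#'   undetected (default 40).
#' @return a `data.frame` with `ct` numeric (NA = undetected).
#' @export
read_ct_table <- function(path, undetected_above = 40) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stopf("Ct table must have columns %s", paste(need, collapse = ", "))
  ct$ct <- suppressWarnings(as.numeric(ifelse(ct$ct %in% c("", "ND", "NA"),
                                              NA, ct$ct)))
  ct$ct[!is.na(ct$ct) & ct$ct > undetected_above] <- NA
  if (any(!is.na(ct$ct) & ct$ct <= 0))
    stopf("Ct values must be positive")
  ct
}

#' Relative expression from a Ct table
#'
#' @param ct a Ct `data.frame` (`gene`, `sample`, `replicate`, `ct`; NA =
#'   undetected).
#' @param refs ids of the reference genes (default `c("histone3",
#'   "UBQ14")`).
#' @return a `data.frame` of class `"gf_expression"`: `gene`, `sample`,
#'   `level` (mean over detected replicates; NA when undetectable),
#'   `sem` (NA with < 2 detected replicates), `n_detected`,
#'   `undetectable`.
#' @export
relative_expression <- function(ct, refs = c("histone3", "UBQ14")) {
  if (!any(ct$gene %in% refs)) stopf("no reference gene rows in the table")
  samples <- unique(ct$sample)
  ref_ct <- list()
  for (s in samples) {
    sub <- ct[ct$sample == s & ct$gene %in% refs & !is.na(ct$ct), ]
    if (!nrow(sub))
      stopf("sample '%s' lacks reference-gene measurements", s)
    ref_ct[[s]] <- tapply(sub$ct, sub$replicate, mean)
  }
  genes <- setdiff(unique(ct$gene), refs)
  rows <- list()
  for (g in genes) for (s in samples) {
    sub <- ct[ct$gene == g & ct$sample == s, ]
    if (!nrow(sub)) next
    lv <- vapply(seq_len(nrow(sub)), function(i) {
      r <- as.character(sub$replicate[i])
      if (is.na(sub$ct[i]) || !r %in% names(ref_ct[[s]])) return(NA_real_)
      2^-(sub$ct[i] - ref_ct[[s]][[r]])
    }, 0)
    det <- !is.na(lv)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, sample = s,
      level = if (any(det)) mean(lv[det]) else NA_real_,
      sem = if (sum(det) >= 2) stats::sd(lv[det]) / sqrt(sum(det)) else
        NA_real_,
      n_detected = sum(det), undetectable = !any(det),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("gf_expression", class(out))
  out
}

#' Expression profile matrix
#'
#' Genes x samples matrices of levels and SEMs; optionally a per-gene
#' max-normalised view (each gene's highest sample set to 1).  Undetectable
#' cells are `NA` numerically and rendered `"ND"`, never 0.
#'
#' @param profiles output of [relative_expression()].
#' @param genes,samples row/column order (defaults: order of appearance).
#' @param normalize add a per-gene max-normalised matrix.
#' @return list: `levels`, `sem` (numeric matrices), `rendered` (character,
#'   ND for undetectable), and `normalized` when requested.
#' @export
profile_matrix <- function(profiles, genes = unique(profiles$gene),
                           samples = unique(profiles$sample),
                           normalize = TRUE) {
  lv <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  se <- lv
  for (i in seq_len(nrow(profiles))) {
    lv[profiles$gene[i], profiles$sample[i]] <- profiles$level[i]
    se[profiles$gene[i], profiles$sample[i]] <- profiles$sem[i]
  }
  rendered <- matrix(ifelse(is.na(lv), "ND", formatC(lv, digits = 4,
                                                     format = "g")),
                     length(genes), length(samples),
                     dimnames = dimnames(lv))
  out <- list(levels = lv, sem = se, rendered = rendered)
  if (normalize) {
    mx <- apply(lv, 1, function(v) if (all(is.na(v))) NA_real_ else
      max(v, na.rm = TRUE))
    out$normalized <- sweep(lv, 1, mx, "/")
  }
  out
}
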