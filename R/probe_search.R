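# Proteome screening with a probe set of representative domains.
#
# Each probe is one representative bHLH domain per known subfamily (plus
# orphans).  Every probe is aligned locally against every protein of a
# source proteome; per protein only the best-scoring probe is kept
# ("repeated entries eliminated"), and the putative domain is cut out of
# the subject along the hit footprint.

#' Construct a probe set
#'
#' @param records protein sequence records (one per probe).
#' @param subfamily character vector of subfamily labels, one per probe.
#' @return a list of class `"gf_probeset"`.
#' @export
probe_set <- function(records, subfamily) {
  if (nrow(records) < 1) stopf("probe set must contain at least one probe")
  if (length(subfamily) != nrow(records))
    stopf("one subfamily label per probe is required")
  structure(list(records = records,
                 subfamily = stats::setNames(subfamily, records$id)),
            class = "gf_probeset")
}

#' Screen a proteome for candidate domains
#'
#' Aligns every probe locally (Smith-Waterman, BLOSUM62, gap 11/1) against
#' every protein.  At most one candidate is returned per protein: the
#' best-scoring probe wins; hits below `min_score` are dropped.  The
#' candidate's residues are the subject subsequence under the hit span,
#' extended outward to the probe's full length when the local alignment is
#' truncated at either end, so downstream validation sees full-width
#' candidates.
#'
#' @param probes a `gf_probeset`.
#' @param proteome protein sequence records with unique ids.
#' @param min_score minimum local-alignment score to report a candidate.
#' @return a `data.frame` of candidates, sorted by subject id: columns
#'   `id` (subject), `source`, `residues` (the cut-out domain), `probe`
#'   (best probe id), `score`, `start`, `end` (0-based half-open span on
#'   the subject).
#' @export
search_proteome <- function(probes, proteome, min_score = 60) {
  if (!inherits(probes, "gf_probeset")) stopf("probes must be a gf_probeset")
  if (anyDuplicated(proteome$id)) stopf("proteome ids must be unique")
  mat <- blosum62()
  pseqs <- probes$records$residues
  pids <- probes$records$id
  out <- vector("list", nrow(proteome))
  subj_set <- Biostrings::AAStringSet(proteome$residues)
  probe_set_ <- Biostrings::AAStringSet(pseqs)
  for (i in seq_len(nrow(proteome))) {
    pa <- Biostrings::pairwiseAlignment(
      probe_set_, subj_set[[i]], substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1, type = "local")
    scores <- Biostrings::score(pa)
    best <- which.max(scores)
    if (scores[best] < min_score) next
    qs <- Biostrings::start(Biostrings::pattern(pa))[best] - 1L
    qe <- Biostrings::end(Biostrings::pattern(pa))[best]
    ss <- Biostrings::start(Biostrings::subject(pa))[best] - 1L
    se <- Biostrings::end(Biostrings::subject(pa))[best]
    plen <- nchar(pseqs[best])
    slen <- nchar(proteome$residues[i])
    # pad truncated hits out to the probe's domain frame
    ext_start <- max(0L, ss - qs)
    ext_end <- min(slen, se + (plen - qe))
    out[[i]] <- data.frame(
      id = proteome$id[i], source = proteome$source[i],
      residues = substr(proteome$residues[i], ext_start + 1L, ext_end),
      probe = pids[best], score = scores[best],
      start = ext_start, end = ext_end, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(id = character(), source = character(),
                      residues = character(), probe = character(),
                      score = numeric(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  res[order(res$id), , drop = FALSE]
}
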