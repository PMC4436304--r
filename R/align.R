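# Pairwise alignment primitives.
#
# The probe search replaces a BLAST screen with exact Smith-Waterman under
# BLOSUM62 with affine gaps (open 11 / extend 1, the BLAST protein
# defaults): only the hit footprint is used downstream, never E-values, so
# the exact local optimum is both simpler and stronger.  The dynamic
# programming itself is Biostrings' C implementation.

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman with an affine gap penalty.  The score floor is 0:
#' when every pairing scores negative the alignment is empty.
#'
#' @param query,subject protein sequence strings.
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties as positive costs; a gap
#'   of length L costs `gap_open + L * gap_extend`.
#' @return a list with `score`, `query_span` and `subject_span` (0-based,
#'   half-open), and the gapped rows `query_aln`, `subject_aln`.
#' @export
smith_waterman <- function(query, subject, matrix = blosum62(),
                           gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(subject))
    stopf("smith_waterman requires non-empty sequences")
  check_in_matrix(c(query, subject), matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  sc <- Biostrings::score(pa)
  if (sc <= 0 && nchar(as.character(Biostrings::alignedPattern(pa))) == 0) {
    return(list(score = 0, query_span = c(0L, 0L), subject_span = c(0L, 0L),
                query_aln = "", subject_aln = ""))
  }
  qs <- Biostrings::start(Biostrings::pattern(pa))
  qe <- Biostrings::end(Biostrings::pattern(pa))
  ss <- Biostrings::start(Biostrings::subject(pa))
  se <- Biostrings::end(Biostrings::subject(pa))
  list(score = sc,
       query_span = c(qs - 1L, qe), subject_span = c(ss - 1L, se),
       query_aln = as.character(Biostrings::alignedPattern(pa)),
       subject_aln = as.character(Biostrings::alignedSubject(pa)))
}

check_in_matrix <- function(seqs, matrix) {
  letters_ok <- rownames(matrix)
  ch <- unique(unlist(strsplit(seqs, "", fixed = TRUE)))
  bad <- setdiff(ch, letters_ok)
  if (length(bad))
    stopf("residue(s) not covered by the substitution matrix: %s",
          paste(bad, collapse = ", "))
}

# Global alignment with free end gaps ("overlap"); used to map candidate
# domains onto profile columns and to align orthologous coding sequences.
align_overlap <- function(a, b, matrix = blosum62(),
                          gap_open = 11, gap_extend = 1, type = "overlap") {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = type)
  list(score = Biostrings::score(pa),
       a_aln = as.character(Biostrings::alignedPattern(pa)),
       b_aln = as.character(Biostrings::alignedSubject(pa)))
}

# Global nucleotide alignment (match 2 / mismatch -3, gap open 10 /
# extend 0.5) -- the scoring used for indel and insertion detection.
align_dna_global <- function(a, b, match = 2, mismatch = -3,
                             gap_open = 10, gap_extend = 0.5) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                mismatch = mismatch,
                                                baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = m, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  list(score = Biostrings::score(pa),
       a_aln = as.character(Biostrings::alignedPattern(pa)),
       b_aln = as.character(Biostrings::alignedSubject(pa)))
}

# p-distance between two unaligned sequences, via overlap alignment:
# mismatches / compared (both-residue) columns.
pairwise_pdist <- function(a, b, moltype = "protein") {
  if (a == b) return(0)
  al <- if (moltype == "protein")
    align_overlap(a, b, type = "global") else
    align_dna_global(a, b)
  x <- s2c(al[[2]]); y <- s2c(al[[3]])
  ok <- x != "-" & y != "-"
  if (!any(ok)) stopf("no comparable columns between sequences")
  sum(x[ok] != y[ok]) / sum(ok)
}
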