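# Newick IO and the alignment container.
#
# Trees are `ape::phylo` objects throughout; integer bootstrap supports
# travel as internal-node labels, the Newick convention shared by MEGA,
# RAxML and ape.

#' Read a Newick tree
#'
#' Internal node labels, when numeric, are interpreted as bootstrap-style
#' support values in \[0, 100\].  Negative branch lengths and unbalanced
#' parentheses are errors.
#'
#' @param path path to a Newick file (or a literal Newick string).
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "") else path
  no <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  nc <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (no != nc) stopf("unbalanced parentheses in Newick input")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stopf("could not parse Newick input")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stopf("negative branch length in Newick input")
  if (anyDuplicated(tr$tip.label))
    stopf("duplicate leaf labels in Newick input")
  tr
}

#' Write a tree to Newick
#'
#' Branch lengths are written with enough digits for a lossless round trip
#' (1e-9); support values ride as internal node labels.
#'
#' @param tree an `ape::phylo`.
#' @param path output path; if `NULL`, the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Construct a multiple alignment
#'
#' A thin container: ids plus equal-length gapped rows.  Gap characters are
#' `-` on output; `.` is accepted on input and normalised to `-`.
#'
#' @param ids row identifiers (unique).
#' @param seqs gapped sequences, all of equal length.
#' @return an object of class `"gf_alignment"` with elements `ids`, `seqs`
#'   (named by id) and `length` (number of columns).
#' @export
new_alignment <- function(ids, seqs) {
  seqs <- toupper(gsub(".", "-", as.character(seqs), fixed = TRUE))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stopf("duplicate alignment row ids")
  if (length(unique(nchar(seqs))) > 1L)
    stopf("alignment rows must have equal length")
  names(seqs) <- ids
  structure(list(ids = ids, seqs = seqs,
                 length = unname(nchar(seqs[1]))),
            class = "gf_alignment")
}

#' @export
print.gf_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d rows x %d columns\n", length(x$ids), x$length))
  invisible(x)
}

# alignment as character matrix (rows x columns)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Read / write gapped FASTA alignments
#' @param path FASTA file of equal-length gapped rows.
#' @return a `gf_alignment`.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  new_alignment(ids, as.character(set))
}

#' @rdname read_alignment
#' @param aln a `gf_alignment`.
#' @param width line-wrap width.
#' @export
write_alignment <- function(aln, path, width = 60) {
  rec <- data.frame(id = aln$ids, residues = unname(aln$seqs),
                    description = "", stringsAsFactors = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(rec))) {
    writeLines(paste0(">", rec$id[i]), con)
    s <- rec$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
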