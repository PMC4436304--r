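# Sequence records and FASTA IO.
#
# A collection of sequence records is a plain data.frame with columns
# id, residues, moltype, source, description -- the shared currency of the
# whole pipeline.  Sources name the annotation origins a gene copy can come
# from (two diploid genome projects, a second assembly of one of them,
# tetraploid unigenes, contigs, and cloned mRNAs).

SOURCE_LEVELS <- c("GrJGI", "GrCGP", "GaCGP", "GhUni", "GoCon", "mRNA", "user")

#' Construct a sequence-record table
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param residues character vector of sequences (no gaps).
#' @param moltype `"protein"` or `"dna"`.
#' @param source provenance tag, one of
#'   `c("GrJGI","GrCGP","GaCGP","GhUni","GoCon","mRNA","user")`.
#' @param description free-text description (never part of identity).
#' @return a `data.frame` with one row per record.
#' @export
seq_records <- function(id, residues, moltype = "protein",
                        source = "user", description = "") {
  rec <- data.frame(id = as.character(id),
                    residues = toupper(as.character(residues)),
                    moltype = moltype, source = source,
                    description = description,
                    stringsAsFactors = FALSE)
  validate_records(rec)
  rec
}

validate_records <- function(rec) {
  if (any(rec$id == "")) stopf("sequence records must have non-empty ids")
  dup <- rec$id[duplicated(rec$id)]
  if (length(dup)) stopf("duplicate sequence id(s): %s",
                         paste(unique(dup), collapse = ", "))
  if (any(nchar(rec$residues) == 0L))
    stopf("empty sequence for id(s): %s",
          paste(rec$id[nchar(rec$residues) == 0L], collapse = ", "))
  if (!all(rec$moltype %in% c("protein", "dna")))
    stopf("moltype must be 'protein' or 'dna'")
  if (!all(rec$source %in% SOURCE_LEVELS))
    stopf("unknown source tag(s): %s",
          paste(setdiff(rec$source, SOURCE_LEVELS), collapse = ", "))
  for (i in seq_len(nrow(rec))) {
    alpha <- if (rec$moltype[i] == "protein") c(AA_LETTERS, "X") else
      c("A", "C", "G", "T", "N")
    ch <- s2c(rec$residues[i])
    bad <- which(!ch %in% alpha)
    if (length(bad))
      stopf("illegal residue '%s' at position %d of record '%s'",
            ch[bad[1]], bad[1], rec$id[i])
  }
  invisible(rec)
}

#' Read a FASTA file into a sequence-record table
#'
#' The header token before the first whitespace becomes the id, the rest the
#' description.  Record order follows file order.  Duplicate ids, empty
#' sequences and residues outside the IUPAC alphabet (protein: amino acids
#' plus X; dna: ACGTN) are errors.
#'
#' @param path path to a FASTA file.
#' @param moltype `"protein"` or `"dna"`.
#' @param source provenance tag attached to every record.
#' @return a sequence-record `data.frame` (see [seq_records()]).
#' @export
read_fasta <- function(path, moltype = c("protein", "dna"), source = "user") {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stopf("no such file: %s", path)
  set <- if (moltype == "protein")
    Biostrings::readAAStringSet(path) else
    Biostrings::readDNAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seq_records(id = ids, residues = as.character(set),
              moltype = moltype, source = source, description = desc)
}

#' Write sequence records to FASTA
#'
#' @param records a sequence-record `data.frame`.
#' @param path output path.
#' @param width line-wrap width for sequence lines (default 60).
#' @export
write_fasta <- function(records, path, width = 60) {
  if (width < 1) stopf("width must be a positive integer")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$description[i]))
      paste(records$id[i], records$description[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
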