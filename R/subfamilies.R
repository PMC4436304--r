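# Subfamily calling by the multi-method support rule.
#
# A clade becomes a subfamily when its bipartition has NJ bootstrap
# support strictly above 88% AND appears in at least one further method's
# tree (MP or ML) -- "supported by at least two methods", NJ counting as
# one.  Clades are named through anchor sequences whose subfamily is
# known; splits (e.g. S5a vs S5b) and merges (one name on several anchors)
# are realised purely through the anchor -> name map.

#' Call subfamilies from NJ/MP/ML trees and anchors
#'
#' Candidate clades are the sides of NJ bipartitions with support >
#' `min_support` that are also present in the MP or the ML tree.  Each
#' subfamily is the maximal candidate clade containing all anchors of its
#' name and no anchor of any other name.  Leaves covered by no subfamily
#' clade are labelled `"orphan"`.  If two anchors of different names
#' cannot be separated by any candidate clade, both names are reported
#' unresolved (never silently merged).
#'
#' @param nj a `gf_supported_tree` (NJ with bootstrap supports).
#' @param mp an `ape::phylo` (MP tree).
#' @param ml an `ape::phylo` or `gf_ml_tree` (ML tree).
#' @param anchors named character vector: anchor leaf id -> subfamily name.
#' @param min_support NJ bootstrap threshold (strict, default 88).
#' @param require_both if `TRUE`, a candidate clade must be present in
#'   both MP and ML (the alternative reading of "two methods").
#' @return a list of class `"gf_subfamilies"`: `assignment` (named vector
#'   leaf -> label), `clades` (list name -> member ids), `unresolved`
#'   (character vector of names), `candidates` (bipartition table).
#' @export
call_subfamilies <- function(nj, mp, ml, anchors, min_support = 88,
                             require_both = FALSE) {
  if (inherits(ml, "gf_ml_tree")) ml <- ml$tree
  tree <- nj$tree
  tips <- tree$tip.label
  if (!setequal(tips, mp$tip.label) || !setequal(tips, ml$tip.label))
    stopf("NJ, MP and ML trees must share one leaf set")
  missing <- setdiff(names(anchors), tips)
  if (length(missing))
    stopf("anchor(s) missing from the trees: %s",
          paste(missing, collapse = ", "))
  mp_keys <- bipartition_keys(mp)$key
  ml_keys <- bipartition_keys(ml)$key
  sup <- nj$support
  in_mp <- names(sup) %in% mp_keys
  in_ml <- names(sup) %in% ml_keys
  extra <- if (require_both) in_mp & in_ml else in_mp | in_ml
  cand_keys <- names(sup)[sup > min_support & extra]
  candidates <- data.frame(key = names(sup), support = unname(sup),
                           in_mp = in_mp, in_ml = in_ml,
                           candidate = names(sup) %in% cand_keys,
                           stringsAsFactors = FALSE)
  # both sides of each candidate bipartition are potential clades
  sides <- list()
  for (k in cand_keys) {
    s1 <- strsplit(k, "|", fixed = TRUE)[[1]]
    sides <- c(sides, list(s1), list(setdiff(tips, s1)))
  }
  names_by <- split(names(anchors), unname(anchors))
  clades <- list()
  unresolved <- character()
  for (nm in names(names_by)) {
    own <- names_by[[nm]]
    other <- setdiff(names(anchors), own)
    ok <- Filter(function(s) all(own %in% s) && !any(other %in% s), sides)
    if (!length(ok)) {
      unresolved <- c(unresolved, nm)
      next
    }
    clades[[nm]] <- ok[[which.max(lengths(ok))]]
  }
  assignment <- stats::setNames(rep("orphan", length(tips)), tips)
  for (nm in names(clades)) assignment[clades[[nm]]] <- nm
  for (nm in unresolved)
    assignment[names_by[[nm]]] <- "unresolved"
  structure(list(assignment = assignment, clades = clades,
                 unresolved = unresolved, candidates = candidates),
            class = "gf_subfamilies")
}

#' @export
print.gf_subfamilies <- function(x, ...) {
  tab <- table(x$assignment)
  cat(sprintf("Subfamily assignment: %d leaves, %d subfamilies%s\n",
              length(x$assignment), length(x$clades),
              if (length(x$unresolved))
                paste0(" (unresolved: ",
                       paste(x$unresolved, collapse = ", "), ")") else ""))
  print(tab)
  invisible(x)
}
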