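# Internal helpers shared across modules.

AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V")

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded generators never perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Natural-sort order for ids like "g2" < "g10"; digits compared numerically.
natural_order <- function(x) {
  parts <- strsplit(x, "(?<=\\D)(?=\\d)|(?<=\\d)(?=\\D)", perl = TRUE)
  n <- max(lengths(parts))
  keys <- lapply(seq_len(n), function(i) {
    p <- vapply(parts, function(v) if (i <= length(v)) v[i] else "", "")
    num <- suppressWarnings(as.numeric(p))
    if (all(!is.na(num) | p == "")) {
      num[p == ""] <- -Inf
      num
    } else p
  })
  do.call(order, keys)
}

s2c <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
c2s <- function(ch) paste(ch, collapse = "")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
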