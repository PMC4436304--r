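# Pipeline configuration and the end-to-end run.
#
# One config object carries every numeric constant of the method (the BL
# bands 0.03 / 0.15, the 60% consensus rule, the >88% support rule, the
# 1000-replicate bootstrap) plus paths and seeds; a run writes its stage
# outputs and a manifest with the resolved config and its hash, so every
# table is reproducible from the manifest alone.

#' Build / validate a pipeline configuration
#'
#' @param inputs named list source tag -> protein FASTA path (or a
#'   record `data.frame` directly).
#' @param probes probe FASTA path or record `data.frame`; `subfamily`
#'   labels may ride in the description column.
#' @param anchors named character vector anchor id -> subfamily name.
#' @param allele_thr,ortholog_thr BL band boundaries.
#' @param consensus_thr consensus-residue fraction rule (strict >).
#' @param min_support NJ bootstrap threshold (strict >).
#' @param bootstrap_reps NJ bootstrap replicates.
#' @param min_score minimum probe-hit score.
#' @param min_intron minimum intron length for gene models.
#' @param seed seed for every stochastic stage (mandatory).
#' @param out_dir output directory.
#' @return validated config list of class `"gf_config"`.
#' @export
pipeline_config <- function(inputs, probes, anchors = NULL,
                            allele_thr = 0.03, ortholog_thr = 0.15,
                            consensus_thr = 0.60, min_support = 88,
                            bootstrap_reps = 1000, min_score = 60,
                            min_intron = 40, seed = NULL,
                            out_dir = tempfile("gofamcat_run_")) {
  if (is.null(seed))
    stopf("config requires an explicit seed; silent clock seeds are not allowed")
  if (!(allele_thr > 0 && allele_thr < ortholog_thr))
    stopf("invalid thresholds: need 0 < allele_thr < ortholog_thr")
  if (consensus_thr <= 0 || consensus_thr >= 1)
    stopf("consensus_thr must be in (0, 1)")
  if (min_support < 0 || min_support > 100)
    stopf("min_support must be in [0, 100]")
  if (bootstrap_reps < 1) stopf("bootstrap_reps must be >= 1")
  structure(list(inputs = inputs, probes = probes, anchors = anchors,
                 allele_thr = allele_thr, ortholog_thr = ortholog_thr,
                 consensus_thr = consensus_thr, min_support = min_support,
                 bootstrap_reps = bootstrap_reps, min_score = min_score,
                 min_intron = min_intron, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "gf_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the [pipeline_config()] fields.
#' @return a `gf_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

load_stage_records <- function(x, source = "user") {
  if (is.data.frame(x)) return(x)
  read_fasta(x, "protein", source = source)
}

#' Run the cataloguing pipeline
#'
#' Stages: probe search over every source proteome, domain validation,
#' reference-set construction (guide tree + BL grouping + coding),
#' and subfamily classification (NJ bootstrap + MP + ML + anchor naming).
#' Stage outputs and a manifest (resolved config, hash, seed) are written
#' under `config$out_dir`.
#'
#' @param config a `gf_config`.
#' @param profile consensus profile (default [default_profile()]).
#' @return list of class `"gf_run"`: `candidates`, `calls`, `refset`,
#'   `classification`, `manifest`.
#' @export
run_pipeline <- function(config, profile = default_profile()) {
  if (!inherits(config, "gf_config")) stopf("config must be a gf_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  probes_rec <- load_stage_records(config$probes)
  probes <- probe_set(probes_rec,
                      ifelse(nzchar(probes_rec$description),
                             probes_rec$description, probes_rec$id))
  # stage 1: search
  candidates <- list()
  for (src in names(config$inputs)) {
    proteome <- load_stage_records(config$inputs[[src]], source = src)
    proteome$source <- src
    candidates[[src]] <- search_proteome(probes, proteome,
                                         min_score = config$min_score)
  }
  candidates <- do.call(rbind, candidates)
  rownames(candidates) <- NULL
  if (!nrow(candidates)) stopf("stage search: no candidate domains found")
  # stage 2: validate
  calls <- lapply(candidates$residues, validate_domain, profile = profile)
  candidates$verdict <- vapply(calls, function(x) x$verdict, TRUE)
  candidates$consensus_fraction <-
    vapply(calls, function(x) x$consensus_fraction, 0)
  validated <- candidates[candidates$verdict, , drop = FALSE]
  if (!nrow(validated)) stopf("stage validate: no candidate passed")
  # stage 3: reference set (full-length validated proteins)
  refrec <- seq_records(validated$id,
                        vapply(seq_len(nrow(validated)), function(i) {
                          src <- validated$source[i]
                          prot <- load_stage_records(config$inputs[[src]],
                                                     source = src)
                          prot$residues[match(validated$id[i], prot$id)]
                        }, ""),
                        source = validated$source)
  refset <- build_reference(refrec, config$allele_thr, config$ortholog_thr)
  # stage 4: classify representatives (domain columns) with anchors
  classification <- NULL
  if (!is.null(config$anchors)) {
    reps <- vapply(refset$groups, function(g) g$representative, "")
    rep_rows <- validated[match(reps, validated$id), , drop = FALSE]
    dom_map <- lapply(rep_rows$residues, map_candidate, profile = profile)
    ids <- rep_rows$id
    anc <- probes_rec[match(names(config$anchors), probes_rec$id), ,
                      drop = FALSE]
    anc_map <- lapply(anc$residues, map_candidate, profile = profile)
    aln <- new_alignment(c(ids, anc$id),
                         c(vapply(dom_map, c2s, ""),
                           vapply(anc_map, c2s, "")))
    nj_sup <- bootstrap_support(aln, reps = config$bootstrap_reps,
                                seed = config$seed)
    mp <- mp_tree(aln, seed = config$seed)
    ml <- ml_tree_poisson(aln)
    classification <- call_subfamilies(nj_sup, mp, ml, config$anchors,
                                       min_support = config$min_support)
    write_newick(nj_sup$tree, file.path(config$out_dir, "nj_support.nwk"))
    utils::write.table(
      data.frame(id = names(classification$assignment),
                 subfamily = unname(classification$assignment)),
      file.path(config$out_dir, "subfamilies.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(candidates[, c("id", "source", "probe", "score",
                                    "verdict", "consensus_fraction")],
                     file.path(config$out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  groups_tbl <- do.call(rbind, lapply(refset$groups, function(g)
    data.frame(code = g$code, representative = g$representative,
               members = paste(g$members, collapse = ","))))
  utils::write.table(groups_tbl, file.path(config$out_dir, "groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(refset$overlap,
                     file.path(config$out_dir, "overlap_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  write_newick(refset$guide$tree, file.path(config$out_dir, "guide.nwk"))
  manifest <- list(config = unclass(config), config_hash = config_hash(config),
                   n_candidates = nrow(candidates),
                   n_validated = nrow(validated),
                   n_groups = length(refset$groups),
                   n_subfamilies = if (is.null(classification)) NA else
                     length(classification$clades))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  structure(list(candidates = candidates, calls = calls, refset = refset,
                 classification = classification, manifest = manifest),
            class = "gf_run")
}

#' @export
print.gf_run <- function(x, ...) {
  cat(sprintf("Pipeline run: %d candidates, %d validated, %d groups%s\n",
              x$manifest$n_candidates, x$manifest$n_validated,
              x$manifest$n_groups,
              if (is.na(x$manifest$n_subfamilies)) "" else
                sprintf(", %d subfamilies", x$manifest$n_subfamilies)))
  invisible(x)
}
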