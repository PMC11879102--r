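#' Pipeline run configuration
#'
#' Paths and thresholds for an end-to-end run: score the drug (and
#' optionally disease) queries against the signature library, call and
#' classify targets, build the component-target network and, given a GMT
#' file, run over-representation analysis.
#'
#' @param drug_rnk Path to the drug query RNK file.
#' @param siglib Path to the signature library TSV
#'   (see [write_signature_library()]).
#' @param out_dir Output directory (created if missing).
#' @param disease_rnk Optional disease query RNK path.
#' @param binding_tsv Optional binding-score TSV
#'   (`compound_id`, `protein_id`, `score`).
#' @param gmt Optional GMT path for enrichment.
#' @param universe Optional universe file (one gene per line) for ORA.
#' @param fdr_threshold Effect/reversal FDR cutoff (default 0.05).
#' @param binding_threshold Binding-score cutoff (default 0.90).
#' @param abs_nets_threshold |NETS| cutoff for high-impact targets
#'   (default 4).
#' @param top_k Compounds kept in the degree ranking (default 100).
#' @param n_perm Permutations per target (default 1000).
#' @param seed Seed for the permutation stream (default 42).
#' @return List of class `run_config`.
#' @export
run_config <- function(drug_rnk, siglib, out_dir,
                       disease_rnk = NULL, binding_tsv = NULL,
                       gmt = NULL, universe = NULL,
                       fdr_threshold = 0.05, binding_threshold = 0.90,
                       abs_nets_threshold = 4, top_k = 100,
                       n_perm = 1000, seed = 42) {
  cfg <- as.list(environment())
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    stop("fdr_threshold must lie in (0, 1]")
  if (binding_threshold < 0 || binding_threshold > 1)
    stop("binding_threshold must lie in [0, 1]")
  if (abs_nets_threshold < 0) stop("abs_nets_threshold must be >= 0")
  if (top_k < 1 || n_perm < 1) stop("top_k and n_perm must be positive")
  for (p in c(cfg$drug_rnk, cfg$siglib, cfg$disease_rnk, cfg$binding_tsv,
              cfg$gmt, cfg$universe))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full target-prediction pipeline
#'
#' Stages: score the drug query (and the disease query if supplied) -->
#' call effect and reversal targets --> classify direct/indirect using
#' binding calls (absent binding input degrades to all-indirect, with a
#' warning) --> component-target network and degree ranking --> optional
#' pathway enrichment with direct/indirect annotation. Writes every stage
#' table plus a `manifest.json` (package version, seeds, thresholds,
#' input checksums) that makes the run reproducible; rerunning with the
#' same seeds yields byte-identical tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, the output directory; stage tables are written
#'   there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  siglib <- .stage("read-siglib", read_signature_library(config$siglib))
  drug <- .stage("read-drug-query", read_rnk(config$drug_rnk))
  drug_res <- .stage("score-drug",
    score_query(drug, siglib, n_perm = config$n_perm, seed = config$seed))
  write_tsv(drug_res, file.path(config$out_dir, "ets_drug.tsv"))

  disease_res <- NULL
  if (!is.null(config$disease_rnk)) {
    disease <- .stage("read-disease-query", read_rnk(config$disease_rnk))
    disease_res <- .stage("score-disease",
      score_query(disease, siglib, n_perm = config$n_perm,
                  seed = config$seed + 1L))
    write_tsv(disease_res, file.path(config$out_dir, "ets_disease.tsv"))
  }

  binding_calls <- NULL
  binding_targets <- character(0L)
  if (!is.null(config$binding_tsv)) {
    scores <- .stage("read-binding", read_tsv(config$binding_tsv))
    binding_calls <- call_binding_targets(scores,
                                          config$binding_threshold)
    binding_targets <- unique(binding_calls$protein_id)
  } else {
    warning("no binding input: every effect target is classified indirect")
  }

  calls <- .stage("classify",
    target_calls(drug_res, disease_res, binding_targets,
                 config$fdr_threshold))
  write_tsv(calls, file.path(config$out_dir, "target_calls.tsv"))

  direct <- calls$target_id[calls$direct]
  if (!is.null(binding_calls)) {
    net <- .stage("network", build_component_network(binding_calls, direct))
    write_tsv(net$edges, file.path(config$out_dir, "edges.tsv"))
    write_tsv(data.frame(compound_id = top_components(net, config$top_k),
                         stringsAsFactors = FALSE),
              file.path(config$out_dir, "top_components.tsv"))
  }

  if (!is.null(config$gmt)) {
    universe <- if (!is.null(config$universe))
      readLines(config$universe, warn = FALSE) else NULL
    coll <- .stage("read-gmt", read_gmt(config$gmt, universe = universe))
    query <- calls$target_id[if (is.null(disease_res)) calls$effect
                             else calls$therapeutic]
    enr <- .stage("enrich",
      annotate_pathway(ora(query, coll,
                           fdr_threshold = config$fdr_threshold),
                       direct = direct,
                       indirect = calls$target_id[calls$indirect]))
    write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
  }

  inputs <- Filter(Negate(is.null),
                   config[c("drug_rnk", "disease_rnk", "siglib",
                            "binding_tsv", "gmt", "universe")])
  manifest <- list(
    package = "targetmap",
    version = as.character(utils::packageVersion("targetmap")),
    seed = config$seed, n_perm = config$n_perm,
    thresholds = list(fdr = config$fdr_threshold,
                      binding = config$binding_threshold,
                      abs_nets = config$abs_nets_threshold,
                      top_k = config$top_k),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = list.files(config$out_dir, pattern = "\\.tsv$"))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}
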