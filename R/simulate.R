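#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: a perturbation
#' library with planted up/down gene blocks per target, queries that
#' activate or reverse chosen targets, a compound-protein binding dataset
#' whose labels follow a planted sequence-motif rule, and gene sets
#' overlapping the planted blocks.
#'
#' @param n_genes Gene-universe size (default 2000).
#' @param n_targets Number of targets (default 50).
#' @param replicates_per_target Replicate signatures per target (default 5).
#' @param signature_size Planted block size per direction, also the
#'   extraction size n (default 20).
#' @param effect_size Mean shift of planted genes, in noise-SD units
#'   (default 3).
#' @param noise_sd Gaussian noise SD (default 1).
#' @param n_perm Permutations used downstream (default 1000).
#' @param seed Master seed; module substreams are derived from it.
#' @param n_compounds,n_proteins,n_pairs Binding-dataset dimensions.
#' @param motif_length Protein-motif length (default 5).
#' @param positive_rate Target positive-class fraction (default 0.5).
#' @param label_noise Label-flip probability (default 0.01).
#' @param disjoint_blocks Keep planted blocks disjoint across targets
#'   (default TRUE; requires `2 * signature_size * n_targets <= n_genes`).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_targets = 50,
                              replicates_per_target = 5,
                              signature_size = 20, effect_size = 3,
                              noise_sd = 1, n_perm = 1000, seed = 1,
                              n_compounds = 60, n_proteins = 40,
                              n_pairs = 2000, motif_length = 5,
                              positive_rate = 0.5, label_noise = 0.01,
                              disjoint_blocks = TRUE) {
  cfg <- as.list(environment())
  counts <- c(n_genes, n_targets, replicates_per_target, signature_size,
              n_perm, n_compounds, n_proteins, n_pairs, motif_length)
  if (any(counts < 1)) stop("all counts must be positive")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (2 * signature_size > n_genes)
    stop("2 * signature_size must not exceed n_genes")
  if (disjoint_blocks && 2 * signature_size * n_targets > n_genes)
    stop("disjoint blocks need 2 * signature_size * n_targets <= n_genes")
  structure(cfg, class = "simulation_config")
}

# Named substreams off the master seed, so each generator can be rerun
# independently with reproducible output. Kept below 2^31 - 1.
.substream <- function(seed, name) {
  offset <- c(library = 101L, query = 211L, binding = 307L,
              genesets = 401L)[[name]]
  (as.integer(seed) + offset) %% 2147483647L
}

#' Generate a replicate perturbation library with planted ground truth
#'
#' Each target receives disjoint up and down gene blocks of
#' `signature_size` genes; every replicate profile carries
#' `+effect_size` on the up block and `-effect_size` on the down block,
#' plus Gaussian noise everywhere.
#'
#' @param config A [simulation_config()].
#' @return List with `profiles` (genes x replicates matrix), `meta`
#'   (signature metadata data frame), `ground_truth` (per-target blocks)
#'   and `config`.
#' @export
generate_signature_library <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.substream(config$seed, "library"))
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  targets <- sprintf("T%03d", seq_len(config$n_targets))
  n <- config$signature_size
  blocks <- vector("list", config$n_targets)
  names(blocks) <- targets
  if (config$disjoint_blocks) {
    pool <- sample(genes)
    for (i in seq_along(targets)) {
      off <- (i - 1L) * 2L * n
      blocks[[i]] <- list(up = pool[off + seq_len(n)],
                          down = pool[off + n + seq_len(n)])
    }
  } else {
    for (i in seq_along(targets)) {
      pick <- sample(genes, 2L * n)
      blocks[[i]] <- list(up = pick[seq_len(n)], down = pick[n + seq_len(n)])
    }
  }
  n_cols <- config$n_targets * config$replicates_per_target
  profiles <- matrix(stats::rnorm(config$n_genes * n_cols, 0,
                                  config$noise_sd),
                     nrow = config$n_genes,
                     dimnames = list(genes, NULL))
  meta <- data.frame(
    signature_id = character(n_cols), perturbagen_id = character(n_cols),
    perturbagen_type = "compound", target_id = character(n_cols),
    stringsAsFactors = FALSE)
  col <- 0L
  for (tg in targets) {
    for (r in seq_len(config$replicates_per_target)) {
      col <- col + 1L
      profiles[blocks[[tg]]$up, col] <-
        profiles[blocks[[tg]]$up, col] + config$effect_size
      profiles[blocks[[tg]]$down, col] <-
        profiles[blocks[[tg]]$down, col] - config$effect_size
      meta$signature_id[col] <- sprintf("%s_r%d", tg, r)
      meta$perturbagen_id[col] <- sprintf("pert_%s", tg)
      meta$target_id[col] <- tg
    }
  }
  colnames(profiles) <- meta$signature_id
  list(profiles = profiles, meta = meta,
       ground_truth = list(blocks = blocks, genes = genes,
                           effect_size = config$effect_size,
                           signature_size = n),
       config = config)
}

#' Generate a query profile activating or reversing chosen targets
#'
#' The per-gene metric is the sum of `direction * effect_size` over the
#' active targets' up blocks (mirrored on the down blocks) plus Gaussian
#' noise, returned as a descending [ranked_query()].
#'
#' @param ground_truth `ground_truth` element of
#'   [generate_signature_library()].
#' @param active_targets Data frame with columns `target_id` and
#'   `direction` (+1 activates, -1 reverses), or `NULL` for a pure-noise
#'   query.
#' @param noise_sd Noise SD (default 1).
#' @param seed RNG seed.
#' @param label Query label.
#' @return A [ranked_query()].
#' @export
generate_query <- function(ground_truth, active_targets = NULL,
                           noise_sd = 1, seed = 1, label = "query") {
  set.seed(.substream(seed, "query"))
  genes <- ground_truth$genes
  metric <- stats::rnorm(length(genes), 0, noise_sd)
  names(metric) <- genes
  if (!is.null(active_targets) && nrow(active_targets) > 0L) {
    unknown <- setdiff(active_targets$target_id,
                       names(ground_truth$blocks))
    if (length(unknown) > 0L)
      stop("unknown target(s): ", paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(active_targets))) {
      b <- ground_truth$blocks[[active_targets$target_id[i]]]
      dir <- active_targets$direction[i]
      metric[b$up] <- metric[b$up] + dir * ground_truth$effect_size
      metric[b$down] <- metric[b$down] - dir * ground_truth$effect_size
    }
  }
  ranked_query(genes, unname(metric), label = label)
}

#' Negate a query (drug-as-reversal-of-disease construction)
#'
#' @param query A [ranked_query()].
#' @param label Label for the negated query.
#' @return A [ranked_query()] with all metrics negated (and hence the
#'   gene order reversed up to ties).
#' @export
negate_query <- function(query, label = paste0(query$label, "_negated")) {
  ranked_query(query$genes, -query$metrics, label = label)
}

#' Block genes of selected targets
#'
#' @inheritParams generate_query
#' @param target_ids Targets whose planted genes to collect.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return Character vector of gene identifiers.
#' @export
target_block_genes <- function(ground_truth, target_ids,
                               direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  unique(unlist(lapply(ground_truth$blocks[target_ids], function(b) {
    switch(direction, up = b$up, down = b$down, both = c(b$up, b$down))
  })))
}

.SIM_FRAGMENTS <- c("C", "CC", "CCC", "O", "N", "CO", "CN", "OC", "NC",
                    "C(=O)O", "C(=O)N", "c1ccccc1", "C1CCCCC1", "S",
                    "Cl", "F", "C(C)C", "CCN", "COC")
.SIM_SMILES_MOTIF <- "N1CCOCC1"

#' Generate a compound-protein binding dataset with a planted rule
#'
#' Compounds are random concatenations of small SMILES fragments; proteins
#' are random amino-acid strings. A fragment motif is planted into a
#' subset of compounds and a sequence motif into a subset of proteins; a
#' pair's label is 1 exactly when both carry their motif, with a small
#' label-flip noise. Motif carrier rates are set so the positive-class
#' fraction is near `positive_rate`.
#'
#' @param config A [simulation_config()].
#' @return List with `pairs` (training data frame), `compounds`,
#'   `proteins`, `smiles_motif`, `protein_motif`.
#' @export
generate_binding_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.substream(config$seed, "binding"))
  p_carry <- sqrt(config$positive_rate)
  protein_motif <- paste(sample(setdiff(.AA_CHARS, "X"),
                                config$motif_length, replace = TRUE),
                         collapse = "")
  compounds <- data.frame(
    compound_id = sprintf("com%03d", seq_len(config$n_compounds)),
    smiles = vapply(seq_len(config$n_compounds), function(i) {
      frags <- sample(.SIM_FRAGMENTS, sample(3:8, 1L), replace = TRUE)
      if (stats::runif(1) < p_carry) {
        at <- sample(length(frags) + 1L, 1L)
        frags <- append(frags, .SIM_SMILES_MOTIF, after = at - 1L)
      }
      paste(frags, collapse = "")
    }, character(1L)), stringsAsFactors = FALSE)
  proteins <- data.frame(
    protein_id = sprintf("prot%03d", seq_len(config$n_proteins)),
    sequence = vapply(seq_len(config$n_proteins), function(i) {
      len <- sample(80:200, 1L)
      s <- paste(sample(setdiff(.AA_CHARS, "X"), len, replace = TRUE),
                 collapse = "")
      if (stats::runif(1) < p_carry) {
        at <- sample(len - config$motif_length, 1L)
        s <- paste0(substr(s, 1L, at), protein_motif,
                    substr(s, at + config$motif_length + 1L, len))
      }
      s
    }, character(1L)), stringsAsFactors = FALSE)
  total <- config$n_compounds * config$n_proteins
  if (config$n_pairs > total)
    stop("n_pairs exceeds the number of distinct compound-protein pairs")
  pick <- sample.int(total, config$n_pairs)
  ci <- ((pick - 1L) %% config$n_compounds) + 1L
  pi <- ((pick - 1L) %/% config$n_compounds) + 1L
  has_f <- grepl(.SIM_SMILES_MOTIF, compounds$smiles[ci], fixed = TRUE)
  has_p <- grepl(protein_motif, proteins$sequence[pi], fixed = TRUE)
  label <- as.integer(has_f & has_p)
  flip <- stats::runif(config$n_pairs) < config$label_noise
  label[flip] <- 1L - label[flip]
  pairs <- data.frame(
    compound_id = compounds$compound_id[ci],
    smiles = compounds$smiles[ci],
    protein_id = proteins$protein_id[pi],
    sequence = proteins$sequence[pi],
    label = label, stringsAsFactors = FALSE)
  list(pairs = pairs, compounds = compounds, proteins = proteins,
       smiles_motif = .SIM_SMILES_MOTIF, protein_motif = protein_motif)
}

#' Generate gene sets overlapping planted target blocks
#'
#' Half of the sets are enriched: a fraction `overlap_fraction` of their
#' members is drawn from one target's up block (cycling over targets), the
#' rest at random; the other half is fully random. The universe is the
#' whole simulated gene space.
#'
#' @inheritParams generate_query
#' @param n_sets Number of gene sets (default 20).
#' @param overlap_fraction Fraction of an enriched set drawn from its
#'   target's up block (default 0.8).
#' @param set_size Members per set (default 20).
#' @param seed RNG seed.
#' @return A [gene_set_collection()] with attribute `planted` (data frame
#'   `pathway_id`, `target_id`; `NA` for random sets).
#' @export
generate_genesets <- function(ground_truth, n_sets = 20,
                              overlap_fraction = 0.8, set_size = 20,
                              seed = 1) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]")
  set.seed(.substream(seed, "genesets"))
  genes <- ground_truth$genes
  targets <- names(ground_truth$blocks)
  n_enriched <- n_sets %/% 2L
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  planted <- rep(NA_character_, n_sets)
  for (i in seq_len(n_sets)) {
    if (i <= n_enriched) {
      tg <- targets[((i - 1L) %% length(targets)) + 1L]
      planted[i] <- tg
      block <- ground_truth$blocks[[tg]]$up
      n_in <- min(round(overlap_fraction * set_size), length(block))
      core <- if (n_in > 0L) sample(block, n_in) else character(0L)
      rest <- sample(setdiff(genes, core), set_size - n_in)
      sets[[i]] <- c(core, rest)
    } else {
      sets[[i]] <- sample(genes, set_size)
    }
  }
  desc <- ifelse(is.na(planted), "random set",
                 paste0("enriched for ", planted, " up-block"))
  coll <- gene_set_collection(sets,
                              descriptions = stats::setNames(desc, names(sets)),
                              universe = genes)
  attr(coll, "planted") <- data.frame(pathway_id = names(sets),
                                      target_id = planted,
                                      stringsAsFactors = FALSE)
  coll
}
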