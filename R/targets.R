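#' Call effect targets from connectivity results
#'
#' Targets whose pooled-null FDR is at or below the threshold are regarded
#' as effect targets of the query perturbagen.
#'
#' @param results Connectivity result `data.frame` (see [score_query()]).
#' @param fdr_threshold Inclusive FDR cutoff (default 0.05).
#' @return Character vector of target identifiers.
#' @export
call_effect_targets <- function(results, fdr_threshold = 0.05) {
  stopifnot(all(c("target_id", "fdr") %in% names(results)))
  results$target_id[results$fdr <= fdr_threshold]
}

#' Drug-versus-disease reversal (therapeutic) targets
#'
#' Targets significantly affected by both the drug and the disease
#' (FDR at or below the threshold in each) whose normalized scores carry
#' strictly opposite signs — the drug pushes the target the opposite way
#' from the disease. A NETS of exactly 0 on either side carries no
#' direction and excludes the target.
#'
#' @param drug,disease Connectivity result data frames sharing a target
#'   universe.
#' @param fdr_threshold Inclusive FDR cutoff applied to both sides.
#' @return Character vector of target identifiers (order: drug table).
#' @export
reversal_targets <- function(drug, disease, fdr_threshold = 0.05) {
  shared <- intersect(drug$target_id, disease$target_id)
  if (length(shared) == 0L)
    stop("drug and disease results share no targets")
  d <- drug[match(shared, drug$target_id), ]
  x <- disease[match(shared, disease$target_id), ]
  keep <- d$fdr <= fdr_threshold & x$fdr <= fdr_threshold &
    sign(d$nets) == -sign(x$nets) & d$nets != 0 & x$nets != 0
  shared[keep]
}

#' Split effect targets into direct and indirect
#'
#' Direct targets both bind the compound(s) and mediate expression effects:
#' the intersection of the effect and binding sets. Indirect targets are
#' the remaining effect targets, influenced downstream of direct ones. The
#' two always partition the effect set.
#'
#' @param effect Character vector of effect targets.
#' @param binding Character vector of binding targets.
#' @return List with elements `direct` and `indirect`.
#' @export
classify_targets <- function(effect, binding) {
  effect <- unique(as.character(effect))
  binding <- unique(as.character(binding))
  list(direct = intersect(effect, binding),
       indirect = setdiff(effect, binding))
}

#' Correlate normalized scores of two queries
#'
#' Pearson product-moment correlation of NETS values over the targets
#' shared by two queries, optionally restricted to a target subset (e.g.
#' the reversal set).
#'
#' @param nets_a,nets_b Named numeric vectors of NETS keyed by target.
#' @param restrict Optional character vector of targets to keep.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
compare_queries <- function(nets_a, nets_b, restrict = NULL) {
  shared <- intersect(names(nets_a), names(nets_b))
  if (!is.null(restrict)) shared <- intersect(shared, restrict)
  if (length(shared) < 3L) stop("need at least 3 shared targets")
  a <- nets_a[shared]; b <- nets_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero variance")
  stats::cor(a, b)
}

#' Extract a named NETS vector from a connectivity result table
#'
#' @param results Connectivity result `data.frame`.
#' @return Named numeric vector of NETS values keyed by target.
#' @export
nets_vector <- function(results) {
  stats::setNames(results$nets, results$target_id)
}

#' Build the component-to-direct-target interaction network
#'
#' Bipartite network linking compounds to the direct targets they are
#' called to bind; edges whose target is not in the direct set are
#' excluded.
#'
#' @param binding_calls Data frame with columns `compound_id` and
#'   `protein_id` (or `target_id`), e.g. from [call_binding_targets()].
#' @param direct Character vector of direct targets.
#' @return Object of class `component_network`: `edges` (data frame),
#'   `compound_degree` and `target_degree` (named integer vectors).
#' @export
build_component_network <- function(binding_calls, direct) {
  tcol <- if ("target_id" %in% names(binding_calls)) "target_id"
          else "protein_id"
  stopifnot("compound_id" %in% names(binding_calls))
  edges <- data.frame(compound_id = as.character(binding_calls$compound_id),
                      target_id = as.character(binding_calls[[tcol]]),
                      stringsAsFactors = FALSE)
  edges <- unique(edges[edges$target_id %in% direct, , drop = FALSE])
  deg <- function(x) {
    t <- table(x)
    stats::setNames(as.integer(t), names(t))
  }
  structure(list(edges = edges,
                 compound_degree = deg(edges$compound_id),
                 target_degree = deg(edges$target_id)),
            class = "component_network")
}

#' @export
print.component_network <- function(x, ...) {
  cat("<component_network> ", nrow(x$edges), " edges, ",
      length(x$compound_degree), " compounds, ",
      length(x$target_degree), " direct targets\n", sep = "")
  invisible(x)
}

#' Top compounds of a component-target network, by degree
#'
#' Compounds ranked by the number of direct targets they hit; ties broken
#' lexicographically by compound identifier for reproducibility.
#'
#' @param network A [build_component_network()] result.
#' @param k Number of compounds to keep (default 100).
#' @return Character vector of at most `k` compound identifiers.
#' @export
top_components <- function(network, k = 100) {
  d <- network$compound_degree
  if (length(d) == 0L) return(character(0L))
  ord <- order(-d, names(d))
  head(names(d)[ord], k)
}

#' High-impact targets by absolute normalized score
#'
#' Targets whose |NETS| reaches the threshold; the default 4 marks the
#' strong-impact tier used when focusing a component-target network.
#'
#' @param results Connectivity result `data.frame`.
#' @param abs_nets_threshold Inclusive |NETS| cutoff (default 4).
#' @return Character vector of target identifiers.
#' @export
top_targets <- function(results, abs_nets_threshold = 4) {
  stopifnot(all(c("target_id", "nets") %in% names(results)))
  results$target_id[abs(results$nets) >= abs_nets_threshold]
}

#' Tabulate target roles across the analysis
#'
#' Combines drug/disease connectivity results and binding calls into one
#' table of per-target role flags (effect, binding, direct, indirect,
#' therapeutic) with the underlying scores.
#'
#' @param drug Connectivity results for the drug query.
#' @param disease Optional connectivity results for the disease query.
#' @param binding Character vector of binding targets (may be empty).
#' @param fdr_threshold Inclusive FDR cutoff.
#' @return Data frame, one row per target in the drug results.
#' @export
target_calls <- function(drug, disease = NULL, binding = character(0L),
                         fdr_threshold = 0.05) {
  effect <- call_effect_targets(drug, fdr_threshold)
  cls <- classify_targets(effect, binding)
  therapeutic <- if (!is.null(disease))
    reversal_targets(drug, disease, fdr_threshold) else character(0L)
  out <- data.frame(
    target_id = drug$target_id,
    effect = drug$target_id %in% effect,
    binding = drug$target_id %in% binding,
    direct = drug$target_id %in% cls$direct,
    indirect = drug$target_id %in% cls$indirect,
    therapeutic = drug$target_id %in% therapeutic,
    nets_drug = drug$nets, fdr_drug = drug$fdr,
    stringsAsFactors = FALSE)
  if (!is.null(disease)) {
    m <- match(out$target_id, disease$target_id)
    out$nets_disease <- disease$nets[m]
    out$fdr_disease <- disease$fdr[m]
  } else {
    out$nets_disease <- NA_real_
    out$fdr_disease <- NA_real_
  }
  out
}
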