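#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (gene sets); an optional
#'   `descriptions` character vector (same names) annotates them.
#' @param descriptions Optional named character vector of descriptions.
#' @param universe Optional gene universe; defaults to the union of all
#'   set members. Members outside the universe are dropped.
#' @return Object of class `gene_set_collection` with elements `sets`,
#'   `descriptions`, `universe`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) universe <- unique(unlist(sets))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, intersect, y = universe)
  if (any(lengths(sets) == 0L))
    stop("gene set(s) empty after universe filtering: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x$sets), " sets over ",
      length(x$universe), " genes (sizes ", min(lengths(x$sets)), "-",
      max(lengths(x$sets)), ")\n", sep = "")
  invisible(x)
}

#' Hypergeometric upper-tail probability for over-representation
#'
#' Probability of observing `k` or more members of a `K`-gene set in a
#' query of `m` genes drawn without replacement from a universe of `N`.
#'
#' @param N Universe size.
#' @param K Gene-set size.
#' @param m Query size.
#' @param k Observed overlap.
#' @return `P(X >= k)`, in `[0, 1]`.
#' @export
hypergeom_p <- function(N, K, m, k) {
  if (any(c(N, K, m, k) < 0) || k > min(m, K) || K > N || m > N)
    stop("inconsistent counts: need 0 <= k <= min(m, K) <= N")
  stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1) || anyNA(pvalues))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a target set against gene sets
#'
#' Hypergeometric upper-tail test of the query against every gene set in
#' the collection (sizes within `[min_size, max_size]` after universe
#' filtering), with Benjamini-Hochberg correction across the tested sets.
#' Query genes outside the universe are dropped (count reported via
#' `message`) before the query size `m` is fixed. Only sets overlapping
#' the query (`k >= 1`) are reported, sorted by p ascending.
#'
#' @param query Character vector of genes/targets of interest.
#' @param collection A [gene_set_collection()].
#' @param fdr_threshold Reporting threshold recorded in the output
#'   attribute `fdr_threshold` (rows are not filtered; default 0.05).
#' @param min_size,max_size Gene-set size bounds (defaults 5 and 2000).
#' @return Data frame with columns `pathway_id`, `description`, `k`, `m`,
#'   `K`, `N`, `p`, `fdr`, `members`.
#' @export
ora <- function(query, collection, fdr_threshold = 0.05,
                min_size = 5, max_size = 2000) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  inside <- intersect(query, collection$universe)
  if (length(inside) == 0L)
    stop("query has no overlap with the collection universe")
  dropped <- length(query) - length(inside)
  if (dropped > 0L)
    message(dropped, " query gene(s) outside the universe dropped")
  sets <- collection$sets
  sets <- sets[lengths(sets) >= min_size & lengths(sets) <= max_size]
  if (length(sets) == 0L) stop("no gene set within the size bounds")
  N <- length(collection$universe)
  m <- length(inside)
  k <- vapply(sets, function(s) length(intersect(s, inside)), integer(1L))
  keep <- k >= 1L
  if (!any(keep)) {
    out <- data.frame(pathway_id = character(0L), description = character(0L),
                      k = integer(0L), m = integer(0L), K = integer(0L),
                      N = integer(0L), p = numeric(0L), fdr = numeric(0L),
                      members = character(0L), stringsAsFactors = FALSE)
    return(structure(out, fdr_threshold = fdr_threshold))
  }
  sets <- sets[keep]; k <- k[keep]
  K <- lengths(sets)
  p <- mapply(function(Ki, ki) hypergeom_p(N, Ki, m, ki), K, k)
  fdr <- bh_fdr(p)
  out <- data.frame(
    pathway_id = names(sets),
    description = as.character(collection$descriptions[names(sets)]),
    k = as.integer(k), m = m, K = as.integer(K), N = N, p = p, fdr = fdr,
    members = vapply(sets, function(s)
      paste(sort(intersect(s, inside)), collapse = ","), character(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, fdr_threshold = fdr_threshold)
}

#' Annotate pathway members as direct or indirect targets
#'
#' Partitions each pathway's overlapping members into direct and indirect
#' targets according to the supplied calls; members in neither set remain
#' unlabeled. Overlap counts and statistics are unchanged.
#'
#' @param result An [ora()] result data frame.
#' @param direct,indirect Character vectors of called targets.
#' @return The result with added `direct_members` / `indirect_members`
#'   columns (comma-separated).
#' @export
annotate_pathway <- function(result, direct, indirect) {
  members <- strsplit(result$members, ",", fixed = TRUE)
  result$direct_members <- vapply(members, function(mm)
    paste(intersect(mm, direct), collapse = ","), character(1L))
  result$indirect_members <- vapply(members, function(mm)
    paste(intersect(mm, indirect), collapse = ","), character(1L))
  result
}
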