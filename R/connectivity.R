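#' Construct a ranked query gene list
#'
#' A query is a gene list ranked in descending order of a differential
#' metric (e.g. signal-to-noise ratio or log fold change between treated
#' and control samples). If the input is not already sorted it is sorted
#' descending, stably, preserving input order among tied metrics.
#'
#' @param genes Character vector of unique gene identifiers.
#' @param metrics Numeric vector of finite per-gene metrics.
#' @param label Query label (e.g. "drug", "disease").
#' @return Object of class `ranked_query` with elements `label`, `genes`
#'   (descending by metric) and `metrics`.
#' @export
ranked_query <- function(genes, metrics, label = "query") {
  genes <- as.character(genes)
  metrics <- as.numeric(metrics)
  if (length(genes) != length(metrics))
    stop("genes and metrics must have the same length")
  if (length(genes) < 2L) stop("a query needs at least 2 genes")
  if (anyDuplicated(genes))
    stop("duplicate gene in query: ",
         genes[anyDuplicated(genes)])
  if (!all(is.finite(metrics))) stop("non-finite metrics in query")
  if (is.unsorted(rev(metrics))) {          # not non-increasing
    ord <- order(metrics, decreasing = TRUE) # stable (radix)
    genes <- genes[ord]
    metrics <- metrics[ord]
  }
  structure(list(label = label, genes = genes, metrics = metrics),
            class = "ranked_query")
}

#' @export
print.ranked_query <- function(x, ...) {
  cat("<ranked_query> ", x$label, ": ", length(x$genes), " genes, metric [",
      signif(x$metrics[length(x$metrics)], 3), ", ",
      signif(x$metrics[1L], 3), "]\n", sep = "")
  invisible(x)
}

# Running-sum extremum from sorted 1-based hit positions in a list of
# length G. Computed in integer units of 1/(h*(G-h)): a hit adds G-h, a
# miss subtracts h, so candidate extrema are exact and ties resolve by
# walk order (earliest prefix position wins), matching a full prefix scan.
.es_from_positions <- function(pos, G) {
  h <- length(pos)
  if (h == 0L) return(0)
  if (h >= G) return(1)
  d <- G - h
  i <- seq_len(h)
  at_hit <- i * d - (pos - i) * h     # prefix value at each hit
  before <- at_hit - d                # prefix value just before each hit
  imax <- which.max(at_hit)
  vmax <- at_hit[imax]; pmax <- pos[imax]
  imin <- which.min(before)
  vmin <- before[imin]; pmin <- pos[imin] - 1L
  if (vmin > 0) {                     # the sum returns to 0 at position G
    vmin <- 0; pmin <- G
  }
  v <- if (abs(vmax) > abs(vmin)) vmax
       else if (abs(vmin) > abs(vmax)) vmin
       else if (pmax <= pmin) vmax else vmin
  v / (h * d)
}

# Metric-weighted variant (weight exponent 1): hits advance by
# |metric|/sum(|metric| over hits); misses retreat by 1/(G - h).
.es_weighted <- function(pos, G, metrics) {
  h <- length(pos)
  if (h == 0L) return(0)
  if (h >= G) return(1)
  w <- abs(metrics[pos])
  tot <- sum(w)
  if (tot == 0) return(.es_from_positions(pos, G))
  step <- rep(-1 / (G - h), G)
  step[pos] <- w / tot
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Running-sum enrichment score of a gene set along a ranked list
#'
#' Walks the ranked list from top to bottom keeping a running sum that
#' rises by `1/|hits|` at each gene of the set and falls by
#' `1/(G - |hits|)` otherwise; the score is the signed extremum of largest
#' absolute value (Kolmogorov-Smirnov-style maximum deviation). `+1` means
#' the set sits exactly at the top of the list, `-1` exactly at the bottom.
#'
#' @param query A [ranked_query()].
#' @param gene_set Character vector of gene identifiers; genes absent from
#'   the query are ignored.
#' @param weighted If `TRUE`, hits are weighted by the absolute query
#'   metric (weight exponent 1) instead of equally.
#' @return Score in `[-1, 1]`; attribute `n_matched` carries the overlap
#'   size. Zero overlap returns 0 with a warning.
#' @export
enrichment_score <- function(query, gene_set, weighted = FALSE) {
  stopifnot(inherits(query, "ranked_query"))
  pos <- which(query$genes %in% gene_set)
  if (length(pos) == 0L) {
    warning("gene set has no overlap with the query; score set to 0")
    return(structure(0, n_matched = 0L))
  }
  es <- if (weighted) .es_weighted(pos, length(query$genes), query$metrics)
        else .es_from_positions(pos, length(query$genes))
  structure(es, n_matched = length(pos))
}

.ets_from_es <- function(es_up, es_down) {
  if ((es_up > 0 && es_down > 0) || (es_up < 0 && es_down < 0)) 0
  else (es_up - es_down) / 2
}

#' Effect target score of a query against one target signature
#'
#' `ETS = (ES_up - ES_down) / 2`, where `ES_up`/`ES_down` are the
#' running-sum enrichment scores of the signature's up and down gene sets
#' along the query. A coherent connection drives the two scores to opposite
#' signs; when both share a strict sign the score is set to 0, since the
#' signature's two halves then point the same way and carry no directional
#' evidence. Signature genes absent from the query are dropped per side; a
#' side left with no genes scores 0 and the result is flagged low-coverage
#' (as is any side matching < 50% of its genes).
#'
#' @inheritParams enrichment_score
#' @param signature A `target_signature` (see [extract_signature()]).
#' @return ETS in `[-1, 1]` with attributes `es_up`, `es_down`,
#'   `up_matched`, `down_matched`, `low_coverage`.
#' @export
ets <- function(query, signature, weighted = FALSE) {
  stopifnot(inherits(query, "ranked_query"),
            inherits(signature, "target_signature"))
  G <- length(query$genes)
  pos_up <- which(query$genes %in% signature$t_up)
  pos_down <- which(query$genes %in% signature$t_down)
  es_fun <- if (weighted) {
    function(p) .es_weighted(p, G, query$metrics)
  } else {
    function(p) .es_from_positions(p, G)
  }
  es_up <- if (length(pos_up)) es_fun(pos_up) else 0
  es_down <- if (length(pos_down)) es_fun(pos_down) else 0
  low <- length(pos_up) < max(1L, signature$n / 2) ||
         length(pos_down) < max(1L, signature$n / 2)
  structure(.ets_from_es(es_up, es_down),
            es_up = es_up, es_down = es_down,
            up_matched = length(pos_up), down_matched = length(pos_down),
            low_coverage = low)
}

#' Permutation null distribution of the effect target score
#'
#' Generates null ETS values by randomly permuting the gene labels of the
#' query (equivalently, placing the signature's matched genes at uniformly
#' random ranks) and rescoring; overlap sizes are preserved. With a seed
#' the output is bit-reproducible.
#'
#' @inheritParams ets
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream (used by [score_query()] to share one stream across targets).
#' @return Numeric vector of `n_perm` null ETS values.
#' @export
permutation_null <- function(query, signature, n_perm = 1000, seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  G <- length(query$genes)
  h_up <- sum(query$genes %in% signature$t_up)
  h_down <- sum(query$genes %in% signature$t_down)
  if (h_up + h_down == 0L) return(rep(0, n_perm))
  vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(G, h_up + h_down)
    eu <- if (h_up) .es_from_positions(sort.int(idx[seq_len(h_up)]), G) else 0
    ed <- if (h_down)
      .es_from_positions(sort.int(idx[seq.int(h_up + 1L, h_up + h_down)]), G)
    else 0
    .ets_from_es(eu, ed)
  }, numeric(1L))
}

#' Nominal permutation p-value of an effect target score
#'
#' Uses only the portion of the null distribution sharing the sign of the
#' actual score: for `actual >= 0`, the fraction of nonnegative nulls at or
#' above it; for `actual < 0`, the fraction of negative nulls below it.
#' A zero numerator is floored at one over the same-sign null count so
#' finite permutations never report p = 0; an empty same-sign portion gives
#' p = 1.
#'
#' @param actual Observed ETS.
#' @param null Numeric vector of null ETS values.
#' @return p-value in `(0, 1]`.
#' @export
p_value <- function(actual, null) {
  if (length(null) == 0L) stop("empty null distribution")
  if (actual >= 0) {
    denom <- sum(null >= 0)
    if (denom == 0L) return(1)
    num <- sum(null >= actual)
  } else {
    denom <- sum(null < 0)
    if (denom == 0L) return(1)
    num <- sum(null < actual)
  }
  max(num, 1L) / denom
}

#' Normalized effect target score (NETS)
#'
#' Divides the actual ETS by the absolute mean of the same-sign portion of
#' its permutation null, making scores comparable across signatures of
#' different sizes and across queries. The sign of the actual score is
#' preserved. A zero actual score, or an empty same-sign null portion,
#' yields 0 (flagged via attribute `undefined`).
#'
#' @inheritParams p_value
#' @return NETS value; `sign(NETS) == sign(actual)`.
#' @export
nets <- function(actual, null) {
  if (length(null) == 0L) stop("empty null distribution")
  if (actual == 0) return(structure(0, undefined = TRUE))
  part <- if (actual > 0) null[null >= 0] else null[null < 0]
  m <- abs(mean(part))
  if (length(part) == 0L || m == 0)
    return(structure(0, undefined = TRUE))
  structure(actual / m, undefined = FALSE)
}

# Normalize a vector of null ETS values by sign portion (for FDR pooling):
# nonnegative values by the mean of the nonnegative portion, negative by
# the absolute mean of the negative portion.
.normalize_null <- function(null) {
  out <- null
  pos <- null >= 0
  mp <- mean(null[pos])
  if (any(pos) && is.finite(mp) && mp > 0) out[pos] <- null[pos] / mp
  else out[pos] <- 0
  mn <- abs(mean(null[!pos]))
  if (any(!pos) && is.finite(mn) && mn > 0) out[!pos] <- null[!pos] / mn
  else out[!pos] <- 0
  out
}

#' Pooled-null false discovery rate for a NETS value
#'
#' Ratio of two tail fractions at the observed NETS: `A`, the same-sign
#' tail fraction in the pooled null NETS over all signatures and all
#' permutations, over `B`, the same-sign tail fraction among the actual
#' NETS of all signatures against the query; clipped at 1. A NETS of 0
#' carries no direction and gets FDR 1.
#'
#' @param nets_i Observed NETS of one signature.
#' @param null_nets Pooled null NETS values (all signatures, all
#'   permutations).
#' @param actual_nets Actual NETS values of all signatures for the query.
#' @return FDR in `[0, 1]`.
#' @export
fdr_pooled <- function(nets_i, null_nets, actual_nets) {
  if (length(null_nets) == 0L || length(actual_nets) == 0L)
    stop("empty null or actual NETS store")
  if (nets_i == 0) return(1)
  if (nets_i > 0) {
    dn <- sum(null_nets >= 0)
    da <- sum(actual_nets >= 0)
    A <- if (dn == 0L) 0 else sum(null_nets >= nets_i) / dn
    B <- if (da == 0L) 0 else sum(actual_nets >= nets_i) / da
  } else {
    dn <- sum(null_nets <= 0)
    da <- sum(actual_nets <= 0)
    A <- if (dn == 0L) 0 else sum(null_nets <= nets_i) / dn
    B <- if (da == 0L) 0 else sum(actual_nets <= nets_i) / da
  }
  if (B == 0) return(1)
  min(A / B, 1)
}

#' Score a ranked query against a signature library
#'
#' Full connectivity analysis for one query: per-target ETS, a shared-seed
#' permutation null (one RNG stream, advanced target by target), nominal p,
#' NETS, and FDR from the null NETS pooled across all targets. Results are
#' sorted by NETS, descending.
#'
#' @inheritParams ets
#' @param library List of `target_signature` objects, or the list returned
#'   by [build_signature_library()].
#' @param n_perm Permutations per target (default 1000).
#' @param seed Integer seed controlling the whole permutation stream.
#' @return `data.frame` with columns `target_id`, `ets`, `p`, `nets`,
#'   `fdr`, `up_matched`, `down_matched`.
#' @export
score_query <- function(query, library, n_perm = 1000, seed = NULL,
                        weighted = FALSE) {
  if (!is.null(library$signatures)) library <- library$signatures
  if (length(library) == 0L) stop("empty signature library")
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(library, function(s) s$target_id, character(1L))
  n_t <- length(library)
  ets_v <- numeric(n_t); p_v <- numeric(n_t); nets_v <- numeric(n_t)
  upm <- integer(n_t); dnm <- integer(n_t)
  null_nets <- vector("list", n_t)
  any_overlap <- FALSE
  for (k in seq_len(n_t)) {
    e <- ets(query, library[[k]], weighted = weighted)
    upm[k] <- attr(e, "up_matched"); dnm[k] <- attr(e, "down_matched")
    if (upm[k] + dnm[k] > 0L) any_overlap <- TRUE
    null <- permutation_null(query, library[[k]], n_perm = n_perm)
    ets_v[k] <- as.numeric(e)
    p_v[k] <- p_value(ets_v[k], null)
    nets_v[k] <- as.numeric(nets(ets_v[k], null))
    null_nets[[k]] <- .normalize_null(null)
  }
  if (!any_overlap) stop("no signature in the library overlaps the query")
  pooled <- unlist(null_nets, use.names = FALSE)
  fdr_v <- vapply(nets_v, fdr_pooled, numeric(1L),
                  null_nets = pooled, actual_nets = nets_v)
  out <- data.frame(target_id = ids, ets = ets_v, p = p_v, nets = nets_v,
                    fdr = fdr_v, up_matched = upm, down_matched = dnm,
                    stringsAsFactors = FALSE)
  out[order(-out$nets, out$target_id), , drop = FALSE]
}
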