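#' Construct an expression signature
#'
#' A single replicate perturbation signature: one differential-expression
#' metric (z-like score, unitless) per gene, tagged with the perturbagen
#' that produced it and the target it is annotated to.
#'
#' @param signature_id Opaque identifier for the replicate.
#' @param genes Character vector of unique gene identifiers.
#' @param values Numeric vector of finite per-gene scores, same length.
#' @param perturbagen_id,target_id Optional annotation strings.
#' @return An object of class `expression_signature`.
#' @export
expression_signature <- function(signature_id, genes, values,
                                 perturbagen_id = NA_character_,
                                 target_id = NA_character_) {
  genes <- as.character(genes)
  values <- as.numeric(values)
  if (length(genes) != length(values))
    stop("genes and values must have the same length")
  if (length(genes) < 2L)
    stop("a signature needs at least 2 genes")
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in signature '", signature_id, "'")
  if (!all(is.finite(values)))
    stop("non-finite values in signature '", signature_id, "'")
  structure(
    list(signature_id = as.character(signature_id), genes = genes,
         values = stats::setNames(values, genes),
         perturbagen_id = perturbagen_id, target_id = target_id),
    class = "expression_signature")
}

.sig_values <- function(x) {
  if (inherits(x, "expression_signature")) return(x$values)
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("expected an expression_signature or a named numeric vector")
}

.common_genes <- function(signatures) {
  Reduce(intersect, lapply(signatures, function(s) names(.sig_values(s))))
}

#' Consensus weights for replicate signatures
#'
#' Weights replicates of one target by mutual agreement: each replicate's
#' weight is the sum of its pairwise Spearman correlations with the other
#' replicates (each correlation clipped below at `clip` so that
#' anticorrelated replicates cannot receive a negative or zero weight),
#' normalized to sum to one. A single replicate gets weight 1.
#'
#' @param signatures List of [expression_signature()] objects or named
#'   numeric vectors. All must share at least 3 common genes.
#' @param clip Lower clip applied to each off-diagonal correlation.
#' @return Numeric weight vector, nonnegative, summing to 1, in input order.
#' @export
consensus_weights <- function(signatures, clip = 0.01) {
  if (length(signatures) == 0L) stop("no signatures")
  if (length(signatures) == 1L) return(1)
  genes <- .common_genes(signatures)
  if (length(genes) < 3L) stop("insufficient overlap")
  mat <- vapply(signatures, function(s) .sig_values(s)[genes],
                numeric(length(genes)))
  rho <- stats::cor(mat, method = "spearman")
  rho <- pmax(rho, clip)
  diag(rho) <- 0
  w <- rowSums(rho)
  unname(w / sum(w))
}

#' Weighted-average consensus profile for one target
#'
#' Aggregates replicate signatures into a single consensus profile over the
#' intersection of their gene universes, using [consensus_weights()].
#' Genes missing from any replicate are dropped (count reported via
#' `message`).
#'
#' @inheritParams consensus_weights
#' @param target_id Identifier attached to the result.
#' @return Named numeric vector (class `consensus_profile`) with attributes
#'   `target_id` and `n_dropped_genes`.
#' @export
build_consensus <- function(signatures, target_id = NA_character_,
                            clip = 0.01) {
  if (length(signatures) == 0L) stop("no signatures")
  genes <- .common_genes(signatures)
  all_genes <- unique(unlist(lapply(signatures,
                                    function(s) names(.sig_values(s)))))
  dropped <- length(all_genes) - length(genes)
  if (length(signatures) == 1L) {
    vals <- .sig_values(signatures[[1L]])[genes]
  } else {
    if (length(genes) < 3L) stop("insufficient overlap")
    w <- consensus_weights(signatures, clip = clip)
    mat <- vapply(signatures, function(s) .sig_values(s)[genes],
                  numeric(length(genes)))
    vals <- as.numeric(mat %*% w)
    names(vals) <- genes
  }
  if (dropped > 0L)
    message(dropped, " gene(s) absent from some replicate(s) dropped from consensus")
  structure(vals, target_id = target_id, n_dropped_genes = dropped,
            class = c("consensus_profile", "numeric"))
}

#' Extract a fixed-size up/down gene signature from a consensus profile
#'
#' Takes the `n` genes with the largest consensus values as the up set and
#' the `n` with the smallest as the down set. Ties are broken by input gene
#' order (stable sort), so the result is deterministic.
#'
#' @param profile Named numeric vector (e.g. from [build_consensus()]).
#' @param n Signature size per side; `2 * n` must not exceed the universe.
#' @param target_id Identifier; defaults to the profile's own.
#' @return Object of class `target_signature` with elements `target_id`,
#'   `t_up`, `t_down`, `n`.
#' @export
extract_signature <- function(profile, n, target_id = NULL) {
  vals <- .sig_values(profile)
  if (is.null(target_id))
    target_id <- attr(profile, "target_id") %||% NA_character_
  n <- as.integer(n)
  if (n < 1L) stop("n must be a positive integer")
  if (2L * n > length(vals)) stop("signature size exceeds universe")
  ord <- order(vals, decreasing = TRUE)  # radix sort: stable in input order
  genes <- names(vals)
  structure(
    list(target_id = target_id,
         t_up = genes[ord[seq_len(n)]],
         t_down = genes[ord[seq.int(length(vals) - n + 1L, length(vals))]],
         n = n),
    class = "target_signature")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.target_signature <- function(x, ...) {
  cat("<target_signature> ", x$target_id, ": n = ", x$n,
      " (t_up: ", x$t_up[1L], " ...; t_down: ... ", x$t_down[x$n], ")\n",
      sep = "")
  invisible(x)
}

#' Build a signature library from a profile matrix and metadata
#'
#' Groups replicate signatures by annotated target, builds a consensus
#' profile per target and extracts its up/down signature.
#'
#' @param profiles Numeric matrix, genes in rows (rownames = gene ids),
#'   replicate signatures in columns (colnames = signature ids).
#' @param meta Data frame with columns `signature_id`, `perturbagen_id`,
#'   `perturbagen_type`, `target_id`; one row per profile column.
#' @param n Signature size per side (library default at full scale: 350).
#' @param type_signs Optional named numeric vector of per-perturbagen-type
#'   sign multipliers (e.g. `c(OE = -1)` to flip over-expression profiles
#'   before averaging); types not named keep sign `+1`.
#' @return List with `signatures` (named list of `target_signature`),
#'   `consensus` (genes x targets matrix) and `n`.
#' @export
build_signature_library <- function(profiles, meta, n = 350,
                                    type_signs = NULL) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)),
            !is.null(colnames(profiles)))
  need <- c("signature_id", "target_id")
  if (!all(need %in% names(meta)))
    stop("meta must contain columns: ", paste(need, collapse = ", "))
  meta <- meta[match(colnames(profiles), meta$signature_id), , drop = FALSE]
  if (anyNA(meta$signature_id))
    stop("every profile column needs a metadata row")
  sgn <- rep(1, ncol(profiles))
  if (!is.null(type_signs) && "perturbagen_type" %in% names(meta)) {
    hit <- match(meta$perturbagen_type, names(type_signs))
    sgn <- ifelse(is.na(hit), 1, as.numeric(type_signs)[hit])
  }
  targets <- unique(meta$target_id)
  cons <- matrix(NA_real_, nrow(profiles), length(targets),
                 dimnames = list(rownames(profiles), targets))
  sigs <- vector("list", length(targets))
  names(sigs) <- targets
  for (tg in targets) {
    idx <- which(meta$target_id == tg)
    reps <- lapply(idx, function(i) {
      stats::setNames(profiles[, i] * sgn[i], rownames(profiles))
    })
    cp <- build_consensus(reps, target_id = tg)
    cons[names(cp), tg] <- as.numeric(cp)
    sigs[[tg]] <- extract_signature(cp, n = n, target_id = tg)
  }
  list(signatures = sigs, consensus = cons, n = as.integer(n))
}

#' Decrease rate of the mean absolute effect target score
#'
#' Quantifies how fast the mean |ETS| shrinks as the signature size grows:
#' `DR(s_i) = |m_{i+1} - m_i| / m_i`, the absolute relative change between
#' consecutive sizes. Defined for every size but the last.
#'
#' @param mean_abs_ets Named numeric vector: names are strictly increasing,
#'   evenly spaced signature sizes; values are positive mean |ETS|.
#' @return Named numeric vector of DR values (one fewer than the input).
#' @export
decrease_rate <- function(mean_abs_ets) {
  if (length(mean_abs_ets) < 2L) stop("need at least 2 sizes")
  sizes <- as.numeric(names(mean_abs_ets))
  if (anyNA(sizes)) stop("names of mean_abs_ets must be numeric sizes")
  steps <- diff(sizes)
  if (any(steps <= 0) || length(unique(steps)) > 1L)
    stop("sizes must be strictly increasing with a constant step")
  if (any(mean_abs_ets <= 0)) stop("mean |ETS| values must be positive")
  m <- as.numeric(mean_abs_ets)
  k <- length(m)
  dr <- abs(m[-1L] - m[-k]) / m[-k]
  stats::setNames(dr, names(mean_abs_ets)[-k])
}

#' Choose the signature size from a decrease-rate profile
#'
#' Returns the smallest size whose DR is at or below `threshold`; if no
#' size qualifies, the largest evaluated size is returned with a warning
#' (attribute `fallback = TRUE`).
#'
#' @param dr Named numeric vector from [decrease_rate()].
#' @param threshold DR cutoff; `0.01` marks the full-scale plateau where
#'   the library default n = 350 sits.
#' @return Integer size, with attribute `fallback`.
#' @export
choose_size <- function(dr, threshold = 0.01) {
  if (length(dr) == 0L) stop("empty DR mapping")
  sizes <- as.integer(names(dr))
  ok <- which(dr <= threshold)
  if (length(ok) > 0L)
    return(structure(min(sizes[ok]), fallback = FALSE))
  warning("no size reaches DR <= ", threshold,
          "; falling back to the largest evaluated size")
  structure(max(sizes), fallback = TRUE)
}

#' Mean absolute ETS across a library, by signature size
#'
#' Support routine for the size heuristic: for each candidate size,
#' signatures are re-extracted from the consensus profiles and every
#' profile (as a ranked query) is scored against every signature; the mean
#' of |ETS| over all pairs is returned.
#'
#' @param consensus Genes x targets consensus matrix
#'   (from [build_signature_library()]).
#' @param sizes Integer vector of candidate sizes (full-scale default grid:
#'   `seq(100, 1000, by = 50)`).
#' @return Named numeric vector, one mean |ETS| per size.
#' @export
mean_abs_ets_by_size <- function(consensus, sizes) {
  stopifnot(is.matrix(consensus), length(sizes) >= 1L)
  targets <- colnames(consensus)
  queries <- lapply(targets, function(tg) {
    v <- consensus[, tg]
    v <- v[!is.na(v)]
    ranked_query(names(v), v, label = tg)
  })
  out <- vapply(sizes, function(nn) {
    sigs <- lapply(targets, function(tg) {
      v <- consensus[, tg]
      extract_signature(v[!is.na(v)], n = nn, target_id = tg)
    })
    vals <- unlist(lapply(queries, function(q)
      vapply(sigs, function(s) ets(q, s), numeric(1L))))
    mean(abs(vals))
  }, numeric(1L))
  stats::setNames(out, sizes)
}
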