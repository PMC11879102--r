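# Character vocabularies. Index 1 = padding, 2 = unknown; characters from 3.
.SMILES_CHARS <- c(
  "#", "%", "(", ")", "+", "-", ".", "/", "\\", "=", "@", "[", "]", ":",
  as.character(0:9),
  "A", "B", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "O",
  "P", "R", "S", "T", "U", "V", "W", "Y", "Z",
  "a", "b", "c", "e", "g", "i", "l", "n", "o", "p", "r", "s", "t", "u")
.AA_CHARS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
.PAD_IDX <- 1L
.UNK_IDX <- 2L

.tokenize <- function(x, max_len, vocab) {
  if (!nzchar(x)) stop("empty string")
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  chars <- chars[seq_len(min(length(chars), max_len))]
  idx <- match(chars, vocab) + 2L
  n_unknown <- sum(is.na(idx))
  idx[is.na(idx)] <- .UNK_IDX
  out <- c(idx, rep(.PAD_IDX, max_len - length(idx)))
  structure(as.integer(out), n_unknown = n_unknown)
}

#' Tokenize a SMILES string to a fixed-length index sequence
#'
#' Character-level encoding over a fixed SMILES vocabulary; sequences are
#' truncated at `max_len` and right-padded with the pad index. Characters
#' outside the vocabulary map to a shared unknown index (count available as
#' attribute `n_unknown`, with a warning).
#'
#' @param smiles SMILES string (nonempty).
#' @param max_len Output length (default 100).
#' @return Integer vector of length `max_len`.
#' @export
tokenize_smiles <- function(smiles, max_len = 100) {
  out <- .tokenize(smiles, max_len, .SMILES_CHARS)
  if (attr(out, "n_unknown") > 0L)
    warning(attr(out, "n_unknown"),
            " character(s) outside the SMILES vocabulary mapped to <unk>")
  out
}

#' Tokenize an amino-acid sequence to a fixed-length index sequence
#'
#' As [tokenize_smiles()], over the 20 standard amino acids plus `X`;
#' input is uppercased before lookup.
#'
#' @param sequence Amino-acid string (nonempty).
#' @param max_len Output length (default 1000).
#' @return Integer vector of length `max_len`.
#' @export
tokenize_protein <- function(sequence, max_len = 1000) {
  out <- .tokenize(toupper(sequence), max_len, .AA_CHARS)
  if (attr(out, "n_unknown") > 0L)
    warning(attr(out, "n_unknown"),
            " non-amino-acid character(s) mapped to <unk>")
  out
}

#' Invert [tokenize_smiles()] / [tokenize_protein()]
#'
#' Reconstructs the (possibly truncated) input string from an index
#' sequence; padding is dropped and unknown indices render as `?`.
#'
#' @param tokens Integer index vector.
#' @param alphabet `"smiles"` or `"protein"`.
#' @return Character scalar.
#' @export
detokenize <- function(tokens, alphabet = c("smiles", "protein")) {
  alphabet <- match.arg(alphabet)
  vocab <- if (alphabet == "smiles") .SMILES_CHARS else .AA_CHARS
  tokens <- tokens[tokens != .PAD_IDX]
  chars <- ifelse(tokens == .UNK_IDX, "?", vocab[tokens - 2L])
  paste(chars, collapse = "")
}

#' Training configuration for the binding classifier
#'
#' Defaults follow the reference training recipe (learning rate 8e-4,
#' batch size 256, binary cross-entropy) with a desk-scale epoch count of
#' 30; the full-scale recipe uses 100 epochs.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param max_smiles_len,max_protein_len Truncation lengths for the two
#'   sequence branches.
#' @param hidden Integer vector of hidden-layer widths.
#' @param max_features Cap on the n-gram feature count per branch.
#' @param seed RNG seed covering the split, initialization and batching.
#' @return A list of class `binding_train_config`.
#' @export
binding_train_config <- function(learning_rate = 8e-4, batch_size = 256,
                                 epochs = 30, max_smiles_len = 100,
                                 max_protein_len = 1000,
                                 hidden = c(64, 32), max_features = 2000,
                                 seed = 1) {
  cfg <- list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              max_smiles_len = as.integer(max_smiles_len),
              max_protein_len = as.integer(max_protein_len),
              hidden = as.integer(hidden),
              max_features = as.integer(max_features), seed = as.integer(seed))
  if (any(unlist(cfg[c("learning_rate", "batch_size", "epochs",
                       "max_smiles_len", "max_protein_len")]) <= 0))
    stop("all training-configuration values must be positive")
  structure(cfg, class = "binding_train_config")
}

# ---- character n-gram featurization -----------------------------------

.ngrams <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0L))
  substring(s, seq_len(n - k + 1L), seq.int(k, n))
}

.ngram_set <- function(s, k_set) unlist(lapply(k_set, .ngrams, s = s))

# Build an n-gram vocabulary from training strings: grams present in at
# least two strings, most frequent first, capped at max_features.
.build_ngram_vocab <- function(strings, k_set, max_features) {
  df <- table(unlist(lapply(strings, function(s) unique(.ngram_set(s, k_set)))))
  df <- df[df >= 2L]
  df <- sort(df, decreasing = TRUE)
  head(names(df), max_features)
}

.ngram_matrix <- function(strings, vocab, k_set) {
  X <- matrix(0, length(strings), length(vocab))
  for (i in seq_along(strings)) {
    tab <- table(.ngram_set(strings[[i]], k_set))
    hit <- match(names(tab), vocab)
    keep <- !is.na(hit)
    X[i, hit[keep]] <- as.numeric(tab[keep])
  }
  X
}

.featurize_pairs <- function(pairs, feat) {
  sm <- substr(pairs$smiles, 1L, feat$max_smiles_len)
  pr <- substr(toupper(pairs$sequence), 1L, feat$max_protein_len)
  X <- cbind(.ngram_matrix(sm, feat$smiles_vocab, feat$k_smiles),
             .ngram_matrix(pr, feat$protein_vocab, feat$k_protein))
  X <- log1p(X)
  sweep(sweep(X, 2L, feat$center, "-"), 2L, feat$scale, "/")
}

# ---- minimal feed-forward network (Adam, binary cross-entropy) --------

.mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(stats::rnorm(fan_in * sizes[l + 1L], 0,
                                 sqrt(2 / fan_in)),
                    fan_in, sizes[l + 1L]),
         b = rep(0, sizes[l + 1L]))
  })
}

.mlp_forward <- function(layers, X) {
  acts <- list(X)
  L <- length(layers)
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  acts
}

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

.mlp_fit <- function(X, y, hidden, lr, batch_size, epochs) {
  sizes <- c(ncol(X), hidden, 1L)
  layers <- .mlp_init(sizes)
  L <- length(layers)
  mom <- lapply(layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  n <- nrow(X)
  loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    starts <- seq.int(1L, n, by = batch_size)
    for (s in starts) {
      rows <- idx[seq.int(s, min(s + batch_size - 1L, n))]
      Xb <- X[rows, , drop = FALSE]
      yb <- y[rows]
      acts <- .mlp_forward(layers, Xb)
      p <- acts[[L + 1L]][, 1L]
      # d(BCE)/d(logit) = (p - y)/m for the sigmoid output layer
      delta <- matrix((p - yb) / length(yb), ncol = 1L)
      t <- t + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
        }
        m <- mom[[l]]
        m$mW <- b1 * m$mW + (1 - b1) * gW
        m$vW <- b2 * m$vW + (1 - b2) * gW^2
        m$mb <- b1 * m$mb + (1 - b1) * gb
        m$vb <- b2 * m$vb + (1 - b2) * gb^2
        mom[[l]] <- m
        ch <- 1 - b1^t; cv <- 1 - b2^t
        layers[[l]]$W <- layers[[l]]$W -
          lr * (m$mW / ch) / (sqrt(m$vW / cv) + eps)
        layers[[l]]$b <- layers[[l]]$b -
          lr * (m$mb / ch) / (sqrt(m$vb / cv) + eps)
      }
    }
    loss[ep] <- .bce(.mlp_forward(layers, X)[[L + 1L]][, 1L], y)
  }
  list(layers = layers, loss = loss)
}

# Area under the precision-recall curve by step integration over the
# score-ranked list (average precision).
.aupr <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  sum(precision[y == 1L]) / sum(y)
}

.auroc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Train the compound-protein binding classifier
#'
#' Encodes each pair as character n-gram count features of its SMILES and
#' protein sequence (k = 1..3, vocabulary learned from the training split,
#' log-scaled and standardized) and fits a small feed-forward network with
#' a sigmoid output by mini-batch Adam under binary cross-entropy. The
#' data are split 80/10/10 (train/validation/test) by pair, seeded;
#' held-out AUROC and AUPR are reported on the test split.
#'
#' @param pairs Data frame with columns `compound_id`, `smiles`,
#'   `protein_id`, `sequence`, `label` (0/1).
#' @param config A [binding_train_config()].
#' @return Object of class `binding_model` carrying the fitted weights,
#'   featurization state, per-epoch training `loss`, and held-out
#'   `metrics` (`auroc`, `aupr`).
#' @export
train_binding <- function(pairs, config = binding_train_config()) {
  need <- c("compound_id", "smiles", "protein_id", "sequence", "label")
  if (!all(need %in% names(pairs)))
    stop("pairs must contain columns: ", paste(need, collapse = ", "))
  if (nrow(pairs) < 2L) stop("need at least 2 training pairs")
  y <- as.integer(pairs$label)
  if (length(unique(y)) < 2L) stop("degenerate labels")
  set.seed(config$seed)
  n <- nrow(pairs)
  part <- sample(cut(seq_len(n) / n, c(0, 0.8, 0.9, 1),
                     labels = c("train", "val", "test")))
  tr <- which(part == "train")
  te <- which(part == "test")
  k_smiles <- 1:3; k_protein <- 1:3
  sm_tr <- substr(pairs$smiles[tr], 1L, config$max_smiles_len)
  pr_tr <- substr(toupper(pairs$sequence[tr]), 1L, config$max_protein_len)
  feat <- list(
    smiles_vocab = .build_ngram_vocab(sm_tr, k_smiles, config$max_features),
    protein_vocab = .build_ngram_vocab(pr_tr, k_protein, config$max_features),
    k_smiles = k_smiles, k_protein = k_protein,
    max_smiles_len = config$max_smiles_len,
    max_protein_len = config$max_protein_len)
  raw <- cbind(.ngram_matrix(sm_tr, feat$smiles_vocab, k_smiles),
               .ngram_matrix(pr_tr, feat$protein_vocab, k_protein))
  raw <- log1p(raw)
  feat$center <- colMeans(raw)
  feat$scale <- pmax(apply(raw, 2L, stats::sd), 1e-8)
  Xtr <- sweep(sweep(raw, 2L, feat$center, "-"), 2L, feat$scale, "/")
  fit <- .mlp_fit(Xtr, y[tr], hidden = config$hidden,
                  lr = config$learning_rate,
                  batch_size = config$batch_size, epochs = config$epochs)
  model <- structure(
    list(layers = fit$layers, feat = feat, config = config, loss = fit$loss,
         metrics = NULL, n_train = length(tr), n_test = length(te)),
    class = "binding_model")
  if (length(te) >= 2L && length(unique(y[te])) == 2L) {
    sc <- predict_binding(model, pairs[te, , drop = FALSE])$score
    model$metrics <- list(auroc = .auroc(y[te], sc),
                          aupr = .aupr(y[te], sc))
  }
  model
}

#' @export
print.binding_model <- function(x, ...) {
  cat("<binding_model> ", length(x$feat$smiles_vocab), "+",
      length(x$feat$protein_vocab), " n-gram features, hidden [",
      paste(x$config$hidden, collapse = ", "), "], ",
      x$config$epochs, " epochs; final loss ",
      signif(x$loss[length(x$loss)], 4), sep = "")
  if (!is.null(x$metrics))
    cat("; held-out AUROC ", round(x$metrics$auroc, 3),
        ", AUPR ", round(x$metrics$aupr, 3), sep = "")
  cat("\n")
  invisible(x)
}

#' Predict binding scores for compound-protein pairs
#'
#' @param model A fitted [train_binding()] model.
#' @param pairs Data frame with columns `compound_id`, `smiles`,
#'   `protein_id`, `sequence`.
#' @return Data frame `compound_id`, `protein_id`, `score` with scores in
#'   `[0, 1]`; deterministic for a fixed model and independent of row
#'   order.
#' @export
predict_binding <- function(model, pairs) {
  stopifnot(inherits(model, "binding_model"))
  need <- c("compound_id", "smiles", "protein_id", "sequence")
  if (!all(need %in% names(pairs)))
    stop("pairs must contain columns: ", paste(need, collapse = ", "))
  X <- .featurize_pairs(pairs, model$feat)
  p <- .mlp_forward(model$layers, X)[[length(model$layers) + 1L]][, 1L]
  data.frame(compound_id = pairs$compound_id,
             protein_id = pairs$protein_id,
             score = as.numeric(p), stringsAsFactors = FALSE)
}

#' Call binding targets at a score threshold
#'
#' Retains pairs whose binding score reaches the threshold (inclusive);
#' the default 0.90 is the high-confidence operating point used for
#' herb-level target calling, where an herb's binding-target set is the
#' union over its component compounds.
#'
#' @param scores Data frame `compound_id`, `protein_id`, `score`.
#' @param threshold Minimum score (default 0.90).
#' @return Data frame of called pairs (subset of `scores`).
#' @export
call_binding_targets <- function(scores, threshold = 0.90) {
  stopifnot(all(c("compound_id", "protein_id", "score") %in% names(scores)))
  if (any(scores$score < 0 | scores$score > 1))
    stop("scores must lie in [0, 1]")
  scores[scores$score >= threshold, , drop = FALSE]
}

#' Sample unobserved pairs as negatives
#'
#' Interaction catalogs list only positives; this draws unobserved
#' compound-protein combinations uniformly (without replacement, never
#' colliding with a positive) to serve as negative examples.
#'
#' @param positives Data frame `compound_id`, `protein_id` of known pairs.
#' @param compounds Data frame `compound_id`, `smiles`.
#' @param proteins Data frame `protein_id`, `sequence`.
#' @param ratio Negatives per positive (default 1).
#' @param seed RNG seed.
#' @return Data frame `compound_id`, `smiles`, `protein_id`, `sequence`,
#'   `label = 0`.
#' @export
sample_negative_pairs <- function(positives, compounds, proteins,
                                  ratio = 1, seed = 1) {
  set.seed(seed)
  n_neg <- ceiling(nrow(positives) * ratio)
  pos_key <- paste(positives$compound_id, positives$protein_id, sep = "\r")
  total <- nrow(compounds) * nrow(proteins)
  if (total - length(unique(pos_key)) < n_neg)
    stop("not enough unobserved pairs to sample ", n_neg, " negatives")
  picked <- character(0L)
  while (length(picked) < n_neg) {
    ci <- sample.int(nrow(compounds), n_neg, replace = TRUE)
    pi <- sample.int(nrow(proteins), n_neg, replace = TRUE)
    key <- paste(compounds$compound_id[ci], proteins$protein_id[pi],
                 sep = "\r")
    ok <- !(key %in% pos_key) & !(key %in% picked) & !duplicated(key)
    picked <- c(picked, key[ok])
  }
  picked <- picked[seq_len(n_neg)]
  parts <- strsplit(picked, "\r", fixed = TRUE)
  cid <- vapply(parts, `[`, character(1L), 1L)
  pid <- vapply(parts, `[`, character(1L), 2L)
  data.frame(
    compound_id = cid,
    smiles = compounds$smiles[match(cid, compounds$compound_id)],
    protein_id = pid,
    sequence = proteins$sequence[match(pid, proteins$protein_id)],
    label = 0L, stringsAsFactors = FALSE)
}
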