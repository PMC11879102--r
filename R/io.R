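# All tables are tab-separated UTF-8 with '#' comment lines permitted and
# missing values written as NA. Gene identifiers are opaque, case-sensitive
# strings; no identifier munging happens anywhere.

#' Read a tab-separated table
#'
#' @param path File path.
#' @param header Whether the first non-comment line is a header.
#' @return `data.frame` with character/numeric columns as found.
#' @export
read_tsv <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.delim(path, header = header, sep = "\t",
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE, na.strings = "NA",
                           check.names = FALSE)
  if (nrow(out) == 0L && ncol(out) == 0L) stop("empty file: ", path)
  out
}

#' Write a tab-separated table
#'
#' @param x Data frame.
#' @param path Destination path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a ranked gene list (RNK)
#'
#' Two tab-separated columns, no header: gene identifier and numeric
#' metric. Rows are sorted descending by metric if not already (with a
#' warning); duplicate genes and non-numeric metrics are rejected with the
#' offending line number.
#'
#' @param path RNK file path.
#' @param label Query label (defaults to the file name).
#' @return A [ranked_query()].
#' @export
read_rnk <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty RNK file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    stop("malformed RNK line ", lineno[bad[1L]], " in ", path)
  genes <- vapply(parts, `[`, character(1L), 1L)
  metrics <- suppressWarnings(as.numeric(vapply(parts, `[`,
                                                character(1L), 2L)))
  if (anyNA(metrics))
    stop("non-numeric metric on line ", lineno[which(is.na(metrics))[1L]],
         " in ", path)
  dup <- which(duplicated(genes))
  if (length(dup) > 0L)
    stop("duplicate gene '", genes[dup[1L]], "' on line ",
         lineno[dup[1L]], " in ", path)
  if (is.unsorted(rev(metrics)))
    warning("RNK file not sorted descending; sorting")
  ranked_query(genes, metrics,
               label = label %||% sub("\\.rnk$", "", basename(path)))
}

#' Write a ranked gene list (RNK)
#'
#' @param query A [ranked_query()].
#' @param path Destination path.
#' @export
write_rnk <- function(query, path) {
  writeLines(paste(query$genes, format(query$metrics, trim = TRUE,
                                       scientific = FALSE), sep = "\t"),
             path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard dialect: one set per line — name, description, then
#' tab-separated members.
#'
#' @param path GMT file path.
#' @param universe Optional universe (defaults to the union of members).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L)
    stop("malformed GMT line ", bad[1L], " in ", path,
         " (need name, description, members)")
  ids <- vapply(parts, `[`, character(1L), 1L)
  desc <- vapply(parts, `[`, character(1L), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  gene_set_collection(sets, descriptions = stats::setNames(desc, ids),
                      universe = universe)
}

#' Write a GMT gene-set file
#'
#' @param collection A [gene_set_collection()].
#' @param path Destination path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Data frame with columns `protein_id` (first word of the
#'   header) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  data.frame(protein_id = vapply(strsplit(names(aa), "\\s+"), `[`,
                                 character(1L), 1L),
             sequence = as.character(aa),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write protein sequences to FASTA
#'
#' @param proteins Data frame `protein_id`, `sequence`.
#' @param path Destination path.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                proteins$protein_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a profile matrix (genes x signatures)
#'
#' First column holds gene identifiers; remaining columns are signatures.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene rownames and signature colnames.
#' @export
read_profiles <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a profile matrix
#'
#' @param profiles Numeric matrix (genes x signatures).
#' @param path Destination path.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(gene_id = rownames(profiles), profiles,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write a signature library as a long table
#'
#' Columns: `target_id`, `direction` (up/down), `gene_id`, `rank`
#' (1 = strongest gene of its side).
#'
#' @param library Result of [build_signature_library()], or a list of
#'   `target_signature` objects.
#' @param path Destination path.
#' @export
write_signature_library <- function(library, path) {
  if (!is.null(library$signatures)) library <- library$signatures
  rows <- lapply(library, function(s) {
    data.frame(target_id = s$target_id,
               direction = rep(c("up", "down"), each = s$n),
               gene_id = c(s$t_up, s$t_down),
               rank = rep(seq_len(s$n), 2L), stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read a signature library written by [write_signature_library()]
#'
#' @param path TSV file path.
#' @return Named list of `target_signature` objects.
#' @export
read_signature_library <- function(path) {
  df <- read_tsv(path)
  need <- c("target_id", "direction", "gene_id", "rank")
  if (!all(need %in% names(df)))
    stop("signature library must have columns: ",
         paste(need, collapse = ", "))
  out <- lapply(split(df, df$target_id), function(d) {
    up <- d[d$direction == "up", ]
    down <- d[d$direction == "down", ]
    if (nrow(up) != nrow(down))
      stop("unbalanced up/down sets for target ", d$target_id[1L])
    structure(list(target_id = d$target_id[1L],
                   t_up = up$gene_id[order(up$rank)],
                   t_down = down$gene_id[order(down$rank)],
                   n = nrow(up)),
              class = "target_signature")
  })
  out[unique(df$target_id)]
}
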