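#' Multiple sequence alignment container
#'
#' The first record is the (ungapped) query; homolog rows are stored mapped
#' to the query's column space, i.e. every row has exactly `nchar(query)`
#' characters over the alphabet of the 20 amino acids, X and the gap `-`.
#' In A3M input, lowercase characters are insertions relative to the query
#' and are removed on load.
#'
#' @param query ungapped query sequence.
#' @param rows character vector of aligned homolog rows (may be empty).
#' @param source free-text provenance tag.
#' @return an object of class `msa`.
#' @export
msa <- function(query, rows = character(0), source = "") {
  validate_aa_string(query, "query")
  L <- nchar(query)
  if (length(rows)) {
    bad <- which(nchar(rows) != L)
    if (length(bad))
      stopf("ragged alignment: row %d has %d columns, query has %d",
            bad[1], nchar(rows[bad[1]]), L)
    for (i in seq_along(rows))
      validate_aa_string(rows[[i]], paste0("row ", i), allow_gap = TRUE)
  }
  structure(list(query = query, rows = unname(rows), source = source),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> query length %d, %d homolog row(s)%s\n",
              nchar(x$query), length(x$rows),
              if (nzchar(x$source)) paste0("  [", x$source, "]") else ""))
  invisible(x)
}

#' Read an alignment in A3M or aligned-FASTA format
#'
#' The first record is taken as the query. For A3M, lowercase insertion
#' states are removed from every row (the query itself must be ungapped
#' after case normalization). Aligned FASTA (`afa`) requires all rows to
#' have equal length already.
#'
#' @param path file path.
#' @param format `"a3m"` (default) or `"afa"`.
#' @return an [msa].
#' @export
read_msa <- function(path, format = c("a3m", "afa")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("empty alignment file: %s", path)
  seqs <- as.character(set)
  if (format == "a3m")
    seqs <- vapply(seqs, function(s) gsub("[a-z.]", "", s), character(1))
  seqs <- unname(seqs)
  query <- toupper(gsub("-", "", seqs[[1]], fixed = TRUE))
  msa(query, rows = toupper(seqs[-1]), source = basename(path))
}

#' Write an alignment in A3M layout
#'
#' Rows are already in query column space, so the output is equally valid as
#' aligned FASTA.
#'
#' @param x an [msa].
#' @param path output file path.
#' @param ids optional record names (default `query`, `seq_1`, ...).
#' @export
write_msa <- function(x, path, ids = NULL) {
  stopifnot(inherits(x, "msa"))
  n <- length(x$rows) + 1L
  if (is.null(ids))
    ids <- c("query", if (n > 1) paste0("seq_", seq_len(n - 1L)))
  recs <- c(x$query, x$rows)
  names(recs) <- ids
  Biostrings::writeXStringSet(Biostrings::BStringSet(recs), filepath = path,
                              width = 60L)
  invisible(path)
}

#' Mask alignment columns with the token X
#'
#' Replaces every homolog character at the listed query columns with `X`,
#' removing the evolutionary signal at those positions (the masking applied
#' to substitution sites before structure prediction with an MSA). The query
#' row is masked too only when `mask_query = TRUE`, since predictors require
#' the first row to spell the exact input sequence.
#'
#' @param x an [msa].
#' @param positions integer vector of 1-based query columns.
#' @param mask_query also mask the query row (default `FALSE`).
#' @return a new [msa]; the input is unmodified.
#' @export
mask_columns <- function(x, positions, mask_query = FALSE) {
  stopifnot(inherits(x, "msa"))
  L <- nchar(x$query)
  positions <- unique(as.integer(positions))
  if (length(positions) && (min(positions) < 1L || max(positions) > L))
    stopf("mask position out of range [1, %d]", L)
  mask_one <- function(s) {
    ch <- seq_chars(s)
    ch[positions] <- "X"
    paste(ch, collapse = "")
  }
  msa(query = if (mask_query && length(positions)) mask_one(x$query) else x$query,
      rows = if (length(positions)) vapply(x$rows, mask_one, character(1))
             else x$rows,
      source = x$source)
}

msa_char_matrix <- function(x) {
  all_rows <- c(x$query, x$rows)
  matrix(unlist(lapply(all_rows, seq_chars)), nrow = length(all_rows),
         byrow = TRUE)
}

#' Redundancy-correcting sequence weights
#'
#' Each row (the query included) gets weight `1 / n_i` where `n_i` is the
#' number of rows — itself included — whose pairwise identity to row i is at
#' least `identity_threshold`, identity being computed over mutually non-gap
#' columns. Clusters of near-identical sequences thus contribute total
#' weight ~1.
#'
#' @param x an [msa].
#' @param identity_threshold clustering threshold in (0, 1]; default 0.8.
#' @return numeric weights in (0, 1], one per row (query first).
#' @export
sequence_weights <- function(x, identity_threshold = 0.8) {
  stopifnot(inherits(x, "msa"))
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1)
    stopf("identity_threshold must be in (0, 1]")
  m <- msa_char_matrix(x)
  n <- nrow(m)
  nongap <- m != "-"
  counts <- integer(n)
  for (i in seq_len(n)) {
    mi <- matrix(m[i, ], n, ncol(m), byrow = TRUE)
    shared <- nongap & matrix(nongap[i, ], n, ncol(m), byrow = TRUE)
    cmp <- (m == mi) & shared
    ns <- rowSums(shared)
    ident <- ifelse(ns > 0, rowSums(cmp) / ns, 0)
    counts[i] <- sum(ident >= identity_threshold)
  }
  1 / counts
}

#' Median per-residue effective sequence count (Neff)
#'
#' At every query position, Neff is the sum of redundancy-corrected
#' [sequence_weights()] over the rows that are non-gap at that position; the
#' alignment-level summary is the median over all positions. A single
#' sequence gives 1; N identical rows also give 1 (each carries weight 1/N).
#'
#' @inheritParams sequence_weights
#' @return median per-residue Neff (>= 0).
#' @export
median_neff <- function(x, identity_threshold = 0.8) {
  stopifnot(inherits(x, "msa"))
  w <- sequence_weights(x, identity_threshold)
  m <- msa_char_matrix(x)
  per_pos <- colSums((m != "-") * w)
  stats::median(per_pos)
}
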