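#' k-peptide feature names
#'
#' All `20^k` k-peptides in lexicographic order over the canonical alphabet
#' `ACDEFGHIKLMNPQRSTVWY`, so that column identity is stable across runs.
#'
#' @param k peptide length.
#' @return character vector of length `20^k`.
#' @export
kpc_names <- function(k) {
  stopifnot(k >= 1)
  out <- AA_ALPHABET
  if (k > 1) for (i in seq_len(k - 1)) {
    out <- as.vector(t(outer(out, AA_ALPHABET, paste0)))
  }
  out
}

#' k-peptide composition of one sequence
#'
#' Encodes a protein sequence as the frequency vector of its `L - k + 1`
#' overlapping k-peptides: `f_i = N_i / (L - k + 1)` where `N_i` counts the
#' i-th k-peptide. The vector has length `20^k`, entries in `[0, 1]`, and
#' sums to 1. `k = 1` is amino-acid composition (AAC), `k = 2` dipeptide
#' composition (DPC), `k = 3` tripeptide composition (TPC).
#'
#' @param residues amino-acid string over the standard alphabet.
#' @param k peptide length; the sequence must satisfy `L >= k`.
#' @return named numeric vector of length `20^k`.
#' @export
kpc_encode <- function(residues, k) {
  stopifnot(length(residues) == 1L, k >= 1)
  codes <- match(strsplit(toupper(residues), "")[[1]], AA_ALPHABET)
  if (anyNA(codes))
    stop("nonstandard residue in sequence; sanitize first")
  L <- length(codes)
  if (L < k) stop("sequence_shorter_than_k: L=", L, " < k=", k)
  n_win <- L - k + 1L
  # window index in base 20: first residue most significant
  idx <- codes[seq_len(n_win)] - 1L
  if (k > 1) for (j in 2:k) idx <- idx * 20L + (codes[j:(n_win + j - 1L)] - 1L)
  v <- tabulate(idx + 1L, nbins = 20L^k) / n_win
  names(v) <- kpc_names(k)
  v
}

#' Encode a sequence set as a fused KPC feature matrix
#'
#' Row i is the concatenation of [kpc_encode]`(seq_i, k)` over the requested
#' `ks`, giving `sum(20^k)` columns: 420 for the default `ks = c(1, 2)`
#' (AAC + DPC), 8420 when tripeptides are added.
#'
#' @param seqs an [rbp_sequences] set.
#' @param ks ordered integer vector of peptide lengths (default `c(1, 2)`).
#' @return numeric matrix with one row per sequence (rownames = ids) and
#'   named feature columns; labels carried in `attr(, "label")`.
#' @export
encode_dataset <- function(seqs, ks = c(1, 2)) {
  stopifnot(nrow(seqs) > 0, length(ks) >= 1)
  lens <- nchar(seqs$residues)
  too_short <- lens < max(ks)
  if (any(too_short))
    stop("sequences shorter than k=", max(ks), ": ",
         paste(seqs$id[too_short], collapse = ", "))
  blocks <- lapply(ks, function(k) {
    t(vapply(seqs$residues, kpc_encode, numeric(20^k), k = k,
             USE.NAMES = FALSE))
  })
  X <- do.call(cbind, blocks)
  dimnames(X) <- list(seqs$id, unlist(lapply(ks, kpc_names)))
  attr(X, "label") <- seqs$label
  X
}

#' Append named columns to a feature matrix
#'
#' Used to fuse base-learner prediction columns onto the KPC block (420 KPC
#' columns + 4 prediction columns = the 424-wide default input of the
#' convolutional classifier). Column names must be disjoint from the base
#' and row counts must agree.
#'
#' @param base feature matrix.
#' @param extra named numeric matrix/data frame of additional columns (may
#'   have zero columns).
#' @return the widened matrix; base columns first, `extra` in given order.
#' @export
append_columns <- function(base, extra) {
  extra <- as.matrix(extra)
  if (ncol(extra) == 0L) return(base)
  if (nrow(extra) != nrow(base))
    stop("row-count mismatch: base has ", nrow(base), ", extra has ",
         nrow(extra))
  if (is.null(colnames(extra)) || any(!nzchar(colnames(extra))))
    stop("extra columns must be named")
  dup <- intersect(colnames(base), colnames(extra))
  if (length(dup))
    stop("duplicate column names: ", paste(dup, collapse = ", "))
  out <- cbind(base, extra)
  attr(out, "label") <- attr(base, "label")
  out
}

#' Export / import a feature matrix as CSV
#'
#' Header = column names, first column = sequence id; the format is meant
#' for inspection and cross-language reuse.
#'
#' @param X feature matrix with rownames.
#' @param path CSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_feature_csv <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  X
}
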