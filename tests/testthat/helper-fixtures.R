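AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_seq <- function(L, prob = NULL) {
  paste(sample(AA, L, replace = TRUE, prob = prob), collapse = "")
}

write_tmp_fasta <- function(records, file = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), file)
  file
}

# naive sliding-window KPC oracle: tallies windows into a named map
kpc_oracle <- function(residues, k) {
  chars <- strsplit(residues, "")[[1]]
  n_win <- length(chars) - k + 1
  counts <- new.env()
  for (t in seq_len(n_win)) {
    pep <- paste(chars[t:(t + k - 1)], collapse = "")
    counts[[pep]] <- (counts[[pep]] %||% 0) + 1
  }
  out <- stats::setNames(numeric(20^k), kpc_names(k))
  for (pep in ls(counts)) out[pep] <- counts[[pep]] / n_win
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force metric oracle: tally cells then evaluate each formula directly
metric_oracle <- function(y_true, y_pred) {
  tp <- sum(y_true == 1 & y_pred == 1); tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1); fn <- sum(y_true == 1 & y_pred == 0)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(ACC = 100 * (tp + tn) / (tp + tn + fp + fn),
       SN = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       SP = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
       Precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
       F1 = if (2 * tp + fp + fn > 0) 100 * 2 * tp / (2 * tp + fp + fn) else NA_real_,
       MCC = if (den > 0) 100 * (tp * tn - fp * fn) / den else NA_real_)
}

# small labeled benchmark shared across module tests (memoised)
tiny_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(n_pos = 40, n_neg = 40, length_mean = 120,
                             length_sd = 30, effect_size = 4, seed = 7)
      cache <<- generate_sequences(spec)
    }
    cache
  }
})

tiny_encoded <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      seqs <- tiny_benchmark()
      X <- encode_dataset(seqs, c(1, 2))
      cache <<- list(X = X, y = seqs$label)
    }
    cache
  }
})

# linearly separable feature set for learner sanity checks
separable_xy <- function(n = 80, p = 12, shift = 2, seed = 42) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(stats::rnorm(n * p), n)
  X[y == 1, 1:3] <- X[y == 1, 1:3] + shift
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}
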