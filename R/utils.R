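#' @useDynLib rbpstack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical one-letter alphabet; fixes the lexicographic order of every
# k-peptide feature name so column identity is stable across runs and files.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Codes stripped by sanitization: ambiguity/rare codes, stop, gaps.
NONSTANDARD_CODES <- c("B", "J", "O", "U", "X", "Z", "*", "-", ".")

#' Stratified fold assignment
#'
#' Assigns each row to one of `n_folds` folds such that both classes are
#' spread as evenly as possible across folds. Reproducible from `seed`.
#'
#' @param y binary label vector (0/1).
#' @param n_folds number of folds, at least 2.
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1:n_folds`, one per element of `y`.
#' @export
stratified_folds <- function(y, n_folds, seed) {
  stopifnot(n_folds >= 2)
  y <- as.integer(y)
  if (any(!y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  folds <- integer(length(y))
  rng <- local_rng(seed)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[rng$sample_int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  if (any(tabulate(folds, n_folds) == 0L))
    stop("too few samples for ", n_folds, " folds")
  for (f in seq_len(n_folds)) {
    if (length(unique(y[folds == f])) < 2L && length(unique(y)) == 2L)
      stop("fold ", f, " contains a single class; use fewer folds or a ",
           "different seed (stratification could not balance this split)")
  }
  folds
}

# A tiny RNG wrapper: isolates our draws from the global .Random.seed so
# library code never perturbs (or depends on) the caller's RNG state.
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, .GlobalEnv)
    on.exit({
      state <<- get(".Random.seed", .GlobalEnv)
      if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
      else assign(".Random.seed", old, .GlobalEnv)
    })
    expr
  }
  list(
    sample_int = function(n, size = n, replace = FALSE)
      with_state(sample.int(n, size, replace = replace)),
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    rbinom = function(n, size, prob) with_state(stats::rbinom(n, size, prob)),
    rlnorm = function(n, meanlog, sdlog) with_state(stats::rlnorm(n, meanlog, sdlog)),
    derive = function(offset) seed + offset
  )
}

# Derive a child seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
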