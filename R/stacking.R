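#' Out-of-fold prediction column for one learner
#'
#' Generates a leakage-free meta-feature: row i's score comes from a model
#' trained on the folds that exclude i, under a stratified fold assignment
#' reproducible from `seed`. The column's single-feature AUC against `y` is
#' computed on the assembled out-of-fold vector.
#'
#' @param spec a [base_learner_spec] or learner name.
#' @param X numeric feature matrix.
#' @param y binary labels.
#' @param n_folds number of stacking folds (default 5).
#' @param seed integer seed (folds + learner fits).
#' @param oof if `FALSE`, a "naive" in-sample column is produced instead
#'   (scores from a model trained on all rows); off by default and only for
#'   faithfulness comparisons.
#' @param folds optional precomputed fold assignment (integer vector in
#'   `1:n_folds`); by default a stratified split is derived from `seed`.
#' @return list with `column` (numeric, `[0,1]`), `auc`, `folds`, `name`.
#' @export
oof_predict <- function(spec, X, y, n_folds = 5, seed = 1, oof = TRUE,
                        folds = NULL) {
  spec <- as_learner_spec(spec)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("labels are single-class")
  learner <- make_learner(spec)
  col <- numeric(length(y))
  if (oof) {
    if (is.null(folds)) folds <- stratified_folds(y, n_folds, seed)
    n_folds <- max(folds)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      m <- learner$fit(X[tr, , drop = FALSE], y[tr],
                       seed = derive_seed(seed, f))
      col[!tr] <- learner$predict_proba(m, X[!tr, , drop = FALSE])
    }
  } else {
    folds <- rep(0L, length(y))
    m <- learner$fit(X, y, seed = derive_seed(seed, 0L))
    col <- learner$predict_proba(m, X)
  }
  list(column = col, auc = auc_score(y, col), folds = folds, name = spec$name)
}

#' Build the stacked meta-feature block
#'
#' Runs [oof_predict] for every requested learner under a common seed,
#' records each column's out-of-fold AUC (the ranking input of the
#' correlation-pruning stage), and fits one full-data model per learner for
#' scoring unseen sequences later.
#'
#' @param X numeric feature matrix (typically the 420-wide KPC block).
#' @param y binary labels.
#' @param specs list of [base_learner_spec]s or learner names; default the
#'   four-learner stack SVM, LR, LDA, LightGBM.
#' @param n_folds stacking folds (default 5).
#' @param seed integer seed.
#' @param oof out-of-fold (default) vs in-sample columns, see [oof_predict].
#' @return an `rbp_stack` object: `columns` (matrix, one
#'   `<name>_Pred_Result` column per learner), `fold_assignment`,
#'   `per_learner_auc`, `fitted_full_models`, `specs`, `seed`.
#' @export
build_stack <- function(X, y, specs = list("SVM", "LR", "LDA", "LightGBM"),
                        n_folds = 5, seed = 1, oof = TRUE) {
  if (length(specs) == 0L) stop("specs must be non-empty")
  specs <- lapply(specs, as_learner_spec)
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(names(specs))) stop("duplicate learner names in specs")
  cols <- matrix(NA_real_, nrow(X), length(specs),
                 dimnames = list(rownames(X),
                                 paste0(names(specs), "_Pred_Result")))
  aucs <- stats::setNames(numeric(length(specs)), colnames(cols))
  folds <- NULL
  full <- vector("list", length(specs))
  names(full) <- names(specs)
  for (i in seq_along(specs)) {
    r <- oof_predict(specs[[i]], X, y, n_folds = n_folds, seed = seed,
                     oof = oof)
    cols[, i] <- r$column
    aucs[i] <- r$auc
    folds <- r$folds
    learner <- make_learner(specs[[i]])
    full[[i]] <- learner$fit(X, y, seed = derive_seed(seed, 1000L + i))
  }
  structure(list(columns = cols, fold_assignment = folds,
                 per_learner_auc = aucs, fitted_full_models = full,
                 specs = specs, n_folds = n_folds, seed = seed, oof = oof),
            class = "rbp_stack")
}

#' Score unseen rows with the full-data base models
#'
#' Prediction columns for independent sequences come from the models trained
#' on the whole training set (standard stacking practice at deployment).
#'
#' @param stack an `rbp_stack` from [build_stack].
#' @param X feature matrix of unseen rows (same columns as training).
#' @return matrix of `<name>_Pred_Result` columns.
#' @export
predict_stack <- function(stack, X) {
  out <- vapply(names(stack$specs), function(nm) {
    learner <- make_learner(stack$specs[[nm]])
    learner$predict_proba(stack$fitted_full_models[[nm]], X)
  }, numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X),
                dimnames = list(rownames(X),
                                paste0(names(stack$specs), "_Pred_Result")))
  out
}

#' Random hyperparameter search for one learner
#'
#' Samples `n_iter` configurations from the learner's search space and
#' returns the configuration maximising mean stratified-CV AUC (ties broken by first
#' occurrence). Reproducible from `seed`.
#'
#' @inheritParams oof_predict
#' @param n_iter number of random configurations to evaluate.
#' @return a [base_learner_spec] carrying the winning hyperparameters, with
#'   the searched configurations and their AUCs in `attr(, "search")`.
#' @export
tune_learner <- function(spec, X, y, n_folds = 5, n_iter = 10, seed = 1) {
  spec <- as_learner_spec(spec)
  space <- learner_search_space(spec$name)
  if (length(space) == 0L)
    stop("empty search space for learner ", spec$name)
  rng <- local_rng(seed)
  draws <- lapply(seq_len(n_iter), function(i) {
    lapply(space, function(vals) vals[rng$sample_int(length(vals), 1)])
  })
  aucs <- vapply(seq_along(draws), function(i) {
    cand <- base_learner_spec(spec$name, draws[[i]])
    oof_predict(cand, X, y, n_folds = n_folds, seed = seed)$auc
  }, numeric(1))
  best <- which.max(aucs)  # which.max returns the first maximum
  out <- base_learner_spec(spec$name, draws[[best]])
  attr(out, "search") <- data.frame(
    iter = seq_len(n_iter), auc = aucs,
    config = vapply(draws, function(d)
      paste(names(d), unlist(d), sep = "=", collapse = ","), "")
  )
  out
}

#' Persist a stacking result
#'
#' Writes the out-of-fold columns as CSV (id, fold, one column per learner)
#' plus a JSON sidecar with per-learner AUCs, spec names and the seed.
#'
#' @param stack an `rbp_stack`.
#' @param csv_path,json_path output paths.
#' @return invisibly, the two paths.
#' @export
write_stack <- function(stack, csv_path, json_path) {
  df <- data.frame(id = rownames(stack$columns) %||% seq_len(nrow(stack$columns)),
                   fold = stack$fold_assignment, stack$columns,
                   check.names = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(per_learner_auc = as.list(stack$per_learner_auc),
         learners = names(stack$specs), n_folds = stack$n_folds,
         seed = stack$seed, oof = stack$oof),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
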