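#' Configuration of an end-to-end run
#'
#' The defaults reproduce the reference configuration: KPC encoding with
#' k = 1, 2 (420 columns), the four-learner stack (SVM, LR, LDA and the
#' leaf-wise histogram GBDT registered as LightGBM), correlation pruning at
#' |r| = 0.80 with the SVM/LDA pair allow-listed, and a three-branch
#' convolutional classifier (kernels 3/4/5, 64 filters, attention fusion,
#' patience 5, at most 50 epochs).
#'
#' @param ks KPC peptide lengths (default `c(1, 2)`).
#' @param learners ordered list of learner names or [base_learner_spec]s;
#'   order defines the ablation ladder D1..Dn.
#' @param threshold correlation-pruning cutoff.
#' @param allow_list pruning exemptions, see [select_features].
#' @param stack_folds out-of-fold stacking folds.
#' @param n_folds outer cross-validation folds.
#' @param val_fraction fraction of each training portion held out (stratified)
#'   as the early-stopping validation split.
#' @param use_attention,filters_per_kernel,kernel_sizes,dense_units,
#'   dropout_rate,learning_rate,batch_size,max_epochs,patience
#'   convolutional-classifier settings, see [textcnn_config].
#' @param oof use out-of-fold stacking columns (default) or naive in-sample
#'   columns.
#' @param seed integer master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(ks = c(1, 2),
                       learners = list("SVM", "LR", "LDA", "LightGBM"),
                       threshold = 0.80,
                       allow_list = list(c("SVM_Pred_Result",
                                           "LDA_Pred_Result")),
                       stack_folds = 5, n_folds = 5, val_fraction = 0.1,
                       kernel_sizes = c(3, 4, 5), filters_per_kernel = 64,
                       use_attention = TRUE, dense_units = 64,
                       dropout_rate = 0.5, learning_rate = 1e-3,
                       batch_size = 32, max_epochs = 50, patience = 5,
                       oof = TRUE, seed = 1) {
  structure(list(ks = ks, learners = learners, threshold = threshold,
                 allow_list = allow_list, stack_folds = stack_folds,
                 n_folds = n_folds, val_fraction = val_fraction,
                 kernel_sizes = kernel_sizes,
                 filters_per_kernel = filters_per_kernel,
                 use_attention = use_attention, dense_units = dense_units,
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, oof = oof, seed = seed),
            class = "run_config")
}

cnn_config_for <- function(config, input_dim, seed) {
  textcnn_config(input_dim = input_dim, kernel_sizes = config$kernel_sizes,
                 filters_per_kernel = config$filters_per_kernel,
                 use_attention = config$use_attention,
                 dense_units = config$dense_units,
                 dropout_rate = config$dropout_rate,
                 learning_rate = config$learning_rate,
                 batch_size = config$batch_size,
                 max_epochs = config$max_epochs, patience = config$patience,
                 seed = seed)
}

# core fit on a pre-encoded KPC matrix; shared by user API and CV closures
fit_encoded <- function(X_kpc, y, config, seed, prediction_columns = NULL) {
  if (is.null(prediction_columns)) {
    stack <- build_stack(X_kpc, y, specs = config$learners,
                         n_folds = config$stack_folds, seed = seed,
                         oof = config$oof)
    sel <- select_features(stack$columns, stack$per_learner_auc,
                           threshold = config$threshold,
                           allow_list = config$allow_list)
    X <- append_columns(X_kpc, stack$columns[, sel$kept, drop = FALSE])
  } else {
    # ablation path: fixed, pre-selected prediction columns
    stack <- attr(prediction_columns, "stack")
    sel <- NULL
    X <- append_columns(X_kpc, prediction_columns)
  }
  val <- stratified_folds(y, max(2L, round(1 / config$val_fraction)),
                          derive_seed(seed, 77L)) == 1L
  cnn <- build_improved_textcnn(
    cnn_config_for(config, ncol(X), derive_seed(seed, 99L)))
  cnn <- train_textcnn(cnn, X[!val, , drop = FALSE], y[!val],
                       X[val, , drop = FALSE], y[val])
  list(stack = stack, selection = sel, cnn = cnn, feature_names = colnames(X))
}

predict_encoded <- function(fit, X_kpc) {
  extra_names <- setdiff(fit$feature_names, colnames(X_kpc))
  if (length(extra_names)) {
    cols <- predict_stack(fit$stack, X_kpc)[, extra_names, drop = FALSE]
    X <- append_columns(X_kpc, cols)
  } else X <- X_kpc
  predict_textcnn(fit$cnn, X)
}

#' Fit the full prediction pipeline on a labeled sequence set
#'
#' Encodes the sequences (KPC), builds the out-of-fold stacking block,
#' prunes it by correlation/AUC, fuses the surviving prediction columns onto
#' the KPC matrix and trains the convolutional classifier with an internal
#' stratified early-stopping split.
#'
#' @param seqs a labeled [rbp_sequences] set.
#' @param config a [run_config].
#' @return an `rbp_bundle` with elements `stack`, `selection`, `cnn`,
#'   `feature_names`, `config`, `ks`.
#' @export
fit_rbp_pipeline <- function(seqs, config = run_config()) {
  y <- seqs$label
  if (anyNA(y)) stop("all sequences must be labeled for training")
  X_kpc <- encode_dataset(seqs, config$ks)
  fit <- fit_encoded(X_kpc, y, config, config$seed)
  structure(c(fit, list(config = config, ks = config$ks)),
            class = "rbp_bundle")
}

#' Predict RBP probabilities for new sequences
#'
#' Sequences shorter than the largest configured k are reported in the
#' `"rejects"` attribute and omitted from the results; the run continues.
#'
#' @param bundle an `rbp_bundle` from [fit_rbp_pipeline] (or [run_train]).
#' @param seqs an [rbp_sequences] set or path to a FASTA file.
#' @return data frame (id, probability, label) with per-sequence
#'   positive-class probability and the implied 0/1 label.
#' @export
predict_rbp <- function(bundle, seqs) {
  if (is.character(seqs)) seqs <- sanitize_sequences(read_fasta(seqs))
  ok <- nchar(seqs$residues) >= max(bundle$ks)
  rejects <- data.frame(id = seqs$id[!ok],
                        reason = rep("sequence_shorter_than_k", sum(!ok)))
  seqs <- seqs[ok, , drop = FALSE]
  if (nrow(seqs) == 0L) stop("no encodable sequences")
  X_kpc <- encode_dataset(seqs, bundle$ks)
  prob <- predict_encoded(bundle, X_kpc)
  out <- data.frame(id = seqs$id, probability = prob,
                    label = as.integer(prob >= 0.5))
  attr(out, "rejects") <- rejects
  out
}

#' Cross-validate and fit the full pipeline
#'
#' Runs leakage-safe k-fold cross-validation (the entire pipeline — stacking,
#' selection, classifier training — is refit per fold), then fits a final
#' bundle on all rows. When `out_dir` is given, metrics, the selection
#' report, the run manifest and the fitted bundle are persisted there.
#'
#' @param seqs a labeled [rbp_sequences] set.
#' @param config a [run_config].
#' @param out_dir optional output directory.
#' @return list with `cv` (a `cv_summary`) and `bundle` (an `rbp_bundle`).
#' @export
run_train <- function(seqs, config = run_config(), out_dir = NULL) {
  y <- seqs$label
  X_kpc <- encode_dataset(seqs, config$ks)
  pipeline <- function(X_tr, y_tr, X_te, seed) {
    fit <- fit_encoded(X_tr, y_tr, config, seed)
    predict_encoded(fit, X_te)
  }
  cv <- cross_validate(pipeline, X_kpc, y, n_folds = config$n_folds,
                       seed = config$seed)
  bundle <- fit_rbp_pipeline(seqs, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cv$summary, file.path(out_dir, "cv_summary.csv"),
                     row.names = FALSE)
    write_selection(bundle$selection, file.path(out_dir, "selection.json"))
    jsonlite::write_json(
      list(config = unclass(config), seed = config$seed,
           n_sequences = nrow(seqs),
           r_version = as.character(getRversion()),
           package_version = as.character(utils::packageVersion("rbpstack"))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    saveRDS(bundle, file.path(out_dir, "bundle.rds"))
  }
  list(cv = cv, bundle = bundle)
}

#' Ablation ladder over incremental prediction-column sets
#'
#' Evaluates feature sets D0..Dn under identical outer folds and seeds:
#' D0 is the bare KPC matrix (420 columns at default k), Di adds the first i
#' prediction columns in configured learner order (SVM, LR, LDA, LightGBM by
#' default, widths 421..424). Per-set mean ± sd of all metrics is reported
#' together with one-tailed paired t-tests (with Shapiro-Wilk normality
#' checks) comparing each set to its predecessor on per-fold ACC and MCC.
#' Identical fold partitions across sets make the paired tests valid.
#'
#' @param seqs a labeled [rbp_sequences] set.
#' @param config a [run_config]; `n_folds` controls the shared outer folds.
#' @return an `rbp_ablation` list: `metrics` (one row per feature set),
#'   `comparisons` (adjacent-set p-values), `per_fold` (ACC/MCC per fold and
#'   set), `widths`, `folds`.
#' @export
run_ablation <- function(seqs, config = run_config()) {
  y <- seqs$label
  X_kpc <- encode_dataset(seqs, config$ks)
  n_learners <- length(config$learners)
  set_names <- paste0("D", 0:n_learners)
  folds <- stratified_folds(y, config$n_folds, config$seed)
  fold_res <- lapply(seq_len(config$n_folds), function(f) {
    tr <- folds != f
    seed_f <- derive_seed(config$seed, f)
    stack <- build_stack(X_kpc[tr, , drop = FALSE], y[tr],
                         specs = config$learners,
                         n_folds = config$stack_folds, seed = seed_f,
                         oof = config$oof)
    te_cols <- predict_stack(stack, X_kpc[!tr, , drop = FALSE])
    per_set <- vector("list", n_learners + 1)
    for (i in 0:n_learners) {
      tr_extra <- stack$columns[, seq_len(i), drop = FALSE]
      attr(tr_extra, "stack") <- stack
      fit <- fit_encoded(X_kpc[tr, , drop = FALSE], y[tr], config, seed_f,
                         prediction_columns = tr_extra)
      X_te <- append_columns(X_kpc[!tr, , drop = FALSE],
                             te_cols[, seq_len(i), drop = FALSE])
      prob <- predict_textcnn(fit$cnn, X_te)
      per_set[[i + 1]] <- list(metrics = evaluate_predictions(y[!tr], prob),
                               width = ncol(X_te))
    }
    per_set
  })
  widths <- vapply(fold_res[[1]], `[[`, 0, "width")
  metric_rows <- lapply(seq_along(set_names), function(i) {
    s <- summarize_folds(lapply(fold_res, function(fr) fr[[i]]$metrics))
    df <- data.frame(feature_set = set_names[i], width = widths[i])
    for (j in seq_len(nrow(s))) {
      df[[paste0(s$metric[j], "_mean")]] <- s$mean[j]
      df[[paste0(s$metric[j], "_sd")]] <- s$sd[j]
    }
    df
  })
  per_fold <- lapply(c(ACC = "ACC", MCC = "MCC"), function(m)
    vapply(seq_along(set_names), function(i)
      vapply(fold_res, function(fr) as.numeric(fr[[i]]$metrics[[m]]),
             numeric(1)),
      numeric(config$n_folds)))
  # exactly tied fold vectors (possible when a set saturates the benchmark)
  # make the paired test undefined; report NA rather than fabricating a p
  cmp_or_na <- function(a, b) {
    tryCatch(compare_feature_sets(a, b),
             error = function(e) list(p_value = NA_real_,
                                      shapiro_p_diff = NA_real_))
  }
  comparisons <- do.call(rbind, lapply(seq_len(n_learners), function(i) {
    cmp_acc <- cmp_or_na(per_fold$ACC[, i], per_fold$ACC[, i + 1])
    cmp_mcc <- cmp_or_na(per_fold$MCC[, i], per_fold$MCC[, i + 1])
    data.frame(comparison = paste(set_names[i + 1], "vs.", set_names[i]),
               p_value_ACC = cmp_acc$p_value, p_value_MCC = cmp_mcc$p_value,
               shapiro_p_ACC = cmp_acc$shapiro_p_diff,
               shapiro_p_MCC = cmp_mcc$shapiro_p_diff)
  }))
  structure(list(metrics = do.call(rbind, metric_rows),
                 comparisons = comparisons, per_fold = per_fold,
                 widths = widths, folds = folds, seed = config$seed),
            class = "rbp_ablation")
}

#' @export
print.rbp_ablation <- function(x, ...) {
  cat("Ablation over incremental prediction-column sets\n")
  print(x$metrics[, c("feature_set", "width", "ACC_mean", "ACC_sd",
                      "MCC_mean", "MCC_sd")], row.names = FALSE)
  cat("\nAdjacent-set paired one-tailed t-tests:\n")
  print(x$comparisons[, c("comparison", "p_value_ACC", "p_value_MCC")],
        row.names = FALSE)
  invisible(x)
}
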