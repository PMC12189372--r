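#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred binary vectors (0/1) of equal length.
#' @return list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(!y_true %in% 0:1) || any(!y_pred %in% 0:1))
    stop("inputs must be binary 0/1")
  list(TP = sum(y_true == 1L & y_pred == 1L),
       TN = sum(y_true == 0L & y_pred == 0L),
       FP = sum(y_true == 0L & y_pred == 1L),
       FN = sum(y_true == 1L & y_pred == 0L))
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney statistic: the probability that a random positive
#' outranks a random negative, with ties counted half. Equals trapezoidal
#' integration of the ROC curve.
#'
#' @param y binary labels.
#' @param scores real-valued scores (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(y, scores) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: single-class labels")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

ratio_pct <- function(num, den, zero_terms) {
  if (den == 0)
    structure(NA_real_, undefined = paste0("zero denominator (",
                                           zero_terms, ")"))
  else 100 * num / den
}

#' Confusion-derived performance metrics
#'
#' ACC, SN (sensitivity), SP (specificity), Precision, F1 and MCC from the
#' four confusion cells, reported as percentages (MCC in `[-100, 100]`);
#' AUC (as a percentage) when scores are supplied. Undefined ratios (zero
#' denominators, e.g. a fold with no predicted positives) are returned as
#' `NA` carrying an `"undefined"` attribute naming the zero term — never a
#' silent 0. `averaging = "weighted"` replaces F1 and Precision by their
#' support-weighted two-class averages (the convention used for
#' independent-set reporting).
#'
#' @param counts a list with `TP`, `TN`, `FP`, `FN` (see [confusion]).
#' @param scores optional real scores for AUC; requires `y_true`.
#' @param y_true labels aligned with `scores` (only needed for AUC).
#' @param averaging `"binary"` (default) or `"weighted"`.
#' @return a named list of metrics (class `metric_set`).
#' @export
metrics <- function(counts, scores = NULL, y_true = NULL,
                    averaging = c("binary", "weighted")) {
  averaging <- match.arg(averaging)
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  n <- TP + TN + FP + FN
  if (n == 0) stop("empty confusion counts")
  out <- list(ACC = 100 * (TP + TN) / n)
  out$SN <- ratio_pct(TP, TP + FN, "TP+FN")
  out$SP <- ratio_pct(TN, TN + FP, "TN+FP")
  if (averaging == "binary") {
    out$Precision <- ratio_pct(TP, TP + FP, "TP+FP")
    out$F1 <- ratio_pct(2 * TP, 2 * TP + FP + FN, "2TP+FP+FN")
  } else {
    # support-weighted average of the per-class precision / F1
    prec_pos <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
    prec_neg <- if (TN + FN > 0) TN / (TN + FN) else NA_real_
    rec_pos <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    rec_neg <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    f1_pos <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_
    f1_neg <- if (2 * TN + FN + FP > 0) 2 * TN / (2 * TN + FN + FP) else NA_real_
    w_pos <- (TP + FN) / n; w_neg <- (TN + FP) / n
    out$Precision <- 100 * (w_pos * prec_pos + w_neg * prec_neg)
    out$F1 <- 100 * (w_pos * f1_pos + w_neg * f1_neg)
  }
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  out$MCC <- if (mcc_den == 0)
    structure(NA_real_, undefined = "zero MCC denominator")
  else 100 * (TP * TN - FP * FN) / mcc_den
  if (!is.null(scores)) {
    if (is.null(y_true)) stop("y_true required to compute AUC from scores")
    out$AUC <- 100 * auc_score(y_true, scores)
  }
  structure(out, class = "metric_set")
}

#' Evaluate binary predictions in one call
#'
#' @param y_true binary labels.
#' @param prob positive-class probabilities; labels are `prob >= 0.5`.
#' @param averaging see [metrics].
#' @return a `metric_set`.
#' @export
evaluate_predictions <- function(y_true, prob, averaging = "binary") {
  metrics(confusion(y_true, as.integer(prob >= 0.5)), scores = prob,
          y_true = y_true, averaging = averaging)
}

#' Aggregate per-fold metrics into mean and spread
#'
#' The default spread is the population standard deviation (ddof = 0),
#' the convention that reproduces "mean ± sd" fold summaries of this
#' pipeline; sample sd (ddof = 1) is available via `sd_type`.
#'
#' @param fold_metrics list of `metric_set`s (or a numeric vector for a
#'   single metric).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return data frame with one row per metric: mean and sd.
#' @export
summarize_folds <- function(fold_metrics, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sd_fun <- if (sd_type == "population") pop_sd else stats::sd
  if (is.numeric(fold_metrics))
    return(data.frame(metric = "value", mean = mean(fold_metrics),
                      sd = sd_fun(fold_metrics)))
  keys <- names(fold_metrics[[1]])
  vals <- lapply(keys, function(k)
    vapply(fold_metrics, function(m) as.numeric(m[[k]]), numeric(1)))
  data.frame(metric = keys,
             mean = vapply(vals, function(v) mean(v, na.rm = TRUE), 0),
             sd = vapply(vals, function(v) sd_fun(v[!is.na(v)]), 0))
}

#' Stratified k-fold cross-validation of an arbitrary pipeline
#'
#' The entire `pipeline` (e.g. stacking, selection and deep-model training)
#' is refit from scratch on each fold's training portion and scored on the
#' held-out portion, so no test row influences any fitted component of its
#' own fold.
#'
#' @param pipeline function `(X_train, y_train, X_test, seed)` returning
#'   positive-class probabilities for `X_test`. `X_*` may be any row-subset
#'   type (matrix or `rbp_sequences`).
#' @param X inputs with one row per sample.
#' @param y binary labels.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the fold split and per-fold refits.
#' @param averaging see [metrics].
#' @return a `cv_summary`: `fold_metrics` (list of `metric_set`),
#'   `summary` (mean ± sd table), `folds`, `predictions`, `n_folds`, `seed`.
#' @export
cross_validate <- function(pipeline, X, y, n_folds = 5, seed = 1,
                           averaging = "binary") {
  y <- as.integer(y)
  folds <- stratified_folds(y, n_folds, seed)
  prob <- numeric(length(y))
  fold_metrics <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    p <- pipeline(X[tr, , drop = FALSE], y[tr], X[!tr, , drop = FALSE],
                  seed = derive_seed(seed, f))
    prob[!tr] <- p
    fold_metrics[[f]] <- evaluate_predictions(y[!tr], p, averaging)
  }
  structure(list(fold_metrics = fold_metrics,
                 summary = summarize_folds(fold_metrics),
                 folds = folds, predictions = prob, n_folds = n_folds,
                 seed = seed),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(x$n_folds, "-fold cross-validation (seed ", x$seed, ")\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %6.2f +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Paired one-tailed comparison of two feature sets
#'
#' Tests whether feature set `b` outperforms `a` on matched folds: a paired
#' t-test with alternative "b > a", preceded by Shapiro-Wilk normality
#' checks on the paired differences and on each sample. Identical vectors
#' (zero-variance differences) are an explicit undefined-test error.
#'
#' @param per_fold_a,per_fold_b equal-length numeric vectors of per-fold
#'   metrics (same folds, n >= 3).
#' @return list with `p_value` (one-tailed paired t), `t_statistic`,
#'   `shapiro_p_diff`, `shapiro_p_a`, `shapiro_p_b`.
#' @export
compare_feature_sets <- function(per_fold_a, per_fold_b) {
  if (length(per_fold_a) != length(per_fold_b)) stop("length mismatch")
  if (length(per_fold_a) < 3L) stop("need at least 3 paired folds")
  d <- per_fold_b - per_fold_a
  if (stats::sd(d) == 0)
    stop("undefined test: paired differences have zero variance")
  sw <- function(x) if (stats::sd(x) == 0) NA_real_
    else stats::shapiro.test(x)$p.value
  tt <- stats::t.test(per_fold_b, per_fold_a, paired = TRUE,
                      alternative = "greater")
  list(p_value = tt$p.value, t_statistic = unname(tt$statistic),
       shapiro_p_diff = sw(d), shapiro_p_a = sw(per_fold_a),
       shapiro_p_b = sw(per_fold_b))
}

#' ROC curve points
#'
#' @param y binary labels.
#' @param scores real scores.
#' @return data frame (threshold, fpr, tpr) suitable for CSV export.
#' @export
roc_points <- function(y, scores) {
  y <- as.integer(y)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  tpr <- cumsum(ys) / sum(ys)
  fpr <- cumsum(1 - ys) / sum(1 - ys)
  data.frame(threshold = c(Inf, scores[ord]), fpr = c(0, fpr),
             tpr = c(0, tpr))
}
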