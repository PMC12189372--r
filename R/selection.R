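#' Pearson correlation coefficient
#'
#' Sample Pearson r = Cov(x, y) / (sd(x) sd(y)). Zero variance in either
#' vector is an explicit error, never a silent 0.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in ",
         if (stats::sd(x) == 0) "x" else "y")
  stats::cor(x, y)
}

#' All pairwise correlations among a set of columns
#'
#' Computes the complete symmetric table of Pearson coefficients for the
#' requested columns. Zero-variance columns are excluded from the table and
#' reported in `attr(, "zero_variance")` (never a silent drop). The table is
#' sorted by `|r|` descending, so `head(...)` reproduces a "top-N most
#' correlated pairs" view.
#'
#' @param X feature matrix.
#' @param subset column names to correlate (default: all).
#' @return data frame (feature_a, feature_b, r), one row per unordered pair.
#' @export
correlation_table <- function(X, subset = colnames(X)) {
  missing_cols <- setdiff(subset, colnames(X))
  if (length(missing_cols))
    stop("columns not in matrix: ", paste(missing_cols, collapse = ", "))
  M <- X[, subset, drop = FALSE]
  sds <- apply(M, 2, stats::sd)
  zero <- colnames(M)[sds == 0]
  M <- M[, sds > 0, drop = FALSE]
  nm <- colnames(M)
  if (length(nm) < 2L) {
    out <- data.frame(feature_a = character(0), feature_b = character(0),
                      r = numeric(0))
  } else {
    cm <- stats::cor(M)
    pairs <- which(upper.tri(cm), arr.ind = TRUE)
    out <- data.frame(feature_a = nm[pairs[, 1]], feature_b = nm[pairs[, 2]],
                      r = cm[pairs], stringsAsFactors = FALSE)
    out <- out[order(-abs(out$r), out$feature_a, out$feature_b), ]
    rownames(out) <- NULL
  }
  attr(out, "zero_variance") <- zero
  out
}

#' Correlation-prune candidate feature columns
#'
#' Resolves every pair with `|r|` above `threshold` by dropping the member
#' with the lower single-feature AUC, unless the pair is allow-listed. Pairs
#' are processed in deterministic order (`|r|` descending, ties by name);
#' a feature already dropped is skipped in later pairs. The default
#' allow-list exempts the SVM/LDA prediction pair, whose complementary
#' decision mechanisms justify keeping both despite high correlation.
#'
#' @param candidates matrix of candidate columns (typically the
#'   `<name>_Pred_Result` block).
#' @param auc named vector mapping every candidate column to its AUC.
#' @param threshold absolute-r cutoff (default 0.80).
#' @param allow_list list of length-2 character vectors naming exempt pairs.
#' @return an `rbp_selection` report: `threshold`, `entries` (full
#'   correlation table), `dropped` (feature, reason, competing feature, r,
#'   auc_dropped, auc_kept), `kept`, `allow_list`, `zero_variance`.
#' @export
select_features <- function(candidates, auc, threshold = 0.80,
                            allow_list = list(c("SVM_Pred_Result",
                                                "LDA_Pred_Result"))) {
  nm <- colnames(candidates)
  missing_auc <- setdiff(nm, names(auc))
  if (length(missing_auc))
    stop("missing AUC for candidate(s): ", paste(missing_auc, collapse = ", "))
  entries <- correlation_table(candidates)
  allow_key <- vapply(allow_list, function(p) paste(sort(p), collapse = "\r"), "")
  dropped <- data.frame(feature = character(0), reason = character(0),
                        competing_feature = character(0), r = numeric(0),
                        auc_dropped = numeric(0), auc_kept = numeric(0),
                        stringsAsFactors = FALSE)
  out <- nm
  for (i in seq_len(nrow(entries))) {
    a <- entries$feature_a[i]; b <- entries$feature_b[i]; r <- entries$r[i]
    if (abs(r) <= threshold) break  # sorted by |r| descending
    if (!(a %in% out) || !(b %in% out)) next
    if (paste(sort(c(a, b)), collapse = "\r") %in% allow_key) next
    lose <- if (auc[[a]] < auc[[b]]) a else b
    keep <- setdiff(c(a, b), lose)
    out <- setdiff(out, lose)
    dropped <- rbind(dropped, data.frame(
      feature = lose, reason = "correlated_lower_auc",
      competing_feature = keep, r = r,
      auc_dropped = auc[[lose]], auc_kept = auc[[keep]],
      stringsAsFactors = FALSE))
  }
  structure(list(threshold = threshold, entries = entries, dropped = dropped,
                 kept = out, allow_list = allow_list,
                 zero_variance = attr(entries, "zero_variance")),
            class = "rbp_selection")
}

#' @export
print.rbp_selection <- function(x, ...) {
  cat("Correlation-based feature selection (|r| threshold ", x$threshold,
      ")\n", sep = "")
  cat("  kept:    ", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("  dropped: %s (r=%.2f with %s; AUC %.3f < %.3f)\n",
                  x$dropped$feature[i], x$dropped$r[i],
                  x$dropped$competing_feature[i], x$dropped$auc_dropped[i],
                  x$dropped$auc_kept[i]))
  } else cat("  dropped: none\n")
  invisible(x)
}

#' Write a selection report as JSON (and the correlation table as CSV)
#'
#' @param report an `rbp_selection`.
#' @param json_path JSON output path.
#' @param csv_path optional CSV path for the full correlation table.
#' @return invisibly, the paths written.
#' @export
write_selection <- function(report, json_path, csv_path = NULL) {
  jsonlite::write_json(
    list(threshold = report$threshold, kept = report$kept,
         dropped = report$dropped, allow_list = report$allow_list,
         zero_variance = report$zero_variance),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(report$entries, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
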