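test_that("confusion tallies the four cells and validates input", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cc, list(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  cc2 <- confusion(rep(c(1, 0), c(6, 4)), rep(c(1, 0), c(6, 4)))
  expect_equal(cc2, list(TP = 6L, TN = 4L, FP = 0L, FN = 0L))
  cc3 <- confusion(c(1, 0), c(1, 1))
  expect_equal(cc3, list(TP = 1L, TN = 0L, FP = 1L, FN = 0L))
  expect_error(confusion(c(1, 2), c(0, 1)), "binary")
  expect_error(confusion(1, c(0, 1)), "length")
})

test_that("metrics evaluate the standard formulas on a worked example", {
  m <- metrics(list(TP = 50, TN = 40, FP = 10, FN = 0))
  expect_equal(m$ACC, 90)
  expect_equal(m$SN, 100)
  expect_equal(m$SP, 80)
  expect_equal(m$Precision, 100 * 50 / 60, tolerance = 1e-10)
  expect_equal(m$F1, 100 * 100 / 110, tolerance = 1e-10)
  expect_equal(m$MCC, 100 * 2000 / sqrt(60 * 50 * 50 * 40), tolerance = 1e-10)

  perfect <- metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(perfect$ACC, 100)
  expect_equal(perfect$MCC, 100)

  chance <- metrics(list(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(chance$MCC, 0)
  expect_error(metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("zero-denominator metrics are undefined with a named reason, not 0", {
  m <- metrics(list(TP = 0, TN = 10, FP = 0, FN = 5))
  expect_true(is.na(m$Precision))
  expect_match(attr(m$Precision, "undefined"), "TP\\+FP")
  expect_true(is.na(m$MCC))
  expect_false(is.na(m$ACC))
})

test_that("metrics match a brute-force oracle over random prediction vectors", {
  set.seed(601)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    y <- rbinom(n, 1, 0.5)
    p <- rbinom(n, 1, 0.5)
    got <- metrics(confusion(y, p))
    want <- metric_oracle(y, p)
    for (k in c("ACC", "SN", "SP", "Precision")) {
      if (is.na(want[[k]])) expect_true(is.na(got[[k]]))
      else expect_identical(as.numeric(got[[k]]), want[[k]])
    }
    for (k in c("MCC", "F1")) {
      if (is.na(want[[k]])) expect_true(is.na(got[[k]]))
      else expect_equal(as.numeric(got[[k]]), want[[k]], tolerance = 1e-10)
    }
  }
})

test_that("weighted averaging reproduces support-weighted per-class scores", {
  # 8 positives, 2 negatives: weights 0.8 / 0.2
  cc <- list(TP = 6, FN = 2, TN = 1, FP = 1)
  m <- metrics(cc, averaging = "weighted")
  prec_pos <- 6 / 7; prec_neg <- 1 / 3
  f1_pos <- 12 / (12 + 1 + 2); f1_neg <- 2 / (2 + 2 + 1)
  expect_equal(m$Precision, 100 * (0.8 * prec_pos + 0.2 * prec_neg),
               tolerance = 1e-10)
  expect_equal(m$F1, 100 * (0.8 * f1_pos + 0.2 * f1_neg), tolerance = 1e-10)
  # binary mode differs
  expect_false(isTRUE(all.equal(metrics(cc)$F1, m$F1)))
})

test_that("AUC is rank-based: monotone transforms leave it unchanged", {
  set.seed(602)
  y <- rbinom(60, 1, 0.5)
  s <- rnorm(60)
  a <- auc_score(y, s)
  expect_equal(auc_score(y, 10 * s + 3), a)
  expect_equal(auc_score(y, plogis(s)), a)
  expect_equal(auc_score(y, rank(s)), a)
  expect_error(auc_score(rep(1, 10), rnorm(10)), "single-class")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(603)
  for (i in 1:20) {
    y <- rbinom(50, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(50) + y
    ref <- as.numeric(suppressMessages(pROC::auc(y, s)))
    expect_equal(auc_score(y, s), ref, tolerance = 1e-10)
  }
})

test_that("fold aggregation uses population sd by default, sample sd on request", {
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  s <- summarize_folds(x)
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 2)           # population sd of this classic example
  s2 <- summarize_folds(x, sd_type = "sample")
  expect_equal(s2$sd, stats::sd(x))
})

test_that("cross_validate partitions samples exactly once and is reproducible", {
  set.seed(604)
  n <- 100
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 5), n)
  X[y == 1, 1] <- X[y == 1, 1] + 3
  colnames(X) <- paste0("f", 1:5)
  ridge_pipeline <- function(X_tr, y_tr, X_te, seed) {
    fit <- glmnet::glmnet(X_tr, y_tr, family = "binomial", alpha = 0,
                          lambda = 0.05)
    as.numeric(stats::predict(fit, X_te, type = "response"))
  }
  cv <- cross_validate(ridge_pipeline, X, y, n_folds = 5, seed = 9)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(tabulate(cv$folds), rep(20, 5))
  expect_length(cv$fold_metrics, 5)
  expect_gte(cv$summary$mean[cv$summary$metric == "ACC"], 80)
  cv2 <- cross_validate(ridge_pipeline, X, y, n_folds = 5, seed = 9)
  expect_identical(cv$predictions, cv2$predictions)
  expect_identical(cv$summary, cv2$summary)
})

test_that("paired one-tailed comparisons detect a shifted feature set", {
  set.seed(605)
  a <- c(80, 82, 81, 79, 83, 80.5, 81.5, 82.5, 80.2, 79.8)
  b <- a + 5 + rnorm(10, 0, 0.4)
  cmp <- compare_feature_sets(a, b)
  expect_lt(cmp$p_value, 0.05)
  expect_gt(cmp$t_statistic, 0)
  expect_true(cmp$shapiro_p_diff > 0 && cmp$shapiro_p_diff <= 1)

  shuffled <- sample(a)
  cmp2 <- compare_feature_sets(a, shuffled)
  expect_true(cmp2$p_value > 0 && cmp2$p_value < 1)

  expect_error(compare_feature_sets(a, a), "zero variance")
  expect_error(compare_feature_sets(a[1:2], a[1:2] + 1), "at least 3")
})

test_that("roc_points trace the empirical ROC from (0,0) to (1,1)", {
  y <- c(1, 1, 0, 0, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  pts <- roc_points(y, s)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})
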