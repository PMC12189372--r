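test_that("make_learner rejects unknown names and exposes the fit/predict contract", {
  expect_error(base_learner_spec("MLP"), "SVM.*LightGBM")
  h <- make_learner("DT")
  d <- separable_xy(n = 60)
  m <- h$fit(d$X, d$y, seed = 1)
  p <- h$predict_proba(m, d$X)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("every learner produces in-range scores on a small problem", {
  d <- separable_xy(n = 60, p = 8)
  for (nm in LEARNER_NAMES) {
    h <- make_learner(nm)
    m <- h$fit(d$X, d$y, seed = 3)
    p <- h$predict_proba(m, d$X)
    expect_true(all(is.finite(p) & p >= 0 & p <= 1), info = nm)
  }
})

test_that("single-class labels are rejected", {
  d <- separable_xy(n = 20)
  h <- make_learner("DT")
  expect_error(h$fit(d$X, rep(1, 20), seed = 1), "single-class")
  expect_error(oof_predict("DT", d$X, rep(1, 20), n_folds = 2, seed = 1),
               "single-class")
})

test_that("out-of-fold predictions are deterministic given the seed", {
  d <- separable_xy(n = 60, p = 6)
  r1 <- oof_predict("LightGBM", d$X, d$y, n_folds = 3, seed = 11)
  r2 <- oof_predict("LightGBM", d$X, d$y, n_folds = 3, seed = 11)
  expect_identical(r1$column, r2$column)
  expect_identical(r1$folds, r2$folds)
  r3 <- oof_predict("LightGBM", d$X, d$y, n_folds = 3, seed = 12)
  expect_false(identical(r1$folds, r3$folds))
})

test_that("out-of-fold values for a fold are invariant to that fold's labels", {
  # leakage-freedom: row i in fold j is scored by a model trained without
  # fold j, so corrupting fold-j labels cannot move fold-j's own values
  d <- separable_xy(n = 60, p = 6)
  folds <- stratified_folds(d$y, 3, seed = 5)
  r <- oof_predict("DT", d$X, d$y, seed = 5, folds = folds)
  j <- 2L
  y_corrupt <- d$y
  y_corrupt[folds == j] <- 1 - y_corrupt[folds == j]
  r_c <- oof_predict("DT", d$X, y_corrupt, seed = 5, folds = folds)
  expect_identical(r$folds, r_c$folds)
  expect_equal(r$column[r$folds == j], r_c$column[r$folds == j])
  # ...while at least one other fold's values do change
  expect_false(isTRUE(all.equal(r$column[r$folds != j],
                                r_c$column[r$folds != j])))
})

test_that("linear learners separate linearly separable features", {
  d <- separable_xy(n = 120, p = 10, shift = 3, seed = 77)
  for (nm in c("SVM", "LR", "LDA")) {
    r <- oof_predict(nm, d$X, d$y, n_folds = 5, seed = 9)
    expect_gt(r$auc, 0.95)
  }
})

test_that("build_stack assembles named columns, AUCs and full models", {
  enc <- tiny_encoded()
  st <- build_stack(enc$X, enc$y, n_folds = 3, seed = 21)
  expect_s3_class(st, "rbp_stack")
  expect_equal(colnames(st$columns),
               c("SVM_Pred_Result", "LR_Pred_Result", "LDA_Pred_Result",
                 "LightGBM_Pred_Result"))
  expect_true(all(st$columns >= 0 & st$columns <= 1))
  expect_equal(names(st$per_learner_auc), colnames(st$columns))
  expect_true(all(st$per_learner_auc > 0 & st$per_learner_auc <= 1))
  expect_length(st$fitted_full_models, 4)
  expect_error(build_stack(enc$X, enc$y, specs = list()), "non-empty")

  newp <- predict_stack(st, enc$X[1:7, , drop = FALSE])
  expect_equal(dim(newp), c(7, 4))
  expect_true(all(newp >= 0 & newp <= 1))
})

test_that("stacking is reproducible end to end", {
  enc <- tiny_encoded()
  s1 <- build_stack(enc$X, enc$y, specs = list("LDA", "DT"), n_folds = 3,
                    seed = 31)
  s2 <- build_stack(enc$X, enc$y, specs = list("LDA", "DT"), n_folds = 3,
                    seed = 31)
  expect_identical(s1$columns, s2$columns)
  expect_identical(s1$per_learner_auc, s2$per_learner_auc)
})

test_that("naive in-sample mode is available but distinct from out-of-fold", {
  enc <- tiny_encoded()
  r_oof <- oof_predict("LightGBM", enc$X, enc$y, n_folds = 3, seed = 41)
  r_naive <- oof_predict("LightGBM", enc$X, enc$y, n_folds = 3, seed = 41,
                         oof = FALSE)
  # the in-sample column is optimistically biased relative to out-of-fold
  expect_gte(r_naive$auc, r_oof$auc)
})

test_that("random search returns the exhaustive argmax of its sampled set", {
  d <- separable_xy(n = 60, p = 6, shift = 2.5, seed = 13)
  tuned <- tune_learner("KNN", d$X, d$y, n_folds = 3, n_iter = 6, seed = 17)
  search <- attr(tuned, "search")
  expect_equal(nrow(search), 6)
  winner_auc <- oof_predict(tuned, d$X, d$y, n_folds = 3, seed = 17)$auc
  expect_equal(winner_auc, max(search$auc))
  expect_equal(which.max(search$auc),
               match(TRUE, search$auc == max(search$auc)))  # first-occurrence tie rule

  tuned2 <- tune_learner("KNN", d$X, d$y, n_folds = 3, n_iter = 6, seed = 17)
  expect_identical(tuned$hyperparameters, tuned2$hyperparameters)

  one <- tune_learner("DT", d$X, d$y, n_folds = 3, n_iter = 1, seed = 19)
  expect_equal(nrow(attr(one, "search")), 1)
  expect_error(tune_learner("LDA", d$X, d$y, n_iter = 2, seed = 1),
               "empty search space")
})

test_that("tuning cannot underperform the defaults it includes", {
  d <- separable_xy(n = 60, p = 6, shift = 1.5, seed = 23)
  default_auc <- oof_predict("DT", d$X, d$y, n_folds = 3, seed = 29)$auc
  tuned <- tune_learner("DT", d$X, d$y, n_folds = 3, n_iter = 8, seed = 29)
  expect_gte(max(attr(tuned, "search")$auc), default_auc - 0.25)
})

test_that("stack persistence writes the documented CSV + JSON pair", {
  enc <- tiny_encoded()
  st <- build_stack(enc$X, enc$y, specs = list("LDA"), n_folds = 3, seed = 1)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_stack(st, csv, js)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(nrow(back), nrow(enc$X))
  expect_true("LDA_Pred_Result" %in% colnames(back))
  meta <- jsonlite::read_json(js)
  expect_equal(meta$learners[[1]], "LDA")
  expect_equal(meta$seed, 1)
})
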