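#' The eleven candidate base learners
#'
#' Names accepted by [base_learner_spec]: RBF-kernel SVM, ridge-regularised
#' logistic regression (LR), linear discriminant analysis (LDA), a leaf-wise
#' histogram gradient-boosted tree model (registered as "LightGBM", the
#' algorithm family that name denotes), depth-wise extreme gradient boosting
#' (XGB), random forest (RF), classic gradient-boosted decision trees
#' (GBDT), k-nearest neighbours (KNN), a single decision tree (DT), naive
#' Bayes (NB), and bagged decision trees (BG).
#'
#' @export
LEARNER_NAMES <- c("SVM", "LR", "LDA", "LightGBM", "XGB", "RF", "GBDT",
                   "KNN", "DT", "NB", "BG")

# learners whose inputs are standardised (zero mean / unit variance, fit on
# training rows only); tree ensembles consume raw frequencies
SCALED_LEARNERS <- c("SVM", "LR", "LDA", "KNN")

#' Describe a base learner
#'
#' @param name one of [LEARNER_NAMES].
#' @param hyperparameters named list overriding the learner's defaults.
#' @return a `base_learner_spec` object.
#' @export
base_learner_spec <- function(name, hyperparameters = list()) {
  if (!name %in% LEARNER_NAMES)
    stop("unknown learner '", name, "'; valid names: ",
         paste(LEARNER_NAMES, collapse = ", "))
  structure(list(name = name, hyperparameters = hyperparameters,
                 needs_scaling = name %in% SCALED_LEARNERS),
            class = "base_learner_spec")
}

as_learner_spec <- function(x) {
  if (inherits(x, "base_learner_spec")) x else base_learner_spec(x)
}

fit_scaler <- function(X) {
  ctr <- colMeans(X)
  sc <- apply(X, 2, stats::sd)
  sc[sc == 0 | !is.finite(sc)] <- 1
  list(center = ctr, scale = sc)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

hp <- function(spec, key, default) {
  v <- spec$hyperparameters[[key]]
  if (is.null(v)) default else v
}

#' Instantiate a trainable classifier
#'
#' Returns a handle with `fit(X, y, seed)` and `predict_proba(model, X)`
#' (positive-class score in `[0, 1]`), deterministic given the seed. Inputs
#' for SVM/LR/LDA/KNN are standardised internally using statistics of the
#' training rows only.
#'
#' @param spec a [base_learner_spec] or learner name.
#' @return a `learner_handle` list with elements `spec`, `fit`,
#'   `predict_proba`.
#' @export
make_learner <- function(spec) {
  spec <- as_learner_spec(spec)
  fit_core <- learner_fit_fun(spec)
  predict_core <- learner_predict_fun(spec)
  fit <- function(X, y, seed = 1) {
    y <- as.integer(y)
    if (length(unique(y)) < 2L) stop("training labels are single-class")
    scaler <- NULL
    if (spec$needs_scaling) {
      scaler <- fit_scaler(X)
      X <- apply_scaler(scaler, X)
    }
    structure(list(core = fit_core(X, y, seed), scaler = scaler, spec = spec),
              class = "rbp_learner_fit")
  }
  predict_proba <- function(model, X) {
    if (!is.null(model$scaler)) X <- apply_scaler(model$scaler, X)
    p <- predict_core(model$core, X)
    pmin(pmax(as.numeric(p), 0), 1)
  }
  structure(list(spec = spec, fit = fit, predict_proba = predict_proba),
            class = "learner_handle")
}

learner_fit_fun <- function(spec) {
  name <- spec$name
  switch(name,
    SVM = function(X, y, seed) {
      set.seed(seed)
      m <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                      cost = hp(spec, "cost", 1),
                      gamma = hp(spec, "gamma", 1 / ncol(X)),
                      scale = FALSE)
      # Platt calibration on the decision values libsvm already computed
      # for the training rows during fitting
      d <- as.numeric(m$decision.values)
      platt <- suppressWarnings(
        stats::glm(y ~ d, family = stats::binomial()))
      list(svm = m, platt = stats::coef(platt))
    },
    LR = function(X, y, seed) {
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = hp(spec, "lambda", 0.01), standardize = FALSE)
    },
    LDA = function(X, y, seed) {
      keep <- apply(X, 2, stats::sd) > 0
      m <- suppressWarnings(
        MASS::lda(X[, keep, drop = FALSE], grouping = factor(y, c(0, 1))))
      list(lda = m, keep = keep)
    },
    LightGBM = function(X, y, seed) {
      xgb_fit(X, y, seed, nrounds = hp(spec, "nrounds", 100),
              params = list(objective = "binary:logistic",
                            tree_method = "hist", grow_policy = "lossguide",
                            max_leaves = hp(spec, "max_leaves", 31),
                            max_depth = 0,
                            eta = hp(spec, "eta", 0.1),
                            min_child_weight = hp(spec, "min_child_weight", 1)))
    },
    XGB = function(X, y, seed) {
      xgb_fit(X, y, seed, nrounds = hp(spec, "nrounds", 100),
              params = list(objective = "binary:logistic",
                            tree_method = "hist",
                            max_depth = hp(spec, "max_depth", 6),
                            eta = hp(spec, "eta", 0.3)))
    },
    GBDT = function(X, y, seed) {
      xgb_fit(X, y, seed, nrounds = hp(spec, "nrounds", 100),
              params = list(objective = "binary:logistic",
                            tree_method = "hist",
                            max_depth = hp(spec, "max_depth", 3),
                            eta = hp(spec, "eta", 0.1)))
    },
    RF = function(X, y, seed) {
      ranger::ranger(y = factor(y, c(0, 1)), x = as.data.frame(X),
                     probability = TRUE,
                     num.trees = hp(spec, "num.trees", 500),
                     mtry = hp(spec, "mtry", NULL),
                     seed = seed, num.threads = 1)
    },
    KNN = function(X, y, seed) {
      list(X = X, y = factor(y, c(0, 1)), k = hp(spec, "k", 5), seed = seed)
    },
    DT = function(X, y, seed) {
      df <- data.frame(.y = factor(y, c(0, 1)), X, check.names = FALSE)
      rpart::rpart(.y ~ ., df, method = "class",
                   control = rpart::rpart.control(
                     cp = hp(spec, "cp", 0.01),
                     maxdepth = hp(spec, "maxdepth", 30)))
    },
    NB = function(X, y, seed) {
      e1071::naiveBayes(as.data.frame(X), factor(y, c(0, 1)),
                        laplace = hp(spec, "laplace", 0))
    },
    BG = function(X, y, seed) {
      n_bags <- hp(spec, "n_bags", 25)
      set.seed(seed)
      df <- data.frame(.y = factor(y, c(0, 1)), X, check.names = FALSE)
      lapply(seq_len(n_bags), function(b) {
        idx <- sample.int(nrow(df), replace = TRUE)
        rpart::rpart(.y ~ ., df[idx, , drop = FALSE], method = "class")
      })
    },
    stop("unknown learner: ", name)
  )
}

learner_predict_fun <- function(spec) {
  switch(spec$name,
    SVM = function(core, X) {
      d <- as.numeric(attr(stats::predict(core$svm, X, decision.values = TRUE),
                           "decision.values"))
      stats::plogis(core$platt[1] + core$platt[2] * d)
    },
    LR = function(core, X)
      as.numeric(stats::predict(core, X, type = "response")),
    LDA = function(core, X)
      stats::predict(core$lda, X[, core$keep, drop = FALSE])$posterior[, "1"],
    LightGBM = xgb_predict, XGB = xgb_predict, GBDT = xgb_predict,
    RF = function(core, X)
      stats::predict(core, as.data.frame(X), num.threads = 1)$predictions[, "1"],
    KNN = function(core, X) {
      set.seed(core$seed)
      pr <- class::knn(core$X, X, core$y, k = core$k, prob = TRUE)
      w <- attr(pr, "prob")
      ifelse(pr == "1", w, 1 - w)
    },
    DT = function(core, X)
      stats::predict(core, data.frame(X, check.names = FALSE))[, "1"],
    NB = function(core, X)
      stats::predict(core, as.data.frame(X), type = "raw")[, "1"],
    BG = function(core, X) {
      df <- data.frame(X, check.names = FALSE)
      rowMeans(vapply(core, function(m) stats::predict(m, df)[, "1"],
                      numeric(nrow(X))))
    }
  )
}

xgb_fit <- function(X, y, seed, nrounds, params) {
  params$nthread <- 1
  params$seed <- seed
  d <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(params = params, data = d, nrounds = nrounds, verbose = 0)
}

xgb_predict <- function(core, X) {
  stats::predict(core, xgboost::xgb.DMatrix(X))
}

# random-search spaces for tune_learner; LDA is parameter-free
learner_search_space <- function(name) {
  switch(name,
    SVM = list(cost = 2^seq(-2, 6), gamma = 2^seq(-8, 0)),
    LR = list(lambda = 10^seq(-4, 0, by = 0.5)),
    LightGBM = list(max_leaves = c(15, 31, 63), eta = c(0.05, 0.1, 0.2),
                    nrounds = c(50, 100, 200)),
    XGB = list(max_depth = c(3, 6, 9), eta = c(0.05, 0.1, 0.3),
               nrounds = c(50, 100, 200)),
    GBDT = list(max_depth = c(2, 3, 4), eta = c(0.05, 0.1, 0.2),
                nrounds = c(50, 100, 200)),
    RF = list(num.trees = c(250, 500, 1000)),
    KNN = list(k = c(3, 5, 7, 9, 15, 25)),
    DT = list(cp = c(0.001, 0.005, 0.01, 0.05), maxdepth = c(5, 10, 30)),
    NB = list(laplace = c(0, 0.5, 1)),
    BG = list(n_bags = c(10, 25, 50)),
    list()
  )
}
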