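test_that("config validation enforces the architecture invariants", {
  expect_error(textcnn_config(input_dim = 424, kernel_sizes = c(500)),
               "kernel size")
  expect_error(textcnn_config(dropout_rate = 1), "dropout_rate")
  expect_silent(textcnn_config())
})

test_that("branch shapes follow the shape contract independent of input_dim", {
  for (n in c(50, 424)) {
    cfg <- textcnn_config(input_dim = n, seed = 2)
    m <- build_improved_textcnn(cfg)
    X <- matrix(runif(8 * n), 8)
    fwd <- rbpstack:::textcnn_forward(m, X)
    # pooled branch width = filters_per_kernel, one vector per kernel size
    expect_length(fwd$P, 3)
    for (P in fwd$P) expect_equal(dim(P), c(8, 64))
    expect_equal(dim(fwd$H0), c(8, 192))  # fused width 3 x 64
    expect_length(fwd$prob, 8)
    expect_true(all(fwd$prob >= 0 & fwd$prob <= 1))
  }
})

test_that("attention fusion preserves shapes; concatenation variant identical in layout", {
  cfg <- textcnn_config(input_dim = 60, use_attention = FALSE, seed = 3)
  m <- build_improved_textcnn(cfg)
  X <- matrix(runif(5 * 60), 5)
  fwd <- rbpstack:::textcnn_forward(m, X)
  expect_equal(dim(fwd$H0), c(5, 192))
  expect_null(fwd$att)
})

test_that("attend matches the scaled dot-product formula", {
  v <- c(0.3, -1, 2, 0.5)
  a <- attend(list(v, v, v))
  expect_equal(unname(a$weights), matrix(1 / 3, 3, 3))
  expect_equal(unname(a$tokens), rbind(v, v, v), ignore_attr = TRUE)
  expect_equal(a$output, rep(v, 3))

  b <- attend(list(c(1, 2), c(3, 6)))
  expect_equal(unname(rowSums(b$weights)), c(1, 1))
  expect_true(all(b$weights >= 0))

  set.seed(501)
  for (i in 1:10) {
    V <- matrix(rnorm(12), 3, 4)
    a <- attend(V)
    S <- V %*% t(V) / sqrt(4)
    A <- exp(S) / rowSums(exp(S))   # direct softmax(QK'/sqrt(d))
    expect_equal(unname(a$weights), unname(A), tolerance = 1e-6)
    expect_equal(unname(a$tokens), unname(A %*% V), tolerance = 1e-6)
  }
  expect_error(attend(list(1:3, 1:4)), "mismatched")
  expect_error(attend(matrix(1, 1, 4)), "at least 2")
})

test_that("analytic gradients match numeric differentiation", {
  set.seed(502)
  X <- matrix(runif(6 * 24), 6)
  y <- c(1, 0, 1, 0, 1, 0)
  cfg <- textcnn_config(input_dim = 24, kernel_sizes = c(3, 5),
                        filters_per_kernel = 6, dense_units = 5,
                        dropout_rate = 0, seed = 7)
  m <- build_improved_textcnn(cfg)
  fwd <- rbpstack:::textcnn_forward(m, X)
  g <- rbpstack:::textcnn_backward(m, fwd, y)
  loss_at <- function(params) {
    mm <- m; mm$params <- params
    rbpstack:::bce_loss(rbpstack:::textcnn_forward(mm, X)$prob, y)
  }
  eps <- 1e-6
  for (probe in list(list("W1", g$W1), list("W2", g$W2))) {
    p0 <- m$params[[probe[[1]]]]
    for (i in sample(length(p0), 4)) {
      pp <- m$params; pp[[probe[[1]]]][i] <- pp[[probe[[1]]]][i] + eps
      pm <- m$params; pm[[probe[[1]]]][i] <- pm[[probe[[1]]]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(probe[[2]][i], num, tolerance = 1e-4)
    }
  }
  p0 <- m$params$Wconv[[1]]
  for (i in sample(length(p0), 4)) {
    pp <- m$params; pp$Wconv[[1]][i] <- pp$Wconv[[1]][i] + eps
    pm <- m$params; pm$Wconv[[1]][i] <- pm$Wconv[[1]][i] - eps
    num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    expect_equal(g$Wconv[[1]][i], num, tolerance = 1e-4)
  }
})

test_that("training is deterministic and records a coherent history", {
  d <- separable_xy(n = 60, p = 30, shift = 1, seed = 503)
  cfg <- textcnn_config(input_dim = 30, filters_per_kernel = 8,
                        dense_units = 8, max_epochs = 4, batch_size = 16,
                        seed = 11)
  tr <- seq_len(48); va <- 49:60
  m1 <- train_textcnn(build_improved_textcnn(cfg), d$X[tr, ], d$y[tr],
                      d$X[va, ], d$y[va])
  m2 <- train_textcnn(build_improved_textcnn(cfg), d$X[tr, ], d$y[tr],
                      d$X[va, ], d$y[va])
  expect_equal(m1$history$val_loss, m2$history$val_loss, tolerance = 1e-6)
  expect_equal(m1$history$train_loss, m2$history$train_loss, tolerance = 1e-6)
  h <- m1$history
  expect_lte(attr(h, "stopped_epoch"), cfg$max_epochs)
  expect_equal(attr(h, "best_epoch"), which.min(h$val_loss))
})

test_that("patience stops training and restores the best epoch", {
  # noise labels: validation loss plateaus quickly, so patience must fire
  set.seed(504)
  X <- matrix(runif(80 * 20), 80)
  y <- rep(0:1, 40)
  cfg <- textcnn_config(input_dim = 20, filters_per_kernel = 4,
                        dense_units = 4, max_epochs = 50, patience = 3,
                        learning_rate = 1e-5, batch_size = 40, seed = 13)
  m <- train_textcnn(build_improved_textcnn(cfg), X[1:60, ], y[1:60],
                     X[61:80, ], y[61:80])
  h <- m$history
  stopped <- attr(h, "stopped_epoch"); best <- attr(h, "best_epoch")
  if (stopped < cfg$max_epochs) {
    expect_lte(stopped - best, cfg$patience)
    # exactly `patience` non-improving epochs follow the best one
    expect_equal(stopped, best + cfg$patience)
  }
  expect_equal(best, which.min(h$val_loss))
})

test_that("early stopping learns separable features to high validation accuracy", {
  set.seed(505)
  n <- 400; p <- 424
  y <- rep(0:1, each = n / 2)
  X <- matrix(runif(n * p), n)
  X[y == 1, 1:8] <- X[y == 1, 1:8] + 0.6
  va <- seq(1, n, by = 5); tr <- setdiff(seq_len(n), va)
  m <- train_textcnn(build_improved_textcnn(textcnn_config(seed = 3)),
                     X[tr, ], y[tr], X[va, ], y[va])
  expect_gte(max(m$history$val_acc), 0.95)
})

test_that("predict_textcnn validates width and is deterministic at inference", {
  cfg <- textcnn_config(input_dim = 30, filters_per_kernel = 4,
                        dense_units = 4, seed = 15)
  m <- build_improved_textcnn(cfg)
  X <- matrix(runif(4 * 30), 4)
  p1 <- predict_textcnn(m, X)
  expect_true(all(p1 >= 0 & p1 <= 1))
  p2 <- predict_textcnn(m, X[c(1, 1), , drop = FALSE])
  expect_equal(p2[1], p2[2])
  expect_error(predict_textcnn(m, X[, 1:10]), "expected 30, got 10")
})

test_that("the embedding baseline pads, embeds and classifies", {
  expect_error(build_original_textcnn(max_len = 2), "max_len")
  cfg <- textcnn_config(input_dim = 424, filters_per_kernel = 4,
                        dense_units = 4, seed = 17)
  m <- build_original_textcnn(vocab_size = 21, embed_dim = 5, max_len = 10,
                              config = cfg)
  expect_equal(dim(m$params$E), c(21, 5))  # 20 residues + padding token

  idx <- encode_residue_indices("ACDEFG", 10)
  expect_equal(as.integer(idx), c(1, 2, 3, 4, 5, 6, 21, 21, 21, 21))

  p <- predict_textcnn(m, c("ACDEFG", "MKVLMKVLWY", "RGGRGGRGGRGGRGG"))
  expect_length(p, 3)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the embedding baseline trains end to end on sequences", {
  set.seed(506)
  pos <- replicate(30, paste0(rand_seq(8), "RGGRGG", rand_seq(8)))
  neg <- replicate(30, rand_seq(22))
  y <- rep(1:0, each = 30)
  Xi <- encode_residue_indices(c(pos, neg), 24)
  cfg <- textcnn_config(input_dim = 424, filters_per_kernel = 8,
                        dense_units = 8, max_epochs = 10, batch_size = 16,
                        seed = 19)
  m <- build_original_textcnn(vocab_size = 21, embed_dim = 8, max_len = 24,
                              config = cfg)
  va <- seq(1, 60, by = 5); tr <- setdiff(1:60, va)
  m <- train_textcnn(m, Xi[tr, ], y[tr], Xi[va, ], y[va])
  expect_equal(nrow(m$history), attr(m$history, "stopped_epoch"))
  expect_true(all(is.finite(m$history$val_loss)))
})

test_that("checkpoints round-trip weights and write a readable config sidecar", {
  cfg <- textcnn_config(input_dim = 30, filters_per_kernel = 4,
                        dense_units = 4, seed = 23)
  m <- build_improved_textcnn(cfg)
  prefix <- tempfile()
  save_textcnn(m, prefix)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(side$input_dim, 30)
  expect_equal(side$kernel_sizes, c(3, 4, 5))
  expect_equal(side$type, "improved")
  m2 <- load_textcnn(prefix)
  X <- matrix(runif(3 * 30), 3)
  expect_identical(predict_textcnn(m, X), predict_textcnn(m2, X))
})

test_that("training history exports to CSV", {
  d <- separable_xy(n = 40, p = 20, seed = 507)
  cfg <- textcnn_config(input_dim = 20, filters_per_kernel = 4,
                        dense_units = 4, max_epochs = 2, seed = 21)
  m <- train_textcnn(build_improved_textcnn(cfg), d$X[1:30, ], d$y[1:30],
                     d$X[31:40, ], d$y[31:40])
  f <- tempfile(fileext = ".csv")
  write_history(m, f)
  h <- utils::read.csv(f)
  expect_equal(colnames(h), c("epoch", "train_loss", "val_loss",
                              "train_acc", "val_acc"))
  expect_equal(nrow(h), 2)
  expect_error(write_history(build_improved_textcnn(cfg), f), "no training")
})
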