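#' Configuration of the convolutional sequence classifier
#'
#' Defaults follow the reference architecture: a 424-dimensional encoded
#' input treated as a length-n single-channel 1D feature map, three parallel
#' convolution branches with kernel sizes 3/4/5 and 64 filters each, global
#' max pooling per branch, scaled dot-product self-attention over the three
#' pooled 64-dim branch vectors followed by concatenation, one hidden dense
#' layer, dropout, and a single sigmoid output. Training uses Adam with
#' binary cross-entropy, early stopping on validation loss (patience 5,
#' maximum 50 epochs).
#'
#' @param input_dim feature count n (default 424).
#' @param kernel_sizes ordered integer kernel widths, all `< input_dim`.
#' @param filters_per_kernel filters per branch (default 64).
#' @param use_attention fuse branches with self-attention before
#'   concatenation (default `TRUE`); `FALSE` = plain concatenation.
#' @param dense_units width of the hidden dense layer.
#' @param dropout_rate dropout probability in `[0, 1)` before the output.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs (default 50).
#' @param patience consecutive epochs without a strict validation-loss
#'   decrease before stopping (default 5).
#' @param seed integer seed controlling weight init, shuffling and dropout.
#' @return a `textcnn_config` list.
#' @export
textcnn_config <- function(input_dim = 424, kernel_sizes = c(3, 4, 5),
                           filters_per_kernel = 64, use_attention = TRUE,
                           dense_units = 64, dropout_rate = 0.5,
                           learning_rate = 1e-3, batch_size = 32,
                           max_epochs = 50, patience = 5, seed = 1) {
  if (any(kernel_sizes >= input_dim))
    stop("kernel size ", max(kernel_sizes), " must be < input_dim ", input_dim)
  stopifnot(filters_per_kernel >= 1, max_epochs >= 1, patience >= 1,
            dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            batch_size >= 1)
  structure(list(input_dim = input_dim, kernel_sizes = as.integer(kernel_sizes),
                 filters_per_kernel = as.integer(filters_per_kernel),
                 use_attention = isTRUE(use_attention),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "textcnn_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build the embedding-free convolutional classifier
#'
#' Each encoded sequence enters as a `(n, 1)` one-dimensional feature map
#' (no embedding layer anywhere). Per kernel size s a valid 1D convolution
#' with `filters_per_kernel` filters and ReLU is followed by global max
#' pooling, giving one pooled vector per branch; the branch vectors are
#' fused (self-attention then concatenation when `use_attention`, plain
#' concatenation otherwise) and classified through a ReLU dense layer with
#' dropout and a sigmoid output unit. Parameter initialisation is seeded.
#'
#' @param config a [textcnn_config].
#' @return a `textcnn_model`.
#' @export
build_improved_textcnn <- function(config) {
  stopifnot(inherits(config, "textcnn_config"))
  set.seed(config$seed)
  F <- config$filters_per_kernel
  nb <- length(config$kernel_sizes)
  params <- list(
    Wconv = lapply(config$kernel_sizes, function(s) glorot(s, F)),
    bconv = lapply(config$kernel_sizes, function(s) numeric(F)),
    W1 = glorot(nb * F, config$dense_units),
    b1 = numeric(config$dense_units),
    W2 = glorot(config$dense_units, 1),
    b2 = numeric(1)
  )
  structure(list(type = "improved", config = config, params = params,
                 channels = 1L, history = NULL),
            class = "textcnn_model")
}

#' Build the embedding-based baseline classifier
#'
#' The original-architecture baseline: residues are integer-encoded over a
#' vocabulary of the 20 standard amino acids plus a padding token, passed
#' through a trainable embedding layer, then through the same multi-kernel
#' convolution / global-max-pooling / dense stack as the embedding-free
#' model. Sequences are padded or truncated to `max_len`.
#'
#' @param vocab_size embedding rows (default 21 = 20 residues + padding).
#' @param embed_dim embedding width.
#' @param max_len fixed residue-sequence length after padding/truncation;
#'   must be at least the largest kernel size.
#' @param config a [textcnn_config]; its `input_dim` is ignored in favour of
#'   `max_len`.
#' @return a `textcnn_model` of type `"original"`.
#' @export
build_original_textcnn <- function(vocab_size = 21, embed_dim = 16, max_len,
                                   config = textcnn_config()) {
  if (max_len < max(config$kernel_sizes))
    stop("max_len ", max_len, " must be >= largest kernel size ",
         max(config$kernel_sizes))
  config$input_dim <- as.integer(max_len)
  set.seed(config$seed)
  F <- config$filters_per_kernel
  nb <- length(config$kernel_sizes)
  params <- list(
    E = glorot(vocab_size, embed_dim),
    Wconv = lapply(config$kernel_sizes, function(s) glorot(s * embed_dim, F)),
    bconv = lapply(config$kernel_sizes, function(s) numeric(F)),
    W1 = glorot(nb * F, config$dense_units),
    b1 = numeric(config$dense_units),
    W2 = glorot(config$dense_units, 1),
    b2 = numeric(1)
  )
  structure(list(type = "original", config = config, params = params,
                 channels = as.integer(embed_dim),
                 vocab_size = as.integer(vocab_size),
                 max_len = as.integer(max_len), history = NULL),
            class = "textcnn_model")
}

#' Integer-encode residue strings for the embedding baseline
#'
#' Residues map to indices 1..20 in canonical alphabet order; position 21 is
#' the padding token. Sequences are right-padded or truncated to `max_len`.
#'
#' @param residues character vector of amino-acid strings.
#' @param max_len output length.
#' @return integer matrix, one row per sequence.
#' @export
encode_residue_indices <- function(residues, max_len) {
  out <- matrix(21L, length(residues), max_len)
  for (i in seq_along(residues)) {
    codes <- match(strsplit(toupper(residues[i]), "")[[1]], AA_ALPHABET)
    codes <- codes[!is.na(codes)]
    n <- min(length(codes), max_len)
    if (n > 0) out[i, seq_len(n)] <- codes[seq_len(n)]
  }
  out
}

#' Scaled dot-product self-attention over branch vectors
#'
#' The pooled branch outputs are treated as a length-`nb` sequence of d-dim
#' tokens with query = key = value: `A = softmax(V V' / sqrt(d))`,
#' output = `A V`, tokens then concatenated. Attention rows are
#' non-negative and sum to 1; identical tokens receive uniform weights and
#' pass through unchanged.
#'
#' @param branches list of equal-length numeric vectors (>= 2), or a matrix
#'   with one token per row.
#' @return list with `output` (concatenated attended tokens), `tokens`
#'   (attended tokens as a matrix) and `weights` (the attention matrix).
#' @export
attend <- function(branches) {
  V <- if (is.matrix(branches)) branches else {
    lens <- lengths(branches)
    if (length(unique(lens)) != 1L)
      stop("branch vectors have mismatched lengths: ",
           paste(lens, collapse = ", "))
    do.call(rbind, branches)
  }
  if (nrow(V) < 2L) stop("need at least 2 branch vectors")
  d <- ncol(V)
  S <- V %*% t(V) / sqrt(d)
  A <- t(apply(S, 1, function(row) {
    e <- exp(row - max(row)); e / sum(e)
  }))
  O <- A %*% V
  list(output = as.numeric(t(O)), tokens = O, weights = A)
}

# ---- batched forward / backward -------------------------------------------

# one convolution branch: im2col + BLAS matmul for the valid 1D convolution,
# C++ kernel for bias + ReLU + global max pooling
conv_branch_forward <- function(Xarr, W, bias, s) {
  d <- dim(Xarr); B <- d[1]; L <- d[2]; C <- d[3]
  T_len <- L - s + 1L
  if (T_len < 1L) stop("kernel size ", s, " exceeds input length ", L)
  Xcol <- matrix(0, B * T_len, s * C)
  for (c in seq_len(C)) for (j in seq_len(s))
    Xcol[, (c - 1L) * s + j] <- Xarr[, j:(j + T_len - 1L), c]
  pm <- relu_max_pool(Xcol %*% W, bias, B)
  list(pooled = pm$pooled, argmax = pm$argmax)
}

# softmax over the nb x nb attention scores, batched: S is a list-of-lists
# of B-vectors. Returns A in the same layout.
batch_attention <- function(P, d) {
  nb <- length(P); B <- nrow(P[[1]])
  S <- lapply(seq_len(nb), function(i)
    matrix(vapply(seq_len(nb), function(j) rowSums(P[[i]] * P[[j]]) / sqrt(d),
                  numeric(B)), nrow = B))
  A <- lapply(S, function(Si) {
    m <- do.call(pmax, lapply(seq_len(nb), function(j) Si[, j]))
    E <- exp(Si - m)
    E / rowSums(E)
  })
  O <- lapply(seq_len(nb), function(i) {
    out <- 0
    for (j in seq_len(nb)) out <- out + A[[i]][, j] * P[[j]]
    out
  })
  list(A = A, O = O)
}

textcnn_forward <- function(model, X, train = FALSE, drop_mask = NULL) {
  cfg <- model$config; p <- model$params
  F <- cfg$filters_per_kernel; nb <- length(cfg$kernel_sizes)
  if (model$type == "improved") {
    B <- nrow(X)
    Xarr <- X; dim(Xarr) <- c(B, cfg$input_dim, 1L)
  } else {
    B <- nrow(X)
    Xarr <- p$E[X, ]  # (B*max_len) x embed_dim
    dim(Xarr) <- c(B, model$max_len, model$channels)
  }
  conv <- lapply(seq_len(nb), function(i)
    conv_branch_forward(Xarr, p$Wconv[[i]], p$bconv[[i]],
                        cfg$kernel_sizes[i]))
  P <- lapply(conv, `[[`, "pooled")
  if (cfg$use_attention) {
    att <- batch_attention(P, F)
    H0 <- do.call(cbind, att$O)
  } else {
    att <- NULL
    H0 <- do.call(cbind, P)
  }
  Z1 <- sweep(H0 %*% p$W1, 2, p$b1, "+")
  H1 <- pmax(Z1, 0)
  H1d <- if (train && cfg$dropout_rate > 0) H1 * drop_mask else H1
  z2 <- as.numeric(H1d %*% p$W2) + p$b2
  prob <- stats::plogis(z2)
  list(Xarr = Xarr, conv = conv, P = P, att = att, H0 = H0, H1 = H1,
       H1d = H1d, prob = prob)
}

textcnn_backward <- function(model, fwd, y, drop_mask = NULL) {
  cfg <- model$config; p <- model$params
  F <- cfg$filters_per_kernel; nb <- length(cfg$kernel_sizes)
  B <- length(y)
  dz2 <- (fwd$prob - y) / B
  g <- list()
  g$W2 <- t(fwd$H1d) %*% dz2
  g$b2 <- sum(dz2)
  dH1d <- outer(dz2, as.numeric(p$W2))
  dH1 <- if (!is.null(drop_mask)) dH1d * drop_mask else dH1d
  dH1[fwd$H1 <= 0] <- 0
  g$W1 <- t(fwd$H0) %*% dH1
  g$b1 <- colSums(dH1)
  dH0 <- dH1 %*% t(p$W1)
  dO <- lapply(seq_len(nb), function(i)
    dH0[, ((i - 1) * F + 1):(i * F), drop = FALSE])
  if (cfg$use_attention) {
    A <- fwd$att$A; P <- fwd$P
    dP <- lapply(seq_len(nb), function(j) matrix(0, B, F))
    dA <- lapply(seq_len(nb), function(i)
      matrix(vapply(seq_len(nb), function(j) rowSums(dO[[i]] * P[[j]]),
                    numeric(B)), nrow = B))
    dS <- lapply(seq_len(nb), function(i) {
      rowdot <- rowSums(dA[[i]] * A[[i]])
      A[[i]] * (dA[[i]] - rowdot)
    })
    for (j in seq_len(nb)) {
      acc <- dP[[j]]
      for (i in seq_len(nb)) {
        acc <- acc + A[[i]][, j] * dO[[i]]                     # value path
        acc <- acc + ((dS[[i]][, j] + dS[[j]][, i]) / sqrt(F)) * P[[i]]  # score path
      }
      dP[[j]] <- acc
    }
  } else {
    dP <- dO
  }
  need_dx <- model$type == "original"
  g$Wconv <- vector("list", nb); g$bconv <- vector("list", nb)
  dXacc <- NULL
  for (i in seq_len(nb)) {
    bk <- conv_pool_backward(fwd$Xarr, p$Wconv[[i]], fwd$conv[[i]]$argmax,
                             fwd$conv[[i]]$pooled, dP[[i]],
                             cfg$kernel_sizes[i], need_dx)
    g$Wconv[[i]] <- bk$dW
    g$bconv[[i]] <- bk$db
    if (need_dx) dXacc <- if (is.null(dXacc)) bk$dX else dXacc + bk$dX
  }
  g$dXarr <- dXacc
  g
}

# flatten params/grads into aligned lists for Adam
adam_init <- function(params) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(p, gr, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, gr, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * gr
      v <- beta2 * v + (1 - beta2) * gr^2
      mh <- m / (1 - beta1^state$t)
      vh <- v / (1 - beta2^state$t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  keys <- intersect(names(params), names(grads))
  out <- Map(upd, params[keys], grads[keys], state$m[keys], state$v[keys])
  params[keys] <- lapply(out, `[[`, "p")
  state$m[keys] <- lapply(out, `[[`, "m")
  state$v[keys] <- lapply(out, `[[`, "v")
  list(params = params, state = state)
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a convolutional classifier with early stopping
#'
#' Minibatch Adam on binary cross-entropy. Training stops at the earlier of
#' `max_epochs` or `patience` consecutive epochs whose validation loss is
#' not strictly lower than the best seen; the returned model carries the
#' weights of the best epoch. The per-epoch history (train/validation loss
#' and accuracy) is recorded in `model$history` together with
#' `stopped_epoch` and `best_epoch`. One seed (from the model's config)
#' controls shuffling and dropout masks.
#'
#' @param model a `textcnn_model` from [build_improved_textcnn] or
#'   [build_original_textcnn].
#' @param X_train,y_train training inputs (feature matrix for the improved
#'   model, integer index matrix for the baseline) and binary labels.
#' @param X_val,y_val validation split, disjoint from training; both classes
#'   must be present in each.
#' @return the trained `textcnn_model` (best-epoch weights, history filled).
#' @export
train_textcnn <- function(model, X_train, y_train, X_val, y_val) {
  cfg <- model$config
  y_train <- as.numeric(y_train); y_val <- as.numeric(y_val)
  if (length(unique(y_train)) < 2L) stop("training labels are single-class")
  if (length(unique(y_val)) < 2L) stop("validation labels are single-class")
  n <- nrow(X_train)
  state <- adam_init(model$params)
  set.seed(derive_seed(cfg$seed, 1L))
  best_loss <- Inf; best_epoch <- 0L; best_params <- model$params
  bad <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), train_acc = numeric(0),
                     val_acc = numeric(0))
  stopped <- cfg$max_epochs
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    batch_starts <- seq(1, n, by = cfg$batch_size)
    tl <- 0; ta <- 0; seen <- 0
    for (b0 in batch_starts) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      Xb <- X_train[idx, , drop = FALSE]
      yb <- y_train[idx]
      mask <- NULL
      if (cfg$dropout_rate > 0)
        mask <- matrix(stats::rbinom(length(idx) * cfg$dense_units, 1,
                                     1 - cfg$dropout_rate),
                       length(idx)) / (1 - cfg$dropout_rate)
      fwd <- textcnn_forward(model, Xb, train = TRUE, drop_mask = mask)
      g <- textcnn_backward(model, fwd, yb, drop_mask = mask)
      if (model$type == "original") {
        dE <- matrix(0, nrow(model$params$E), ncol(model$params$E))
        dX <- g$dXarr; dim(dX) <- c(length(idx) * model$max_len, model$channels)
        sums <- rowsum(dX, as.integer(Xb))  # grouped by embedding row
        dE[as.integer(rownames(sums)), ] <- sums
        g$E <- dE
      }
      g$dXarr <- NULL
      st <- adam_step(model$params, g, state, cfg$learning_rate)
      model$params <- st$params; state <- st$state
      tl <- tl + bce_loss(fwd$prob, yb) * length(idx)
      ta <- ta + sum((fwd$prob >= 0.5) == yb)
      seen <- seen + length(idx)
    }
    vfwd <- textcnn_forward(model, X_val, train = FALSE)
    vl <- bce_loss(vfwd$prob, y_val)
    va <- mean((vfwd$prob >= 0.5) == y_val)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / seen,
                                   val_loss = vl, train_acc = ta / seen,
                                   val_acc = va))
    if (vl < best_loss) {         # strict decrease resets patience
      best_loss <- vl; best_epoch <- epoch; best_params <- model$params
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) { stopped <- epoch; break }
    }
    stopped <- epoch
  }
  model$params <- best_params
  model$history <- structure(hist, stopped_epoch = stopped,
                             best_epoch = best_epoch)
  model
}

#' Predict positive-class probabilities
#'
#' @param model a trained `textcnn_model`.
#' @param X feature matrix (improved model; column count must equal the
#'   configured `input_dim`) or integer index matrix / residue strings
#'   (baseline model).
#' @return numeric vector of probabilities in `[0, 1]`; the implied label is
#'   1 iff probability >= 0.5.
#' @export
predict_textcnn <- function(model, X) {
  if (model$type == "original" && is.character(X))
    X <- encode_residue_indices(X, model$max_len)
  if (ncol(X) != model$config$input_dim)
    stop("input width mismatch: expected ", model$config$input_dim,
         ", got ", ncol(X))
  out <- numeric(nrow(X))
  # bounded batches keep the conv workspace small on large inputs
  for (b0 in seq(1, nrow(X), by = 512)) {
    idx <- b0:min(b0 + 511, nrow(X))
    out[idx] <- textcnn_forward(model, X[idx, , drop = FALSE])$prob
  }
  out
}

#' Save / load a model checkpoint
#'
#' The model (weights, config, history) is serialised to `<prefix>.rds` with
#' a human-readable JSON sidecar `<prefix>.json` recording the architecture
#' configuration, for inspection and provenance.
#'
#' @param model a `textcnn_model`.
#' @param prefix output path prefix (no extension).
#' @return `save_textcnn`: invisibly, the two paths; `load_textcnn`: the
#'   restored `textcnn_model`.
#' @export
save_textcnn <- function(model, prefix) {
  rds <- paste0(prefix, ".rds"); js <- paste0(prefix, ".json")
  saveRDS(model, rds)
  jsonlite::write_json(
    c(unclass(model$config), list(type = model$type)),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(rds, js))
}

#' @rdname save_textcnn
#' @export
load_textcnn <- function(prefix) {
  model <- readRDS(paste0(prefix, ".rds"))
  stopifnot(inherits(model, "textcnn_model"))
  model
}

#' Export a training history as CSV
#'
#' @param model a trained `textcnn_model`.
#' @param path CSV path (columns epoch, train_loss, val_loss, train_acc,
#'   val_acc).
#' @return `path`, invisibly.
#' @export
write_history <- function(model, path) {
  if (is.null(model$history)) stop("model has no training history")
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
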