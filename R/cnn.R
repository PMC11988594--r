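#' Configuration of the 1D convolutional origin classifier
#'
#' The reference architecture takes a standardized 107-length VOC intensity
#' vector through two valid cross-correlation layers (kernel length 3,
#' filter widths 4 then 8, ReLU), each followed by non-overlapping max
#' pooling of width 3 (trailing remainder dropped), then flattens to an
#' 88-element vector feeding a 32-unit ReLU dense layer and a 3-class
#' softmax output. With these defaults the network has 3067 trainable
#' parameters. Training uses mini-batch Adam on categorical cross-entropy.
#'
#' @param input_len Length of the input feature vector (default 107).
#' @param conv_filters Integer pair of filter counts for the two
#'   convolutional layers (default `c(4, 8)`).
#' @param kernel_len Convolution kernel length (default 3).
#' @param pool_len Max-pool window and stride (default 3, non-overlapping).
#' @param dense_units Hidden dense-layer width (default 32).
#' @param n_classes Number of output classes (default 3).
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 16).
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A list of class `cnn_config` with a precomputed `flatten_len`.
#' @export
#' @examples
#' cnn_config()$flatten_len  # 88
cnn_config <- function(input_len = 107L, conv_filters = c(4L, 8L),
                       kernel_len = 3L, pool_len = 3L, dense_units = 32L,
                       n_classes = 3L, learning_rate = 1e-3, epochs = 100L,
                       batch_size = 16L, seed = NULL) {
  cfg <- list(
    input_len = as.integer(input_len),
    conv_filters = as.integer(conv_filters),
    kernel_len = as.integer(kernel_len),
    pool_len = as.integer(pool_len),
    dense_units = as.integer(dense_units),
    n_classes = as.integer(n_classes),
    learning_rate = learning_rate,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  geom <- cnn_geometry(cfg)
  if (geom$p2 < 1L) {
    stop_kelp(sprintf(
      "degenerate geometry: input_len %d leaves no flattened features (conv %d, pool %d)",
      cfg$input_len, cfg$kernel_len, cfg$pool_len),
      class = "kelptrace_config_error")
  }
  cfg$flatten_len <- geom$p2 * cfg$conv_filters[2L]
  class(cfg) <- "cnn_config"
  cfg
}

# Layer output lengths implied by valid convolutions and floor-divided pools.
cnn_geometry <- function(cfg) {
  l1 <- cfg$input_len - cfg$kernel_len + 1L
  p1 <- l1 %/% cfg$pool_len
  l2 <- p1 - cfg$kernel_len + 1L
  p2 <- if (l2 >= 1L) l2 %/% cfg$pool_len else 0L
  list(l1 = l1, p1 = p1, l2 = max(l2, 0L), p2 = p2)
}

#' Build the classifier with seeded Glorot-uniform weights
#'
#' Weights are drawn from the Glorot (Xavier) uniform distribution,
#' `U(-sqrt(6/(fan_in + fan_out)), +...)`, biases start at zero. A fixed
#' `seed` in the config gives bit-identical initializations.
#'
#' @param config A [cnn_config()].
#' @return An object of class `kelp_cnn`: the config plus per-layer weight
#'   and bias arrays.
#' @export
build_cnn <- function(config = cnn_config()) {
  if (!inherits(config, "cnn_config")) {
    stop_kelp("`config` must be created by cnn_config()",
              class = "kelptrace_config_error")
  }
  geom <- cnn_geometry(config)
  if (geom$p2 * config$conv_filters[2L] != config$flatten_len) {
    stop_kelp("config flatten length is inconsistent with its geometry",
              class = "kelptrace_config_error")
  }
  k <- config$kernel_len
  f1 <- config$conv_filters[1L]
  f2 <- config$conv_filters[2L]
  if (!is.null(config$seed)) set.seed(config$seed)
  glorot <- function(fan_in, fan_out, n) {
    lim <- sqrt(6 / (fan_in + fan_out))
    stats::runif(n, -lim, lim)
  }
  weights <- list(
    w1 = matrix(glorot(k, k * f1, k * f1), k, f1),
    b1 = numeric(f1),
    w2 = array(glorot(k * f1, k * f2, k * f1 * f2), dim = c(k, f1, f2)),
    b2 = numeric(f2),
    w3 = matrix(glorot(config$flatten_len, config$dense_units,
                       config$flatten_len * config$dense_units),
                config$flatten_len, config$dense_units),
    b3 = numeric(config$dense_units),
    w4 = matrix(glorot(config$dense_units, config$n_classes,
                       config$dense_units * config$n_classes),
                config$dense_units, config$n_classes),
    b4 = numeric(config$n_classes)
  )
  structure(list(config = config, weights = weights, feature_ids = NULL,
                 history = NULL),
            class = "kelp_cnn")
}

relu <- function(x) {
  x * (x > 0)
}

# column-wise bias addition without sweep()'s aperm overhead
bias_add <- function(m, b) {
  m + rep(b, rep.int(nrow(m), length(b)))
}

# Internally, convolutional activations live in "stacked" layout: an
# (n_samples * n_positions) x n_filters matrix whose rows are ordered
# sample-fastest (row (t - 1) * n + s holds sample s, position t). This
# turns both convolutions into single BLAS matrix products over im2col
# matrices, which matters for the batched forwards behind Shapley masking.

# Map from position-fastest reshape columns to the documented
# channel-fastest flatten indices: column t + (g - 1) * p2 of the reshape
# holds flatten element (t - 1) * f2 + g.
flatten_perm <- function(p2, f2) {
  j <- seq_len(p2 * f2)
  t_pos <- ((j - 1L) %% p2) + 1L
  g <- ((j - 1L) %/% p2) + 1L
  (t_pos - 1L) * f2 + g
}

# Row indices selecting position offset `off` (0-based) blocks of length
# `len`, stride `stride`, from a stacked matrix with n samples.
stacked_rows <- function(n, len, stride, off) {
  rep.int((seq_len(len) - 1L) * stride + off, rep.int(n, len)) * n +
    rep.int(seq_len(n), len)
}

# im2col for a stacked single/multi-channel input: returns an
# (n * out_len) x (kernel * n_channels) matrix, kernel offset fastest,
# matching the column-major layout of the (k, channels, filters) kernels.
im2col_stacked <- function(a, n, out_len, kernel) {
  n_chan <- ncol(a)
  out <- matrix(0, n * out_len, kernel * n_chan)
  for (cc in seq_len(n_chan)) {
    for (kk in seq_len(kernel)) {
      out[, (cc - 1L) * kernel + kk] <- a[stacked_rows(n, out_len, 1L, kk - 1L), cc]
    }
  }
  out
}

# Non-overlapping max pool over a stacked matrix; first-wins tie handling.
# Returns the pooled stacked matrix and per-offset routing masks.
pool_stacked <- function(a, n, out_len, pool_len, keep_masks = FALSE) {
  rows1 <- stacked_rows(n, out_len, pool_len, 0L)
  pooled <- a[rows1, , drop = FALSE]
  masks <- if (keep_masks) list(matrix(TRUE, nrow(pooled), ncol(pooled))) else NULL
  if (pool_len >= 2L) for (kk in 2:pool_len) {
    slice <- a[stacked_rows(n, out_len, pool_len, kk - 1L), , drop = FALSE]
    better <- slice > pooled
    if (keep_masks) {
      for (j in seq_len(kk - 1L)) masks[[j]][better] <- FALSE
      masks[[kk]] <- better
    }
    pooled[better] <- slice[better]
  }
  list(pooled = pooled, masks = masks)
}

# Batched forward pass; x is n x input_len. Returns softmax probabilities,
# optionally with the intermediates needed for backprop.
cnn_forward <- function(model, x, keep_cache = FALSE, output = "prob") {
  cfg <- model$config
  w <- model$weights
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != cfg$input_len) {
    stop_kelp(sprintf("input has %d features; model expects %d",
                      ncol(x), cfg$input_len),
              class = "kelptrace_argument_error")
  }
  if (any(!is.finite(x))) {
    stop_kelp("non-finite model input", class = "kelptrace_argument_error")
  }
  geom <- cnn_geometry(cfg)
  n <- nrow(x)
  k <- cfg$kernel_len
  f2 <- cfg$conv_filters[2L]

  # conv1: single input channel, stacked layout from the input matrix
  m1 <- im2col_stacked(matrix(as.vector(x), n * cfg$input_len, 1L),
                       n, geom$l1, k)
  c1 <- bias_add(m1 %*% w$w1, w$b1)        # (n*l1) x f1
  a1 <- relu(c1)
  pl1 <- pool_stacked(a1, n, geom$p1, cfg$pool_len, keep_masks = keep_cache)
  p1 <- pl1$pooled                               # (n*p1) x f1

  m2 <- im2col_stacked(p1, n, geom$l2, k)        # (n*l2) x (k*f1)
  w2m <- matrix(w$w2, k * cfg$conv_filters[1L], f2)
  c2 <- bias_add(m2 %*% w2m, w$b2)         # (n*l2) x f2
  a2 <- relu(c2)
  pl2 <- pool_stacked(a2, n, geom$p2, cfg$pool_len, keep_masks = keep_cache)
  p2 <- pl2$pooled                               # (n*p2) x f2

  # Flatten semantics are channel-fastest: index (t - 1) * f2 + g holds
  # filter g, step t. Instead of physically permuting the activations, the
  # stacked matrix is reshaped position-fastest (a free, contiguous reshape)
  # and the rows of w3 are permuted to match.
  fm <- matrix(as.vector(p2), n, cfg$flatten_len)
  perm <- flatten_perm(geom$p2, f2)
  z3 <- bias_add(fm %*% w$w3[perm, , drop = FALSE], w$b3)
  a3 <- relu(z3)
  z4 <- bias_add(a3 %*% w$w4, w$b4)
  if (identical(output, "logit") && !keep_cache) return(z4)
  ez <- exp(z4 - z4[cbind(seq_len(n), max.col(z4, ties.method = "first"))])
  probs <- ez / rowSums(ez)

  if (!keep_cache) return(probs)
  list(probs = probs, m1 = m1, c1 = c1, masks1 = pl1$masks, p1 = p1,
       m2 = m2, c2 = c2, masks2 = pl2$masks, fm = fm, z3 = z3, a3 = a3)
}

# Backprop of mean categorical cross-entropy; returns gradients (same shapes
# as the weights) and the batch loss.
cnn_backward <- function(model, x, y_onehot) {
  cfg <- model$config
  w <- model$weights
  geom <- cnn_geometry(cfg)
  k <- cfg$kernel_len
  f1 <- cfg$conv_filters[1L]
  f2 <- cfg$conv_filters[2L]
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  n <- nrow(x)

  cache <- cnn_forward(model, x, keep_cache = TRUE)
  probs <- cache$probs
  loss <- -mean(log(rowSums(probs * y_onehot) + 1e-12))

  dz4 <- (probs - y_onehot) / n
  g_w4 <- crossprod(cache$a3, dz4)
  g_b4 <- colSums(dz4)
  dz3 <- (dz4 %*% t(w$w4)) * (cache$z3 > 0)
  # cache$fm is the position-fastest reshape; undo the w3 row permutation
  perm <- flatten_perm(geom$p2, f2)
  g_w3_perm <- crossprod(cache$fm, dz3)
  g_w3 <- g_w3_perm
  g_w3[perm, ] <- g_w3_perm
  g_b3 <- colSums(dz3)
  dfm <- dz3 %*% t(w$w3[perm, , drop = FALSE])

  # unflatten back to stacked layout (free reshape), un-pool, gate by ReLU
  dp2 <- matrix(dfm, n * geom$p2, f2)
  da2 <- matrix(0, n * geom$l2, f2)
  for (kk in seq_len(cfg$pool_len)) {
    rows <- stacked_rows(n, geom$p2, cfg$pool_len, kk - 1L)
    da2[rows, ] <- da2[rows, , drop = FALSE] + dp2 * cache$masks2[[kk]]
  }
  dc2 <- da2 * (cache$c2 > 0)

  g_w2 <- array(crossprod(cache$m2, dc2), dim = c(k, f1, f2))
  g_b2 <- colSums(dc2)
  dm2 <- dc2 %*% t(matrix(w$w2, k * f1, f2))

  # scatter im2col gradient back onto pooled layer-1 activations
  dp1 <- matrix(0, n * geom$p1, f1)
  for (cc in seq_len(f1)) {
    for (kk in seq_len(k)) {
      rows <- stacked_rows(n, geom$l2, 1L, kk - 1L)
      dp1[rows, cc] <- dp1[rows, cc] + dm2[, (cc - 1L) * k + kk]
    }
  }
  da1 <- matrix(0, n * geom$l1, f1)
  for (kk in seq_len(cfg$pool_len)) {
    rows <- stacked_rows(n, geom$p1, cfg$pool_len, kk - 1L)
    da1[rows, ] <- da1[rows, , drop = FALSE] + dp1 * cache$masks1[[kk]]
  }
  dc1 <- da1 * (cache$c1 > 0)
  g_w1 <- crossprod(cache$m1, dc1)
  g_b1 <- colSums(dc1)

  list(grads = list(w1 = g_w1, b1 = g_b1, w2 = g_w2, b2 = g_b2,
                    w3 = g_w3, b3 = g_b3, w4 = g_w4, b4 = g_b4),
       loss = loss, probs = probs)
}

#' Train the classifier with mini-batch Adam
#'
#' Minimizes categorical cross-entropy by backpropagation and Adam
#' (beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7) with seeded within-epoch
#' shuffling. Training is bit-reproducible for a fixed seed.
#'
#' @param model A `kelp_cnn` from [build_cnn()].
#' @param x Standardized feature matrix (samples x `input_len`).
#' @param y Integer class labels (0-based, in `0:(n_classes - 1)`).
#' @param epochs,batch_size,learning_rate,seed Override the config values.
#' @return The trained `kelp_cnn`, with `history`: a tibble of per-epoch
#'   full-set training `loss` (nats) and `accuracy`.
#' @export
cnn_train <- function(model, x, y, epochs = NULL, batch_size = NULL,
                      learning_rate = NULL, seed = NULL) {
  cfg <- model$config
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) cfg$batch_size else as.integer(batch_size)
  lr <- if (is.null(learning_rate)) cfg$learning_rate else learning_rate
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  n <- nrow(x)
  if (length(y) != n) {
    stop_kelp("length(y) must match nrow(x)", class = "kelptrace_argument_error")
  }
  if (!all(y %in% 0:(cfg$n_classes - 1L))) {
    stop_kelp("labels must be integer codes in 0..n_classes-1",
              class = "kelptrace_argument_error")
  }
  y_onehot <- matrix(0, n, cfg$n_classes)
  y_onehot[cbind(seq_len(n), y + 1L)] <- 1

  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-7
  m_t <- lapply(model$weights, function(p) p * 0)
  v_t <- lapply(model$weights, function(p) p * 0)
  t_step <- 0L

  if (!is.null(seed)) set.seed(seed)
  hist_loss <- numeric(epochs)
  hist_acc <- numeric(epochs)

  for (epoch in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1L, n)]
      bk <- cnn_backward(model, x[idx, , drop = FALSE],
                         y_onehot[idx, , drop = FALSE])
      if (!is.finite(bk$loss)) {
        stop_kelp(sprintf("non-finite loss at epoch %d; aborting training", epoch),
                  class = "kelptrace_numeric_error")
      }
      t_step <- t_step + 1L
      bc1 <- 1 - beta1^t_step
      bc2 <- 1 - beta2^t_step
      for (p in names(model$weights)) {
        g <- bk$grads[[p]]
        m_t[[p]] <- beta1 * m_t[[p]] + (1 - beta1) * g
        v_t[[p]] <- beta2 * v_t[[p]] + (1 - beta2) * g^2
        model$weights[[p]] <- model$weights[[p]] -
          lr * (m_t[[p]] / bc1) / (sqrt(v_t[[p]] / bc2) + adam_eps)
      }
    }
    probs <- cnn_forward(model, x)
    hist_loss[epoch] <- -mean(log(rowSums(probs * y_onehot) + 1e-12))
    hist_acc[epoch] <- mean(max.col(probs, ties.method = "first") - 1L == y)
  }

  model$history <- tibble::tibble(
    epoch = seq_len(epochs), loss = hist_loss, accuracy = hist_acc
  )
  model
}

#' Fit the origin classifier to a standardized cohort
#'
#' Data-frame front end: takes a cohort tibble whose feature columns have
#' already been standardized (see [fit_scaler()]), builds the network sized
#' to the cohort's feature count, and trains it.
#'
#' @param data A cohort tibble with `origin` labels and feature columns.
#' @param config A [cnn_config()]; its `input_len` is checked against the
#'   cohort's feature count.
#' @param ... Passed to [cnn_train()] (e.g. `epochs`, `seed`).
#' @return A trained `kelp_cnn` carrying `feature_ids` and `history`.
#' @export
fit_origin_cnn <- function(data, config = NULL, ...) {
  ids <- cohort_feature_ids(data)
  if (is.null(config)) {
    config <- cnn_config(input_len = length(ids))
  } else if (config$input_len != length(ids)) {
    stop_kelp(sprintf("config expects %d features but data has %d",
                      config$input_len, length(ids)),
              class = "kelptrace_config_error")
  }
  model <- build_cnn(config)
  model <- cnn_train(model, cohort_matrix(data), data$origin, ...)
  model$feature_ids <- ids
  model
}

#' Predict origin class probabilities
#'
#' @param object A `kelp_cnn`.
#' @param newdata A numeric matrix, a cohort tibble, or a single feature
#'   vector (already standardized with the training scaler).
#' @param type `"prob"` for a tibble of class probabilities, `"class"` for
#'   integer labels (argmax, ties to the lowest class index), `"matrix"` for
#'   the raw probability matrix.
#' @param ... Unused.
#' @export
predict.kelp_cnn <- function(object, newdata, type = c("prob", "class", "matrix"),
                             ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    ids <- if (!is.null(object$feature_ids)) object$feature_ids else
      cohort_feature_ids(newdata)
    newdata <- as.matrix(newdata[ids])
    storage.mode(newdata) <- "double"
  }
  probs <- cnn_forward(object, newdata)
  if (type == "matrix") return(probs)
  if (type == "class") return(max.col(probs, ties.method = "first") - 1L)
  colnames(probs) <- paste0("p_", names(.kelp_origins)[seq_len(ncol(probs))])
  tibble::as_tibble(probs)
}

#' Pre-softmax (logit) predictor for a model
#'
#' Returns a function mapping an input matrix to the network's pre-softmax
#' scores. Useful for attributing on the logit scale instead of probability
#' units, e.g. `shap_permutation(logit_predictor(model), ...)`.
#'
#' @param model A `kelp_cnn`.
#' @return A function: input matrix -> n x n_classes logit matrix.
#' @export
logit_predictor <- function(model) {
  if (!inherits(model, "kelp_cnn")) {
    stop_kelp("`model` must be a kelp_cnn", class = "kelptrace_argument_error")
  }
  function(x) cnn_forward(model, x, output = "logit")
}

#' Count trainable parameters
#' @param model A `kelp_cnn`.
#' @return Integer: total number of weights and biases.
#' @export
#' @examples
#' count_params(build_cnn(cnn_config(seed = 1)))  # 3067
count_params <- function(model) {
  sum(vapply(model$weights, length, integer(1L)))
}

#' Count forward-pass FLOPs
#'
#' Static floating-point operation count for one forward pass under the
#' documented convention: 2 FLOPs per multiply-accumulate in convolutions
#' (`2 * K * C_in * C_out * L_out`) and dense layers (`2 * n_in * n_out`),
#' plus one addition per bias application, plus `pool_len` comparisons per
#' max-pool output element; activation and softmax operations are excluded.
#'
#' @param model A `kelp_cnn`.
#' @return Integer FLOP count (16083 for the default architecture).
#' @export
count_flops <- function(model) {
  cfg <- model$config
  geom <- cnn_geometry(cfg)
  k <- cfg$kernel_len
  f1 <- cfg$conv_filters[1L]
  f2 <- cfg$conv_filters[2L]
  conv1 <- 2L * k * 1L * f1 * geom$l1 + geom$l1 * f1
  pool1 <- geom$p1 * f1 * cfg$pool_len
  conv2 <- 2L * k * f1 * f2 * geom$l2 + geom$l2 * f2
  pool2 <- geom$p2 * f2 * cfg$pool_len
  dense1 <- 2L * cfg$flatten_len * cfg$dense_units + cfg$dense_units
  dense2 <- 2L * cfg$dense_units * cfg$n_classes + cfg$n_classes
  conv1 + pool1 + conv2 + pool2 + dense1 + dense2
}

#' @export
print.kelp_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("1D-CNN origin classifier: input %d -> conv(%d)x%d -> pool%d -> conv(%d)x%d -> pool%d -> flatten %d -> dense %d -> softmax %d\n",
              cfg$input_len, cfg$kernel_len, cfg$conv_filters[1L], cfg$pool_len,
              cfg$kernel_len, cfg$conv_filters[2L], cfg$pool_len,
              cfg$flatten_len, cfg$dense_units, cfg$n_classes))
  cat(sprintf("parameters: %d (%.1f K); forward FLOPs: %d (%.1f K)%s\n",
              count_params(x), count_params(x) / 1000,
              count_flops(x), count_flops(x) / 1000,
              if (is.null(x$history)) " [untrained]" else ""))
  invisible(x)
}

#' Per-layer parameter and FLOP breakdown
#' @param x A `kelp_cnn`.
#' @param ... Unused.
#' @method tidy kelp_cnn
#' @export
tidy.kelp_cnn <- function(x, ...) {
  cfg <- x$config
  geom <- cnn_geometry(cfg)
  k <- cfg$kernel_len; f1 <- cfg$conv_filters[1L]; f2 <- cfg$conv_filters[2L]
  tibble::tibble(
    layer = c("conv1", "pool1", "conv2", "pool2", "dense1", "dense2"),
    output_shape = c(sprintf("%d x %d", geom$l1, f1), sprintf("%d x %d", geom$p1, f1),
                     sprintf("%d x %d", geom$l2, f2), sprintf("%d x %d", geom$p2, f2),
                     as.character(cfg$dense_units), as.character(cfg$n_classes)),
    n_params = c((k + 1L) * f1, 0L, (k * f1 + 1L) * f2, 0L,
                 (cfg$flatten_len + 1L) * cfg$dense_units,
                 (cfg$dense_units + 1L) * cfg$n_classes),
    flops = c(2L * k * f1 * geom$l1 + geom$l1 * f1,
              geom$p1 * f1 * cfg$pool_len,
              2L * k * f1 * f2 * geom$l2 + geom$l2 * f2,
              geom$p2 * f2 * cfg$pool_len,
              2L * cfg$flatten_len * cfg$dense_units + cfg$dense_units,
              2L * cfg$dense_units * cfg$n_classes + cfg$n_classes)
  )
}

#' One-row model summary
#' @param x A `kelp_cnn`.
#' @param ... Unused.
#' @method glance kelp_cnn
#' @export
glance.kelp_cnn <- function(x, ...) {
  tibble::tibble(
    n_params = count_params(x),
    flops = count_flops(x),
    flatten_len = x$config$flatten_len,
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)],
    final_accuracy = if (is.null(x$history)) NA_real_ else
      x$history$accuracy[nrow(x$history)]
  )
}

#' Serialize / restore a model
#'
#' Weights and config are written to a single JSON file with layer-named
#' arrays at full precision; `read_cnn()` restores an identical model.
#'
#' @param model A `kelp_cnn`.
#' @param path JSON output path.
#' @return `path` invisibly; `read_cnn()` returns the model.
#' @export
write_cnn <- function(model, path) {
  cfg <- model$config
  payload <- list(
    config = unclass(cfg),
    weights = lapply(model$weights, function(p) {
      if (is.array(p) || is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = length(p), data = as.vector(p))
    }),
    feature_ids = model$feature_ids
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_cnn
#' @export
read_cnn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_args <- payload$config
  cfg <- cnn_config(
    input_len = cfg_args$input_len, conv_filters = cfg_args$conv_filters,
    kernel_len = cfg_args$kernel_len, pool_len = cfg_args$pool_len,
    dense_units = cfg_args$dense_units, n_classes = cfg_args$n_classes,
    learning_rate = cfg_args$learning_rate, epochs = cfg_args$epochs,
    batch_size = cfg_args$batch_size, seed = cfg_args$seed
  )
  weights <- lapply(payload$weights, function(p) {
    if (length(p$dim) > 1L) array(p$data, dim = p$dim) else as.numeric(p$data)
  })
  structure(list(config = cfg, weights = weights,
                 feature_ids = payload$feature_ids, history = NULL),
            class = "kelp_cnn")
}
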