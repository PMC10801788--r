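# Model substrate: initialization, forward/backward passes, training,
# validation. Dense and convolutional layers only; the output layer is a
# linear dense layer read through a softmax cross-entropy loss.
#
# Two forward paths exist on purpose. Training uses BLAS `%*%` for speed.
# Prediction/validation uses det_matmul(), whose fixed accumulation order
# makes unit surgery on zero-weight units bitwise function-preserving.

#' Build an initialized (untrained) classifier from a spec
#'
#' Weights are He-initialized (`rnorm * sqrt(2 / fan_in)`), biases zero;
#' construction is reproducible given `seed`.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization (`NULL` uses the
#'   current RNG stream).
#' @return A `jgrs_model`: the spec plus per-layer weight/bias tensors and
#'   recorded layer shapes.
#' @export
build_model <- function(spec, seed = NULL) {
  if (!inherits(spec, "model_spec")) {
    stop_jgrs("`spec` must be a model_spec", "jgrs_config_error")
  }
  with_seed(seed, {
    layers <- list()
    if (spec$kind == "mlp") {
      in_dim <- spec$input_shape
      for (l in spec$hidden_layers) {
        layers[[length(layers) + 1L]] <- init_dense(in_dim, l$units, l$activation)
        in_dim <- l$units
      }
    } else {
      shape <- spec$input_shape # c(channels, H, W)
      dense_in <- NULL
      for (l in spec$hidden_layers) {
        if (l$layer_kind == "conv") {
          kh <- l$kernel[1]; kw <- l$kernel[2]
          h_out <- shape[2] - kh + 1L
          w_out <- shape[3] - kw + 1L
          if (h_out < 1 || w_out < 1) {
            stop_jgrs("conv kernel larger than its input map", "jgrs_config_error")
          }
          if (!is.null(l$pool)) {
            h_out <- h_out %/% l$pool
            w_out <- w_out %/% l$pool
            if (h_out < 1 || w_out < 1) {
              stop_jgrs("pooling collapses the feature map below 1x1",
                        "jgrs_config_error")
            }
          }
          layers[[length(layers) + 1L]] <- init_conv(
            cin = shape[1], filters = l$units, kernel = l$kernel,
            activation = l$activation, pool = l$pool,
            in_hw = shape[2:3], out_hw = c(h_out, w_out))
          shape <- c(l$units, h_out, w_out)
        } else {
          if (is.null(dense_in)) dense_in <- prod(shape)
          layers[[length(layers) + 1L]] <- init_dense(dense_in, l$units,
                                                      l$activation)
          dense_in <- l$units
        }
      }
      if (is.null(dense_in)) dense_in <- prod(shape)
      in_dim <- dense_in
    }
    layers[[length(layers) + 1L]] <- init_dense(in_dim, spec$num_classes,
                                                "linear")
    structure(
      list(spec = spec, layers = layers, num_classes = spec$num_classes,
           input_shape = spec$input_shape, seed = seed),
      class = "jgrs_model"
    )
  })
}

init_dense <- function(in_dim, out_dim, activation) {
  list(kind = "dense",
       W = matrix(stats::rnorm(in_dim * out_dim, sd = sqrt(2 / in_dim)),
                  in_dim, out_dim),
       b = numeric(out_dim),
       activation = activation)
}

init_conv <- function(cin, filters, kernel, activation, pool, in_hw, out_hw) {
  kh <- kernel[1]; kw <- kernel[2]
  fan_in <- kh * kw * cin
  list(kind = "conv",
       W = array(stats::rnorm(kh * kw * cin * filters, sd = sqrt(2 / fan_in)),
                 dim = c(kh, kw, cin, filters)),
       b = numeric(filters),
       activation = activation, pool = pool,
       in_hw = as.integer(in_hw), out_hw = as.integer(out_hw))
}

n_hidden <- function(model) length(model$layers) - 1L

unit_count_layer <- function(model, layer) {
  lay <- model$layers[[layer]]
  if (lay$kind == "dense") ncol(lay$W) else dim(lay$W)[4]
}

# ---- forward passes ---------------------------------------------------------

apply_activation <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else z
}

# x: n x (C*H*W) matrix, channel-major flatten -> array (n, H, W, C)
as_image_array <- function(x, shape) {
  n <- nrow(x)
  a <- array(x, dim = c(n, shape[2], shape[3], shape[1]))
  a
}

conv_forward <- function(x4, lay, det = FALSE) {
  dm <- dim(x4)
  n <- dm[1]
  kh <- dim(lay$W)[1]; kw <- dim(lay$W)[2]
  cin <- dim(lay$W)[3]; nf <- dim(lay$W)[4]
  h_out <- dm[2] - kh + 1L
  w_out <- dm[3] - kw + 1L
  wmat <- matrix(lay$W, ncol = nf)
  bmat <- matrix(lay$b, n, nf, byrow = TRUE)
  out <- array(0, dim = c(n, h_out, w_out, nf))
  for (i in seq_len(h_out)) {
    for (j in seq_len(w_out)) {
      patch <- x4[, i:(i + kh - 1L), j:(j + kw - 1L), , drop = FALSE]
      dim(patch) <- c(n, kh * kw * cin)
      z <- if (det) det_matmul(patch, wmat) else patch %*% wmat
      out[, i, j, ] <- z + bmat
    }
  }
  out
}

pool_forward <- function(a4, p) {
  dm <- dim(a4)
  n <- dm[1]; nf <- dm[4]
  hp <- dm[2] %/% p; wp <- dm[3] %/% p
  out <- array(-Inf, dim = c(n, hp, wp, nf))
  for (i in seq_len(hp)) {
    for (j in seq_len(wp)) {
      for (di in seq_len(p)) {
        for (dj in seq_len(p)) {
          out[, i, j, ] <- pmax(out[, i, j, ],
                                a4[, (i - 1L) * p + di, (j - 1L) * p + dj, ])
        }
      }
    }
  }
  out
}

# Forward pass to logits. det = TRUE uses the order-stable matmul.
forward_logits <- function(model, x, det = FALSE) {
  if (ncol(x) != prod(model$input_shape)) {
    stop_jgrs(sprintf("input has %d features, model expects %d",
                      ncol(x), prod(model$input_shape)), "jgrs_data_error")
  }
  a <- x
  in_conv <- model$spec$kind == "cnn"
  x4 <- if (in_conv) as_image_array(x, model$input_shape) else NULL
  for (lay in model$layers) {
    if (lay$kind == "conv") {
      z <- conv_forward(x4, lay, det = det)
      z <- apply_activation(z, lay$activation)
      if (!is.null(lay$pool)) z <- pool_forward(z, lay$pool)
      x4 <- z
    } else {
      if (in_conv) {
        a <- x4
        dim(a) <- c(dim(x4)[1], prod(dim(x4)[-1]))
        in_conv <- FALSE
      }
      z <- (if (det) det_matmul(a, lay$W) else a %*% lay$W) +
        matrix(lay$b, nrow(a), length(lay$b), byrow = TRUE)
      a <- apply_activation(z, lay$activation)
    }
  }
  a
}

#' Predict from a model
#'
#' @param object A `jgrs_model`.
#' @param newdata Numeric matrix of samples by features (CNN inputs are
#'   flattened channel-major).
#' @param type `"class"` (0-based label), `"prob"` (softmax) or `"logits"`.
#' @param ... Unused.
#' @return Vector of class labels or a matrix of probabilities/logits.
#' @export
predict.jgrs_model <- function(object, newdata, type = c("class", "prob", "logits"),
                               ...) {
  type <- match.arg(type)
  logits <- forward_logits(object, newdata, det = TRUE)
  if (type == "logits") return(logits)
  if (type == "prob") return(softmax(logits))
  apply(logits, 1L, which.max) - 1L
}

softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- training ---------------------------------------------------------------

#' Training hyperparameters
#'
#' The pruning schedule is agnostic to how retraining is done; these defaults
#' (mini-batch Adam) are chosen so that the decoding tasks in this package
#' train in seconds while leaving retraining genuinely stochastic, which the
#' randomized pruning baselines rely on.
#'
#' @param epochs Epochs for initial training.
#' @param fine_tune_epochs Epochs for each retraining (fine-tuning) call.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size (clamped to the sample count).
#' @param seed Optional seed applied inside each training call; `NULL` (the
#'   default) draws shuffling randomness from the current RNG stream so that
#'   one algorithm-level seed governs a whole pruning run.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 40L, fine_tune_epochs = 6L,
                         learning_rate = 0.01, batch_size = 128L,
                         seed = NULL) {
  if (epochs < 1 || fine_tune_epochs < 1 || learning_rate <= 0 || batch_size < 1) {
    stop_jgrs("training hyperparameters must be positive", "jgrs_config_error")
  }
  structure(list(epochs = as.integer(epochs),
                 fine_tune_epochs = as.integer(fine_tune_epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = seed),
            class = "train_config")
}

#' Bundle a feature matrix and binary labels
#'
#' @param x Numeric matrix, samples by features.
#' @param y Integer labels in `0:(num_classes-1)`.
#' @return A `data_pair`.
#' @export
as_data_pair <- function(x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) {
    stop_jgrs("feature rows and label length differ", "jgrs_data_error")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_jgrs("data contain missing values", "jgrs_data_error")
  }
  structure(list(x = x, y = y), class = "data_pair")
}

check_pair <- function(data, model = NULL) {
  if (!inherits(data, "data_pair")) data <- as_data_pair(data$x, data$y)
  if (nrow(data$x) == 0L) stop_jgrs("empty data split", "jgrs_data_error")
  if (!is.null(model) && ncol(data$x) != prod(model$input_shape)) {
    stop_jgrs("data feature shape does not match model input shape",
              "jgrs_data_error")
  }
  data
}

#' Train a model from its current weights
#'
#' `train_model()` performs initial training of an overparameterized network
#' and increments the global `train` counter; [fine_tune()] retrains a pruned
#' model warm-starting from its surviving weights (so learned forward paths
#' are inherited, not re-initialized) and increments the `fine_tune` counter.
#'
#' @param model A `jgrs_model`.
#' @param data A `data_pair` (typically the training split).
#' @param cfg A [train_config()].
#' @return The trained `jgrs_model`.
#' @export
train_model <- function(model, data, cfg = train_config()) {
  data <- check_pair(data, model)
  bump_counter("train")
  with_seed(cfg$seed, sgd_fit(model, data$x, data$y, cfg$epochs,
                              cfg$learning_rate, cfg$batch_size))
}

#' @rdname train_model
#' @export
fine_tune <- function(model, data, cfg = train_config()) {
  data <- check_pair(data, model)
  bump_counter("fine_tune")
  with_seed(cfg$seed, sgd_fit(model, data$x, data$y, cfg$fine_tune_epochs,
                              cfg$learning_rate, cfg$batch_size))
}

#' Validation accuracy of a model on a data split
#'
#' @param model A `jgrs_model`.
#' @param data A `data_pair` (validation or test split).
#' @return Fraction of correctly predicted labels, in `[0, 1]`; deterministic
#'   for fixed model and data.
#' @export
validate <- function(model, data) {
  data <- check_pair(data, model)
  bump_counter("validate")
  pred <- predict.jgrs_model(model, data$x, type = "class")
  mean(pred == data$y)
}

# Mini-batch Adam on softmax cross-entropy.
sgd_fit <- function(model, x, y, epochs, lr, batch_size,
                    beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  n <- nrow(x)
  y1 <- y + 1L
  batch_size <- min(batch_size, n)
  mstate <- lapply(model$layers, function(l) list(W = array(0, dim(as.array(l$W))),
                                                  b = numeric(length(l$b))))
  vstate <- mstate
  t <- 0L
  for (ep in seq_len(epochs)) {
    ord <- if (epochs > 0) sample.int(n) else seq_len(n)
    nb <- ceiling(n / batch_size)
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
      grads <- backward_pass(model, x[idx, , drop = FALSE], y1[idx])
      t <- t + 1L
      for (li in seq_along(model$layers)) {
        for (nm in c("W", "b")) {
          g <- grads[[li]][[nm]]
          mstate[[li]][[nm]] <- beta1 * mstate[[li]][[nm]] + (1 - beta1) * g
          vstate[[li]][[nm]] <- beta2 * vstate[[li]][[nm]] + (1 - beta2) * g^2
          mhat <- mstate[[li]][[nm]] / (1 - beta1^t)
          vhat <- vstate[[li]][[nm]] / (1 - beta2^t)
          model$layers[[li]][[nm]] <- model$layers[[li]][[nm]] -
            lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
  }
  model
}

# Backward pass; returns per-layer gradients of mean cross-entropy.
backward_pass <- function(model, x, y1) {
  n <- nrow(x)
  nl <- length(model$layers)
  caches <- vector("list", nl)
  in_conv <- model$spec$kind == "cnn"
  x4 <- if (in_conv) as_image_array(x, model$input_shape) else NULL
  a <- x
  flat_from <- NULL
  for (li in seq_len(nl)) {
    lay <- model$layers[[li]]
    if (lay$kind == "conv") {
      pre <- conv_forward(x4, lay, det = FALSE)
      act <- apply_activation(pre, lay$activation)
      pooled <- if (!is.null(lay$pool)) pool_forward(act, lay$pool) else act
      caches[[li]] <- list(input = x4, pre = pre, act = act, out = pooled)
      x4 <- pooled
    } else {
      if (in_conv) {
        a <- x4
        flat_dim <- dim(x4)
        dim(a) <- c(n, prod(flat_dim[-1]))
        in_conv <- FALSE
        flat_from <- li
        flat_shape <- flat_dim
      }
      pre <- a %*% lay$W + matrix(lay$b, n, length(lay$b), byrow = TRUE)
      act <- apply_activation(pre, lay$activation)
      caches[[li]] <- list(input = a, pre = pre)
      a <- act
    }
  }
  probs <- softmax(a)
  delta <- probs
  delta[cbind(seq_len(n), y1)] <- delta[cbind(seq_len(n), y1)] - 1
  delta <- delta / n
  grads <- vector("list", nl)
  for (li in rev(seq_len(nl))) {
    lay <- model$layers[[li]]
    if (lay$kind == "dense") {
      if (li < nl) {
        # delta currently w.r.t. this layer's activation output
        delta <- delta * relu_grad(caches[[li]]$pre, lay$activation)
      }
      grads[[li]] <- list(W = crossprod(caches[[li]]$input, delta),
                          b = colSums(delta))
      delta <- delta %*% t(lay$W)
      if (!is.null(flat_from) && li == flat_from) {
        dim(delta) <- flat_shape
      }
    } else {
      cache <- caches[[li]]
      d4 <- delta # gradient w.r.t. pooled output, array
      if (!is.null(lay$pool)) {
        d4 <- pool_backward(cache$act, cache$out, d4, lay$pool)
      }
      d4 <- d4 * relu_grad(cache$pre, lay$activation)
      cb <- conv_backward(cache$input, lay, d4)
      grads[[li]] <- list(W = cb$dW, b = cb$db)
      delta <- cb$dx
    }
  }
  grads
}

relu_grad <- function(pre, activation) {
  if (activation == "relu") (pre > 0) * 1 else array(1, dim(as.array(pre)))
}

pool_backward <- function(act, pooled, dpooled, p) {
  dm <- dim(act)
  dact <- array(0, dm)
  hp <- dim(pooled)[2]; wp <- dim(pooled)[3]
  for (i in seq_len(hp)) {
    for (j in seq_len(wp)) {
      maxv <- pooled[, i, j, , drop = FALSE]
      dv <- dpooled[, i, j, , drop = FALSE]
      # count ties within the window, then split gradient equally
      cnt <- array(0, dim(maxv))
      for (di in seq_len(p)) {
        for (dj in seq_len(p)) {
          cnt <- cnt + (act[, (i - 1L) * p + di, (j - 1L) * p + dj, ,
                            drop = FALSE] == maxv)
        }
      }
      for (di in seq_len(p)) {
        for (dj in seq_len(p)) {
          hit <- act[, (i - 1L) * p + di, (j - 1L) * p + dj, ,
                     drop = FALSE] == maxv
          dact[, (i - 1L) * p + di, (j - 1L) * p + dj, ] <-
            dact[, (i - 1L) * p + di, (j - 1L) * p + dj, ] +
            (dv * hit / cnt)[, 1L, 1L, ]
        }
      }
    }
  }
  dact
}

conv_backward <- function(x4, lay, d4) {
  dmx <- dim(x4)
  n <- dmx[1]
  kh <- dim(lay$W)[1]; kw <- dim(lay$W)[2]
  cin <- dim(lay$W)[3]; nf <- dim(lay$W)[4]
  h_out <- dim(d4)[2]; w_out <- dim(d4)[3]
  wmat <- matrix(lay$W, ncol = nf)
  dwmat <- matrix(0, nrow(wmat), nf)
  db <- numeric(nf)
  dx <- array(0, dmx)
  for (i in seq_len(h_out)) {
    for (j in seq_len(w_out)) {
      patch <- x4[, i:(i + kh - 1L), j:(j + kw - 1L), , drop = FALSE]
      dim(patch) <- c(n, kh * kw * cin)
      dz <- matrix(d4[, i, j, ], n, nf)
      dwmat <- dwmat + crossprod(patch, dz)
      db <- db + colSums(dz)
      dpatch <- dz %*% t(wmat)
      dim(dpatch) <- c(n, kh, kw, cin)
      dx[, i:(i + kh - 1L), j:(j + kw - 1L), ] <-
        dx[, i:(i + kh - 1L), j:(j + kw - 1L), , drop = FALSE] + dpatch
    }
  }
  list(dW = array(dwmat, dim = dim(lay$W)), db = db, dx = dx)
}

#' @export
print.jgrs_model <- function(x, ...) {
  cat(sprintf("<jgrs_model> %s; hidden units [%s]; %d params, %d FLOPs\n",
              x$spec$kind, paste(hidden_units(x), collapse = ","),
              param_count(x), flop_count(x)))
  invisible(x)
}
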