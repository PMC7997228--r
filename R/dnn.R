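DNN_ACTIVATIONS <- c("elu", "selu", "softplus", "softsign", "relu", "tanh",
                     "hard_sigmoid")
DNN_OPTIMIZERS <- c("RMSprop", "Adam", "Adamax", "SGD", "Nadam", "Adadelta",
                    "Adagrad")
DNN_INITIALIZERS <- c("uniform", "normal", "lecun_uniform", "glorot_uniform",
                      "glorot_normal", "he_normal", "he_uniform")

#' Deep neural network configuration
#'
#' Hyper-parameter assignment for the fully connected classifier: two or
#' three hidden layers, each followed by dropout, then a one-unit sigmoid
#' output trained with binary cross-entropy.  The defaults are the reference
#' network used throughout the encoder/selection sweeps (ReLU activation,
#' Adam optimizer, two hidden layers); the tunable ranges mirror the
#' hyper-parameter search space (see [default_search_space()]).
#'
#' @param layers number of hidden layers, 2 or 3.
#' @param hidden_1,hidden_2,hidden_3 hidden-layer widths (`hidden_3`
#'   required iff `layers = 3`).
#' @param activation hidden activation: one of `r paste(DNN_ACTIVATIONS, collapse = ", ")`.
#' @param optimizer one of `r paste(DNN_OPTIMIZERS, collapse = ", ")`.
#' @param learning_rate optimizer step size.
#' @param kernel_initializer weight-initialization scheme: one of
#'   `r paste(DNN_INITIALIZERS, collapse = ", ")`.
#' @param dropout dropout rate in `(0, 1)` after each hidden layer.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param seed RNG seed driving initialization, shuffling and dropout masks.
#' @return a validated `m6aDnnConfig` list.
#' @export
dnn_config <- function(layers = 2L, hidden_1 = 128L, hidden_2 = 64L,
                       hidden_3 = NULL, activation = "relu",
                       optimizer = "Adam", learning_rate = 0.001,
                       kernel_initializer = "glorot_uniform",
                       dropout = 0.2, epochs = 30L, batch_size = 80L,
                       seed = 1L) {
  layers <- as.integer(layers)
  if (!layers %in% c(2L, 3L)) stop("layers must be 2 or 3")
  if (layers == 3L && is.null(hidden_3))
    stop("hidden_3 must be set when layers = 3")
  if (!activation %in% DNN_ACTIVATIONS)
    stop(sprintf("unknown activation '%s'; valid: %s", activation,
                 paste(DNN_ACTIVATIONS, collapse = ", ")))
  if (!optimizer %in% DNN_OPTIMIZERS)
    stop(sprintf("unknown optimizer '%s'; valid: %s", optimizer,
                 paste(DNN_OPTIMIZERS, collapse = ", ")))
  if (!kernel_initializer %in% DNN_INITIALIZERS)
    stop(sprintf("unknown kernel_initializer '%s'; valid: %s",
                 kernel_initializer,
                 paste(DNN_INITIALIZERS, collapse = ", ")))
  if (dropout <= 0 || dropout >= 1) stop("dropout must be in (0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(layers = layers, hidden_1 = as.integer(hidden_1),
                 hidden_2 = as.integer(hidden_2),
                 hidden_3 = if (layers == 3L) as.integer(hidden_3) else NULL,
                 activation = activation, optimizer = optimizer,
                 learning_rate = learning_rate,
                 kernel_initializer = kernel_initializer,
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "m6aDnnConfig")
}

activation_fns <- function(name) {
  switch(name,
    relu = list(f = function(z) pmax(z, 0),
                g = function(z, a) (z > 0) * 1),
    tanh = list(f = tanh,
                g = function(z, a) 1 - a^2),
    elu = list(f = function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1),
               g = function(z, a) ifelse(z > 0, 1, a + 1)),
    selu = {
      lam <- 1.0507009873554805
      alf <- 1.6732632423543772
      list(f = function(z) lam * ifelse(z > 0, z, alf * (exp(pmin(z, 0)) - 1)),
           g = function(z, a) ifelse(z > 0, lam, a + lam * alf))
    },
    softplus = list(f = function(z) log1p(exp(-abs(z))) + pmax(z, 0),
                    g = function(z, a) 1 / (1 + exp(-z))),
    softsign = list(f = function(z) z / (1 + abs(z)),
                    g = function(z, a) 1 / (1 + abs(z))^2),
    hard_sigmoid = list(f = function(z) pmin(pmax(0.2 * z + 0.5, 0), 1),
                        g = function(z, a) (z > -2.5 & z < 2.5) * 0.2),
    stop("unknown activation"))
}

init_weights <- function(scheme, fan_in, fan_out, rng) {
  unif <- function(lim) rng$runif(fan_in * fan_out, -lim, lim)
  norm <- function(sd) rng$rnorm(fan_in * fan_out, 0, sd)
  w <- switch(scheme,
    uniform = unif(0.05),
    normal = norm(0.05),
    lecun_uniform = unif(sqrt(3 / fan_in)),
    glorot_uniform = unif(sqrt(6 / (fan_in + fan_out))),
    glorot_normal = norm(sqrt(2 / (fan_in + fan_out))),
    he_normal = norm(sqrt(2 / fan_in)),
    he_uniform = unif(sqrt(6 / fan_in)),
    stop("unknown initializer"))
  matrix(w, fan_in, fan_out)
}

#' Build an (untrained) deep neural network
#'
#' Fully connected stack `input -> hidden_1 -> dropout -> hidden_2 ->
#' dropout [-> hidden_3 -> dropout] -> 1-unit sigmoid`.  Weights are drawn
#' by the configured initializer from the configuration seed, so identical
#' config + seed gives identical initial weights.
#'
#' @param config an [dnn_config()].
#' @param input_dim number of input features.
#' @return an `m6aDnn` object (weights `W`, biases `b`, `config`,
#'   `input_dim`, `trained`, `loss_trace`).
#' @export
build_dnn <- function(config, input_dim) {
  stopifnot(inherits(config, "m6aDnnConfig"))
  input_dim <- as.integer(input_dim)
  if (input_dim < 1L) stop("input_dim must be >= 1")
  widths <- c(input_dim, config$hidden_1, config$hidden_2,
              if (config$layers == 3L) config$hidden_3, 1L)
  rng <- local_rng(config$seed)
  W <- b <- vector("list", length(widths) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- init_weights(config$kernel_initializer, widths[l],
                           widths[l + 1L], rng)
    b[[l]] <- numeric(widths[l + 1L])
  }
  structure(list(W = W, b = b, config = config, input_dim = input_dim,
                 trained = FALSE, loss_trace = numeric(0)),
            class = "m6aDnn")
}

#' @export
print.m6aDnn <- function(x, ...) {
  widths <- c(x$input_dim, vapply(x$W, ncol, integer(1)))
  cat(sprintf("m6aDnn (%s): %s; %s/%s lr=%g dropout=%g [%s]\n",
              if (x$trained) "trained" else "untrained",
              paste(widths, collapse = "-"),
              x$config$activation, x$config$optimizer,
              x$config$learning_rate, x$config$dropout,
              x$config$kernel_initializer))
  invisible(x)
}

dnn_forward <- function(model, X, dropout_masks = NULL) {
  act <- activation_fns(model$config$activation)
  n_hidden <- length(model$W) - 1L
  A <- X
  Zs <- As <- vector("list", length(model$W))
  for (l in seq_len(n_hidden)) {
    Z <- sweep(A %*% model$W[[l]], 2L, model$b[[l]], "+")
    A <- act$f(Z)
    if (!is.null(dropout_masks)) A <- A * dropout_masks[[l]]
    Zs[[l]] <- Z
    As[[l]] <- A
  }
  lo <- length(model$W)
  Zout <- sweep(A %*% model$W[[lo]], 2L, model$b[[lo]], "+")
  p <- 1 / (1 + exp(-Zout))
  list(p = p, Zs = Zs, As = As)
}

make_optimizer <- function(name, lr) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- st$v <- st$d <- NULL
  zeros_like <- function(params) lapply(params, function(p) p * 0)
  eps <- 1e-7
  function(params, grads) {
    st$t <- st$t + 1L
    if (is.null(st$m)) {
      st$m <- zeros_like(params)
      st$v <- zeros_like(params)
      st$d <- zeros_like(params)
    }
    t <- st$t
    for (i in seq_along(params)) {
      g <- grads[[i]]
      params[[i]] <- switch(name,
        SGD = params[[i]] - lr * g,
        Adagrad = {
          st$v[[i]] <- st$v[[i]] + g^2
          params[[i]] - lr * g / (sqrt(st$v[[i]]) + eps)
        },
        RMSprop = {
          st$v[[i]] <- 0.9 * st$v[[i]] + 0.1 * g^2
          params[[i]] - lr * g / (sqrt(st$v[[i]]) + eps)
        },
        Adadelta = {
          st$v[[i]] <- 0.95 * st$v[[i]] + 0.05 * g^2
          upd <- sqrt(st$d[[i]] + eps) / sqrt(st$v[[i]] + eps) * g
          st$d[[i]] <- 0.95 * st$d[[i]] + 0.05 * upd^2
          params[[i]] - lr * upd
        },
        Adam = {
          st$m[[i]] <- 0.9 * st$m[[i]] + 0.1 * g
          st$v[[i]] <- 0.999 * st$v[[i]] + 0.001 * g^2
          mhat <- st$m[[i]] / (1 - 0.9^t)
          vhat <- st$v[[i]] / (1 - 0.999^t)
          params[[i]] - lr * mhat / (sqrt(vhat) + eps)
        },
        Adamax = {
          st$m[[i]] <- 0.9 * st$m[[i]] + 0.1 * g
          st$v[[i]] <- pmax(0.999 * st$v[[i]], abs(g))
          params[[i]] - lr / (1 - 0.9^t) * st$m[[i]] / (st$v[[i]] + eps)
        },
        Nadam = {
          st$m[[i]] <- 0.9 * st$m[[i]] + 0.1 * g
          st$v[[i]] <- 0.999 * st$v[[i]] + 0.001 * g^2
          mhat <- st$m[[i]] / (1 - 0.9^(t + 1L))
          vhat <- st$v[[i]] / (1 - 0.999^t)
          params[[i]] - lr * (0.9 * mhat + 0.1 * g / (1 - 0.9^t)) /
            (sqrt(vhat) + eps)
        },
        stop("unknown optimizer"))
    }
    params
  }
}

#' Train a deep neural network
#'
#' Minimizes mean binary cross-entropy by minibatch gradient descent with
#' the configured optimizer.  Inverted dropout is applied after every
#' hidden layer during training only.  `epochs = 0` returns the model with
#' its initial weights; a non-finite loss aborts with the offending epoch.
#'
#' @param model an `m6aDnn` from [build_dnn()].
#' @param X training feature matrix.
#' @param y 0/1 labels.
#' @param config training configuration; defaults to the one the model was
#'   built with.
#' @return the trained `m6aDnn` with a per-epoch `loss_trace`.
#' @export
train_dnn <- function(model, X, y, config = model$config) {
  stopifnot(inherits(model, "m6aDnn"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) == 0L) stop("empty training matrix")
  if (ncol(X) != model$input_dim)
    stop(sprintf("X has %d columns but the model expects %d", ncol(X),
                 model$input_dim))
  if (!all(is.finite(X))) stop("X contains non-finite values")
  n <- nrow(X)
  act <- activation_fns(config$activation)
  step <- make_optimizer(config$optimizer, config$learning_rate)
  rng <- local_rng(config$seed + 1L)
  n_hidden <- length(model$W) - 1L
  keep <- 1 - config$dropout
  loss_trace <- numeric(0)
  W <- model$W
  b <- model$b
  if (config$epochs > 0L) for (epoch in seq_len(config$epochs)) {
    perm <- rng$sample_int(n)
    starts <- seq(1L, n, by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      nb <- length(idx)
      masks <- lapply(seq_len(n_hidden), function(l) {
        width <- ncol(W[[l]])
        matrix((rng$runif(nb * width) < keep) / keep, nb, width)
      })
      # forward
      A <- Xb
      Zs <- As_in <- vector("list", n_hidden)
      for (l in seq_len(n_hidden)) {
        As_in[[l]] <- A
        Z <- sweep(A %*% W[[l]], 2L, b[[l]], "+")
        A <- act$f(Z) * masks[[l]]
        Zs[[l]] <- Z
      }
      lo <- n_hidden + 1L
      Zout <- sweep(A %*% W[[lo]], 2L, b[[lo]], "+")
      p <- as.numeric(1 / (1 + exp(-Zout)))
      pe <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      epoch_loss <- epoch_loss -
        sum(yb * log(pe) + (1 - yb) * log(1 - pe))
      # backward
      gW <- gb <- vector("list", lo)
      delta <- matrix((p - yb) / nb, nb, 1L)
      gW[[lo]] <- crossprod(A, delta)
      gb[[lo]] <- colSums(delta)
      back <- delta %*% t(W[[lo]])
      for (l in rev(seq_len(n_hidden))) {
        a_l <- act$f(Zs[[l]])
        dZ <- back * masks[[l]] * act$g(Zs[[l]], a_l)
        gW[[l]] <- crossprod(As_in[[l]], dZ)
        gb[[l]] <- colSums(dZ)
        if (l > 1L) back <- dZ %*% t(W[[l]])
      }
      upd <- step(c(W, b), c(gW, gb))
      W <- upd[seq_len(lo)]
      b <- upd[lo + seq_len(lo)]
    }
    epoch_loss <- epoch_loss / n
    if (!is.finite(epoch_loss))
      stop(sprintf("non-finite training loss at epoch %d", epoch))
    loss_trace <- c(loss_trace, epoch_loss)
  }
  model$W <- W
  model$b <- b
  model$trained <- TRUE
  model$loss_trace <- loss_trace
  model
}

#' Predict class probabilities
#'
#' Forward pass with dropout disabled; outputs are sigmoid probabilities in
#' `[0, 1]`.
#'
#' @param model a (trained) `m6aDnn`.
#' @param X feature matrix with the training column count.
#' @return numeric vector of probabilities.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "m6aDnn"))
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim)
    stop(sprintf("X has %d columns but the model expects %d", ncol(X),
                 model$input_dim))
  as.numeric(dnn_forward(model, X)$p)
}

#' @export
predict.m6aDnn <- function(object, newdata, type = c("prob", "class"),
                           threshold = 0.5, ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else as.integer(p >= threshold)
}
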