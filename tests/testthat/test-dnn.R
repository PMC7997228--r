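toy_separable <- function(n = 100, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(y * 2 - 1 + rnorm(n, sd = 0.2), rnorm(n))
  colnames(X) <- c("signal", "noise")
  list(X = X, y = y)
}

test_that("build_dnn realizes the configured architecture deterministically", {
  cfg <- dnn_config(layers = 2, hidden_1 = 116, hidden_2 = 697, seed = 3)
  net <- build_dnn(cfg, input_dim = 50)
  expect_equal(vapply(net$W, dim, integer(2)),
               matrix(c(50, 116, 116, 697, 697, 1), 2))
  net2 <- build_dnn(cfg, input_dim = 50)
  expect_identical(net$W, net2$W)
  cfg3 <- dnn_config(layers = 3, hidden_1 = 30, hidden_2 = 20,
                     hidden_3 = 10)
  expect_equal(length(build_dnn(cfg3, 5)$W), 4L)
  expect_error(dnn_config(layers = 3), "hidden_3")
  expect_error(dnn_config(activation = "swish"), "relu")
  expect_error(dnn_config(optimizer = "AdamW"), "Nadam")
  expect_error(dnn_config(kernel_initializer = "orthogonal"), "he_normal")
})

test_that("training fits a separable toy problem to perfect accuracy", {
  dd <- toy_separable(seed = 5)
  cfg <- dnn_config(hidden_1 = 16, hidden_2 = 8, epochs = 100,
                    batch_size = 20, seed = 2)
  net <- train_dnn(build_dnn(cfg, 2), dd$X, dd$y)
  acc <- mean((predict_proba(net, dd$X) >= 0.5) == (dd$y == 1))
  expect_equal(acc, 1.0)
  # loss trace decreases overall, allowing small minibatch upticks;
  # near-zero dropout isolates the optimizer from mask-resampling noise
  cfg2 <- dnn_config(hidden_1 = 16, hidden_2 = 8, epochs = 100,
                     batch_size = 20, dropout = 0.01, seed = 2)
  tr <- train_dnn(build_dnn(cfg2, 2), dd$X, dd$y)$loss_trace
  expect_length(tr, 100L)
  expect_lt(tr[length(tr)], 0.1 * tr[1])
  # near-monotone: any single uptick stays within 5% of the total descent
  expect_lte(max(diff(tr)), 0.05 * (tr[1] - min(tr)))
})

test_that("epochs = 0 leaves the initial weights untouched", {
  cfg <- dnn_config(hidden_1 = 8, hidden_2 = 4, epochs = 0, seed = 1)
  net0 <- build_dnn(cfg, 3)
  dd <- toy_separable(20, seed = 2)
  net <- train_dnn(net0, dd$X[, 1:2] |> cbind(1), dd$y)
  expect_identical(net$W, net0$W)
  expect_identical(net$b, net0$b)
})

test_that("every activation, optimizer and initializer trains", {
  dd <- toy_separable(40, seed = 7)
  for (act in c("elu", "selu", "softplus", "softsign", "relu", "tanh",
                "hard_sigmoid")) {
    cfg <- dnn_config(hidden_1 = 6, hidden_2 = 4, activation = act,
                      epochs = 2, batch_size = 20, seed = 1)
    net <- train_dnn(build_dnn(cfg, 2), dd$X, dd$y)
    expect_true(all(is.finite(net$loss_trace)), info = act)
  }
  for (opt in c("RMSprop", "Adam", "Adamax", "SGD", "Nadam", "Adadelta",
                "Adagrad")) {
    cfg <- dnn_config(hidden_1 = 6, hidden_2 = 4, optimizer = opt,
                      epochs = 2, batch_size = 20, seed = 1)
    net <- train_dnn(build_dnn(cfg, 2), dd$X, dd$y)
    expect_true(all(is.finite(net$loss_trace)), info = opt)
  }
  for (ini in c("uniform", "normal", "lecun_uniform", "glorot_uniform",
                "glorot_normal", "he_normal", "he_uniform")) {
    cfg <- dnn_config(hidden_1 = 6, hidden_2 = 4,
                      kernel_initializer = ini, epochs = 1,
                      batch_size = 20, seed = 1)
    expect_true(all(is.finite(
      train_dnn(build_dnn(cfg, 2), dd$X, dd$y)$loss_trace)), info = ini)
  }
})

test_that("inference is a pure sigmoid forward pass", {
  dd <- toy_separable(30, seed = 9)
  cfg <- dnn_config(hidden_1 = 6, hidden_2 = 4, epochs = 5,
                    batch_size = 10, seed = 4)
  net <- train_dnn(build_dnn(cfg, 2), dd$X, dd$y)
  p <- predict_proba(net, dd$X)
  expect_true(all(p >= 0 & p <= 1))
  # duplicate rows score identically (no dropout at inference)
  expect_identical(predict_proba(net, dd$X[c(1, 1), ]),
                   rep(predict_proba(net, dd$X[1, , drop = FALSE]), 2))
  # zero weights give sigmoid(0) = 0.5 everywhere
  net$W <- lapply(net$W, function(w) w * 0)
  net$b <- lapply(net$b, function(b) b * 0)
  expect_equal(predict_proba(net, dd$X), rep(0.5, 30))
  expect_error(predict_proba(net, dd$X[, 1, drop = FALSE]), "columns")
})

test_that("metrics match the closed-form cases", {
  m <- compute_metrics(rep(c(1, 0), each = 50),
                       rep(c(0.9, 0.1), each = 50))
  expect_equal(c(m$ACC, m$MCC, m$AUC), c(1, 1, 1))
  m2 <- compute_metrics(rep(c(1, 0), each = 50), rep(0.9, 100))
  expect_equal(c(m2$Sn, m2$Sp, m2$ACC, m2$MCC, m2$AUC),
               c(1, 0, 0.5, 0, 0.5))
  expect_warning(m3 <- compute_metrics(rep(1, 10), runif(10)), "single")
  expect_true(is.nan(m3$Sp) && is.nan(m3$AUC))
})

test_that("metrics equal brute-force enumeration on random draws", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # rounding forces ties
    got <- compute_metrics(y, s)
    want <- oracle_metrics(y, s)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], info = f, tolerance = 1e-12)
  }
})

test_that("AUC is rank-based: transform-invariant and 0.5 under noise", {
  set.seed(17)
  y <- rbinom(300, 1, 0.5)
  s <- runif(300)
  a1 <- compute_metrics(y, s)$AUC
  a2 <- compute_metrics(y, plogis(5 * s - 2))$AUC  # strictly increasing
  expect_equal(a1, a2)
  y_big <- rbinom(10000, 1, 0.5)
  expect_equal(compute_metrics(y_big, runif(10000))$AUC, 0.5,
               tolerance = 0.02)
})
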