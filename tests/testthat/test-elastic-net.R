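make_design <- function(n = 60, d = 8, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  colnames(X) <- paste0("f", seq_len(d))
  y <- as.numeric(X[, 1] * 0.8 - X[, 2] * 0.5 + rnorm(n, sd = 0.3) > 0)
  list(X = X, y = y)
}

test_that("penalties at or above alpha_max kill every coefficient", {
  dd <- make_design(seed = 2)
  n <- nrow(dd$X)
  Xs <- scale(dd$X, scale = apply(dd$X, 2, function(c)
    sqrt(mean((c - mean(c))^2))))
  beta <- 0.7
  alpha_max <- max(abs(crossprod(Xs, dd$y - mean(dd$y)))) / (n * beta)
  fit <- fit_elastic_net(dd$X, dd$y, alpha = alpha_max * 1.001, beta = beta)
  expect_length(fit$selected, 0)
  fit2 <- fit_elastic_net(dd$X, dd$y, alpha = alpha_max * 0.5, beta = beta)
  expect_gt(length(fit2$selected), 0)
})

test_that("beta = 0 reproduces the ridge closed form", {
  dd <- make_design(n = 50, d = 10, seed = 3)
  n <- nrow(dd$X)
  alpha <- 0.3
  Xc <- scale(dd$X, scale = FALSE)
  yc <- dd$y - mean(dd$y)
  w_exact <- solve(crossprod(Xc) + n * alpha * diag(ncol(Xc)),
                   crossprod(Xc, yc))
  # the fit does not center internally when standardize = FALSE, so feed
  # the centered design directly
  fit_c <- fit_elastic_net(Xc, dd$y, alpha = alpha, beta = 0,
                           standardize = FALSE, tol = 1e-10)
  expect_equal(unname(fit_c$coef), as.numeric(w_exact), tolerance = 1e-6)
})

test_that("beta = 1 on an orthonormal design equals soft thresholding", {
  set.seed(4)
  n <- 80; d <- 20
  Q <- qr.Q(qr(matrix(rnorm(n * d), n, d))) * sqrt(n)  # X'X/n = I
  y <- as.numeric(Q %*% c(rep(0.5, 3), rep(0, d - 3)) + rnorm(n, sd = 0.2))
  yc <- y - mean(y)
  alpha <- 0.1
  fit <- fit_elastic_net(Q, y, alpha = alpha, beta = 1,
                         standardize = FALSE, tol = 1e-10)
  w_oracle <- sapply(seq_len(d), function(j) {
    z <- mean(Q[, j] * yc)
    sign(z) * max(abs(z) - alpha, 0)
  })
  expect_equal(unname(fit$coef), w_oracle, tolerance = 1e-6)
})

test_that("informative features survive while noise is dropped", {
  hits <- 0; noise_kept <- numeric(0)
  for (sd in 1:20) {
    set.seed(sd)
    n <- 200
    y <- rep(c(0, 1), each = n / 2)
    X <- cbind(y + rnorm(n, sd = 0.1),
               matrix(rnorm(n * 50), n, 50))
    colnames(X) <- paste0("f", 0:50)
    fit <- fit_elastic_net(X, y, alpha = 0.05, beta = 0.5)
    hits <- hits + (1 %in% fit$selected)
    noise_kept <- c(noise_kept, sum(fit$selected > 1) / 50)
  }
  expect_equal(hits, 20)
  expect_lte(mean(noise_kept), 0.10)
})

test_that("the coordinate-descent objective never increases", {
  dd <- make_design(n = 100, d = 30, seed = 6)
  fit <- fit_elastic_net(dd$X, dd$y, alpha = 0.02, beta = 0.5,
                         track_objective = TRUE)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-12))
  expect_true(fit$converged)
})

test_that("selection respects invariants and apply_selection contracts", {
  dd <- make_design(seed = 7)
  fit <- fit_elastic_net(dd$X, dd$y, alpha = 0.02, beta = 0.5)
  expect_setequal(fit$selected, which(fit$coef != 0))
  Xr <- apply_selection(dd$X, fit)
  expect_equal(colnames(Xr), names(fit$coef)[fit$selected])
  expect_error(apply_selection(dd$X[, 1:3], fit), "mismatch")
  allzero <- fit_elastic_net(dd$X, dd$y, alpha = 50, beta = 0.5)
  expect_error(apply_selection(dd$X, allzero), "smaller alpha")
  expect_error(fit_elastic_net(dd$X, dd$y, alpha = -1), "alpha")
  expect_error(fit_elastic_net(dd$X, rep(1, nrow(dd$X)), alpha = 0.1),
               "classes")
})

test_that("heavier lasso-dominant penalties select no more features", {
  s <- tiny_seqset(40, seed = 9)
  p1 <- fit_propensity(s, 1); p2 <- fit_propensity(s, 2)
  X <- encode_all(s, psnp_model = p1, psdp_model = p2)
  d_small <- length(fit_elastic_net(X, s$labels, 0.01, 0.8)$selected)
  d_large <- length(fit_elastic_net(X, s$labels, 0.1, 0.8)$selected)
  expect_lte(d_large, d_small)
})

test_that("sweep_alpha records the grid, breaks ties and is deterministic", {
  set.seed(11)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(y + rnorm(n, sd = 0.15), matrix(rnorm(n * 20), n, 20))
  colnames(X) <- paste0("f", 0:20)
  folds <- stratified_kfold(y, k = 3, seed = 1)
  cfg <- dnn_config(hidden_1 = 8, hidden_2 = 4, epochs = 10,
                    batch_size = 20, seed = 1)
  sw <- sweep_alpha(X, y, grid = c(0.02, 0.05), beta = 0.5, folds = folds,
                    config = cfg)
  expect_equal(nrow(sw$table), 2L)
  expect_true(all(sw$table$valid))
  expect_true(sw$chosen_alpha %in% c(0.02, 0.05))
  sw2 <- sweep_alpha(X, y, grid = c(0.02, 0.05), beta = 0.5,
                     folds = folds, config = cfg)
  expect_identical(sw$table, sw2$table)
  # single-value grid chooses that value
  sw1 <- sweep_alpha(X, y, grid = 0.05, beta = 0.5, folds = folds,
                     config = cfg)
  expect_equal(sw1$chosen_alpha, 0.05)
  expect_error(sweep_alpha(X, y, grid = numeric(0), folds = folds), "empty")
})
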