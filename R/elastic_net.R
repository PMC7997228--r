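#' Elastic-net feature selection
#'
#' Fits the penalized least-squares objective
#' \deqn{\min_w \frac{1}{2n}\lVert y - Xw\rVert_2^2
#'       + \alpha\beta \lVert w\rVert_1
#'       + \frac{\alpha(1-\beta)}{2}\lVert w\rVert_2^2}
#' by cyclic coordinate descent on the 0/1 labels treated as a continuous
#' response.  `beta = 0` is ridge regression, `beta = 1` the lasso.
#' Features are standardized internally (population mean/scale, stored for
#' test-time reuse) and coefficients are reported on the standardized scale;
#' the surviving feature set is `{j : w_j != 0}`.
#'
#' @param X numeric feature matrix (samples x features).
#' @param y 0/1 labels.
#' @param alpha non-negative overall penalty weight.
#' @param beta L1/L2 mixing fraction in `[0, 1]` (default 0.5).
#' @param standardize center and scale features before fitting (default
#'   `TRUE`).  Disable only for pre-whitened designs.
#' @param tol convergence: maximum absolute coefficient change per sweep
#'   (default 1e-6).
#' @param max_iter maximum coordinate-descent sweeps (default 1000).
#' @param track_objective record the objective after every sweep (for
#'   diagnostics; default `FALSE`).
#' @return an `m6aSelection` object: `alpha`, `beta`, `coef` (named, on the
#'   standardized scale), `intercept`, `selected` (indices of nonzero
#'   coefficients), `center`, `scale`, `converged`, `n_iter`, and optionally
#'   `objective_trace`.
#' @export
fit_elastic_net <- function(X, y, alpha, beta = 0.5, standardize = TRUE,
                            tol = 1e-6, max_iter = 1000L,
                            track_objective = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (alpha < 0) stop("alpha must be non-negative")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (length(y) != nrow(X)) stop("X and y disagree in length")
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  n <- nrow(X)
  d <- ncol(X)
  if (standardize) {
    center <- colMeans(X)
    scale_ <- sqrt(colMeans(X^2) - center^2)
    scale_[scale_ < 1e-12] <- 1   # constant columns stay at coefficient 0
    Xs <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  } else {
    center <- rep(0, d)
    scale_ <- rep(1, d)
    Xs <- X
  }
  ybar <- mean(y)
  yc <- y - ybar
  # covariance-mode coordinate descent: G = X'X/n, q = X'y/n
  G <- crossprod(Xs) / n
  q <- as.numeric(crossprod(Xs, yc)) / n
  w <- numeric(d)
  v <- numeric(d)              # v = G %*% w, maintained incrementally
  l1 <- alpha * beta
  l2 <- alpha * (1 - beta)
  gjj <- diag(G)
  obj_trace <- if (track_objective) numeric(0) else NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    max_delta <- 0
    for (j in seq_len(d)) {
      if (gjj[j] < 1e-12) next
      rho <- q[j] - v[j] + gjj[j] * w[j]
      wj <- soft_threshold(rho, l1) / (gjj[j] + l2)
      delta <- wj - w[j]
      if (delta != 0) {
        v <- v + G[, j] * delta
        w[j] <- wj
        max_delta <- max(max_delta, abs(delta))
      }
    }
    if (track_objective)
      obj_trace <- c(obj_trace,
                     elastic_net_objective(Xs, yc, w, alpha, beta))
    if (max_delta < tol) {
      converged <- TRUE
      break
    }
  }
  w_named <- w
  names(w_named) <- colnames(X)
  structure(list(alpha = alpha, beta = beta, coef = w_named,
                 intercept = ybar, selected = which(w != 0),
                 center = center, scale = scale_,
                 standardize = standardize,
                 converged = converged, n_iter = it,
                 objective_trace = obj_trace),
            class = "m6aSelection")
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Elastic-net objective value
#'
#' Evaluates `1/(2n) ||y - Xw||^2 + alpha*beta ||w||_1 +
#' alpha*(1-beta)/2 ||w||^2` for a given coefficient vector; used by the
#' convergence diagnostics and tests.
#'
#' @param X design matrix (already centered/standardized as intended).
#' @param y centered response.
#' @param w coefficient vector.
#' @param alpha,beta penalty parameters.
#' @return the scalar objective value.
#' @export
elastic_net_objective <- function(X, y, w, alpha, beta) {
  n <- nrow(X)
  r <- y - as.numeric(X %*% w)
  sum(r^2) / (2 * n) + alpha * beta * sum(abs(w)) +
    alpha * (1 - beta) / 2 * sum(w^2)
}

#' @export
print.m6aSelection <- function(x, ...) {
  cat(sprintf(
    "m6aSelection: alpha = %g, beta = %g; %d / %d features retained (%s)\n",
    x$alpha, x$beta, length(x$selected), length(x$coef),
    if (x$converged) sprintf("converged in %d sweeps", x$n_iter)
    else "NOT converged"))
  invisible(x)
}

#' Restrict a feature matrix to the selected features
#'
#' @param X feature matrix whose columns match the fitted model.
#' @param model an [fit_elastic_net()] selection model.
#' @return `X` restricted to the surviving columns (names and encoder tags
#'   preserved).
#' @export
apply_selection <- function(X, model) {
  stopifnot(inherits(model, "m6aSelection"))
  if (ncol(X) != length(model$coef))
    stop(sprintf("feature count mismatch: matrix has %d, model has %d",
                 ncol(X), length(model$coef)))
  if (length(model$selected) == 0L)
    stop("selection model retained no features; refit with a smaller alpha")
  tags <- attr(X, "encoder_tags")
  out <- X[, model$selected, drop = FALSE]
  if (!is.null(tags)) attr(out, "encoder_tags") <- tags[model$selected]
  out
}

#' Cross-validated sweep over the elastic-net penalty grid
#'
#' For every `alpha` in the grid, fits the selection model on each training
#' fold, trains the downstream DNN on the surviving features, and records
#' the mean held-out accuracy and the mean selected dimension.  The chosen
#' `alpha` maximizes CV accuracy; ties break toward the smaller dimension,
#' then the smaller `alpha`.  A fit failure marks that `alpha` invalid
#' rather than aborting the sweep.
#'
#' @param X fused feature matrix.
#' @param y 0/1 labels.
#' @param grid numeric vector of `alpha` values (default the canonical
#'   `0.01 .. 0.1` grid).
#' @param beta L1/L2 mix (default 0.5).
#' @param folds an [stratified_kfold()] assignment.
#' @param config downstream [dnn_config()] (default the reference
#'   two-hidden-layer relu/Adam network).
#' @return an `m6aAlphaSweep` object: `table` (data frame with `alpha`,
#'   `cv_accuracy`, `dimension`, `valid`) and `chosen_alpha`.
#' @export
sweep_alpha <- function(X, y, grid = seq(0.01, 0.1, by = 0.01), beta = 0.5,
                        folds, config = dnn_config()) {
  if (length(grid) == 0L) stop("empty alpha grid")
  stopifnot(inherits(folds, "m6aFolds"))
  res <- data.frame(alpha = grid, cv_accuracy = NA_real_,
                    dimension = NA_real_, valid = FALSE)
  for (gi in seq_along(grid)) {
    a <- grid[gi]
    accs <- dims <- numeric(0)
    ok <- TRUE
    for (f in seq_len(folds$k)) {
      test_idx <- which(folds$fold == f)
      train_idx <- which(folds$fold != f)
      acc <- tryCatch({
        sel <- fit_elastic_net(X[train_idx, , drop = FALSE], y[train_idx],
                               alpha = a, beta = beta)
        if (length(sel$selected) == 0L)
          stop("no features retained")
        Xtr <- apply_selection(X[train_idx, , drop = FALSE], sel)
        Xte <- apply_selection(X[test_idx, , drop = FALSE], sel)
        net <- train_dnn(build_dnn(config, ncol(Xtr)), Xtr, y[train_idx])
        p <- predict_proba(net, Xte)
        dims <- c(dims, length(sel$selected))
        mean((p >= 0.5) == (y[test_idx] == 1L))
      }, error = function(e) NA_real_)
      if (is.na(acc)) {
        ok <- FALSE
        break
      }
      accs <- c(accs, acc)
    }
    if (ok) {
      res$cv_accuracy[gi] <- mean(accs)
      res$dimension[gi] <- mean(dims)
      res$valid[gi] <- TRUE
    }
  }
  chosen <- NA_real_
  if (any(res$valid)) {
    v <- res[res$valid, ]
    v <- v[order(-v$cv_accuracy, v$dimension, v$alpha), ]
    chosen <- v$alpha[1L]
  }
  structure(list(table = res, chosen_alpha = chosen, beta = beta),
            class = "m6aAlphaSweep")
}

#' @export
print.m6aAlphaSweep <- function(x, ...) {
  cat("m6aAlphaSweep (chosen alpha =", x$chosen_alpha, ")\n")
  print(x$table)
  invisible(x)
}
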