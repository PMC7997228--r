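#' Train the full m6A prediction pipeline
#'
#' End-to-end orchestration: encode all eight feature sets, fuse, fit the
#' elastic-net selection, optionally tune the DNN hyper-parameters with
#' TPE, train the final network on all training data, and estimate
#' performance by stratified fold-safe cross-validation.  The returned
#' bundle contains everything needed to score new sequences without
#' refitting: encoder parameters, the propensity matrices, the selection
#' model (with its standardization), and the trained network.
#'
#' @param seqset training data as an [m6a_seqset()] (e.g. from
#'   [read_sample_files()] or [generate_synthetic()]).
#' @param params encoder parameters ([encoder_params()]).
#' @param selection list with `alpha`, `beta` (default `alpha = 0.05`,
#'   `beta = 0.5`), or `NULL` to skip selection.
#' @param config the final [dnn_config()]; ignored when `tune` is given.
#' @param tune `NULL`, or a list with `n_trials` (and optionally `space`,
#'   `gamma`, `n_startup`, `cv_k`): runs [tpe_optimize()] with
#'   `1 - mean CV accuracy` as the loss and uses the best configuration.
#' @param k,seed cross-validation folds and master seed.
#' @param out_dir optional directory: the bundle is saved there via
#'   [save_bundle()].
#' @param verbose log per-stage dimensions.
#' @return an `m6aBundle` list: `params`, `psnp_model`, `psdp_model`,
#'   `selection_model`, `dnn`, `cv` (an `m6aCv`), `config`, `manifest`.
#' @export
m6a_train <- function(seqset, params = encoder_params(),
                      selection = list(alpha = 0.05, beta = 0.5),
                      config = dnn_config(), tune = NULL,
                      k = 5L, seed = 1L, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(seqset, "m6aSeqSet"))
  say <- function(...) if (verbose) message(sprintf(...))
  say("stage encode: %d sequences of length %d", length(seqset), seqset$L)
  y <- seqset$labels
  psnp_model <- fit_propensity(seqset, 1L)
  psdp_model <- fit_propensity(seqset, 2L)
  X <- fuse(c(encode_static(seqset, params),
              list(encode_psnp(seqset, psnp_model),
                   encode_psdp(seqset, psdp_model))))
  say("stage fuse: initial dimension %d", ncol(X))
  sel_model <- NULL
  Xsel <- X
  if (!is.null(selection)) {
    sel_model <- fit_elastic_net(X, y, alpha = selection$alpha,
                                 beta = selection$beta)
    Xsel <- apply_selection(X, sel_model)
    say("stage select: alpha %g, beta %g -> %d features",
        selection$alpha, selection$beta, ncol(Xsel))
  }
  if (!is.null(tune)) {
    space <- tune$space %||% default_search_space()
    cv_k <- tune$cv_k %||% k
    tune_folds <- stratified_kfold(y, k = cv_k, seed = seed)
    objective <- function(cfg) {
      dc <- do.call(dnn_config, c(cfg, list(seed = seed)))
      accs <- numeric(tune_folds$k)
      for (f in seq_len(tune_folds$k)) {
        te <- which(tune_folds$fold == f)
        tr <- which(tune_folds$fold != f)
        net <- train_dnn(build_dnn(dc, ncol(Xsel)),
                         Xsel[tr, , drop = FALSE], y[tr])
        p <- predict_proba(net, Xsel[te, , drop = FALSE])
        accs[f] <- mean((p >= 0.5) == (y[te] == 1L))
      }
      1 - mean(accs)
    }
    say("stage tune: TPE over %d trials", tune$n_trials)
    opt <- tpe_optimize(objective, space, n_trials = tune$n_trials,
                        seed = seed, gamma = tune$gamma %||% 0.25,
                        n_startup = tune$n_startup %||% 10L)
    config <- do.call(dnn_config, c(opt$best_config, list(seed = seed)))
    say("stage tune: best CV accuracy %.4f", 1 - opt$best_loss)
  }
  say("stage cv: %d-fold fold-safe cross-validation", k)
  cv <- cross_validate(seqset, k = k, seed = seed, params = params,
                       selection = selection, config = config)
  say("stage cv: mean ACC %.4f AUC %.4f", cv$mean$ACC, cv$mean$AUC)
  net <- train_dnn(build_dnn(config, ncol(Xsel)), Xsel, y)
  bundle <- structure(list(
    params = params, psnp_model = psnp_model, psdp_model = psdp_model,
    selection_model = sel_model, dnn = net, cv = cv, config = config,
    manifest = list(
      package = "m6aFuse",
      version = as.character(utils::packageVersion("m6aFuse")),
      r_version = R.version.string,
      n_train = length(seqset), L = seqset$L, seed = as.integer(seed),
      k = as.integer(k), initial_dim = ncol(X), final_dim = ncol(Xsel),
      selection = selection, created = format(Sys.time(), tz = "UTC"))),
    class = "m6aBundle")
  if (!is.null(out_dir)) save_bundle(bundle, out_dir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.m6aBundle <- function(x, ...) {
  cat(sprintf("m6aBundle: L = %d, %d -> %d features; CV ACC %.4f AUC %.4f\n",
              x$manifest$L, x$manifest$initial_dim, x$manifest$final_dim,
              x$cv$mean$ACC, x$cv$mean$AUC))
  invisible(x)
}

#' Score sequences with a trained bundle
#'
#' Applies the stored propensity matrices, selection and network; never
#' refits anything, so the bundle is read-only.
#'
#' @param bundle an `m6aBundle` from [m6a_train()] or [load_bundle()].
#' @param x an [m6a_seqset()], character vector of sequences, or a FASTA
#'   path.
#' @param threshold positive-call threshold (default 0.5).
#' @return data frame with `id`, `probability`, `label`.
#' @export
m6a_predict <- function(bundle, x, threshold = 0.5) {
  stopifnot(inherits(bundle, "m6aBundle"))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    rec <- read_fasta_records(x, expected_length = bundle$manifest$L)
    x <- m6a_seqset(rec$sequences, labels = rep(0L, length(rec$sequences)),
                    ids = rec$ids, check_center = FALSE)
  } else if (!inherits(x, "m6aSeqSet")) {
    x <- m6a_seqset(x, labels = rep(0L, length(x)), check_center = FALSE)
  }
  if (x$L != bundle$manifest$L)
    stop(sprintf("sequence length %d does not match the bundle (%d)",
                 x$L, bundle$manifest$L))
  X <- fuse(c(encode_static(x, bundle$params),
              list(encode_psnp(x, bundle$psnp_model),
                   encode_psdp(x, bundle$psdp_model))))
  if (!is.null(bundle$selection_model))
    X <- apply_selection(X, bundle$selection_model)
  p <- predict_proba(bundle$dnn, X)
  data.frame(id = x$ids, probability = p,
             label = as.integer(p >= threshold))
}

#' Evaluate a trained bundle on held-out positive/negative files
#'
#' Mirrors the independent-dataset protocol: the stored encoders, selection
#' and network are applied unchanged to a disjoint labeled set and the full
#' metric suite is reported.
#'
#' @param bundle an `m6aBundle`.
#' @param pos,neg FASTA paths or `m6aSeqSet`s of positive / negative
#'   samples (when `pos` is an `m6aSeqSet` with both classes, `neg` may be
#'   omitted).
#' @param threshold classification threshold.
#' @return an [compute_metrics()] report.
#' @export
m6a_evaluate <- function(bundle, pos, neg = NULL, threshold = 0.5) {
  stopifnot(inherits(bundle, "m6aBundle"))
  if (inherits(pos, "m6aSeqSet") && is.null(neg)) {
    testset <- pos
  } else {
    testset <- read_sample_files(pos, neg,
                                 expected_length = bundle$manifest$L,
                                 check_center = FALSE)
  }
  scored <- m6a_predict(bundle, testset, threshold = threshold)
  compute_metrics(testset$labels, scored$probability, threshold)
}

#' Grid sweep of the encoder parameters
#'
#' Grid-evaluates the KSNPF spacing `k_max` and the PseDNC `(lambda, w)`
#' pair by cross-validated accuracy of the reference DNN trained on that
#' single encoder's features (the protocol used to pick per-dataset encoder
#' parameters).  Ties break toward the smaller parameter values.
#'
#' @param seqset an [m6a_seqset()].
#' @param k_max_grid KSNPF spacings (default `1:5`).
#' @param lambda_grid,w_grid PseDNC grids (defaults `c(10, 20, 30)` and
#'   `seq(0.1, 0.9, 0.2)`).
#' @param config the reference [dnn_config()].
#' @param k,seed cross-validation controls.
#' @return list with data frames `ksnpf` (`k_max`, `cv_accuracy`, `best`)
#'   and `psednc` (`lambda`, `w`, `cv_accuracy`, `best`).
#' @export
sweep_encoder_params <- function(seqset, k_max_grid = 1:5,
                                 lambda_grid = c(10L, 20L, 30L),
                                 w_grid = seq(0.1, 0.9, by = 0.2),
                                 config = dnn_config(), k = 5L, seed = 1L) {
  stopifnot(inherits(seqset, "m6aSeqSet"))
  if (length(k_max_grid) == 0L || length(lambda_grid) == 0L ||
      length(w_grid) == 0L)
    stop("empty parameter grid")
  y <- seqset$labels
  folds <- stratified_kfold(y, k = k, seed = seed)
  cv_acc <- function(X) {
    accs <- numeric(folds$k)
    for (f in seq_len(folds$k)) {
      te <- which(folds$fold == f)
      tr <- which(folds$fold != f)
      net <- train_dnn(build_dnn(config, ncol(X)), X[tr, , drop = FALSE],
                       y[tr])
      p <- predict_proba(net, X[te, , drop = FALSE])
      accs[f] <- mean((p >= 0.5) == (y[te] == 1L))
    }
    mean(accs)
  }
  ks <- data.frame(k_max = k_max_grid, cv_accuracy = NA_real_)
  for (i in seq_along(k_max_grid))
    ks$cv_accuracy[i] <- cv_acc(encode_ksnpf(seqset, k_max_grid[i]))
  ks$best <- seq_len(nrow(ks)) ==
    order(-ks$cv_accuracy, ks$k_max)[1L]
  grid <- expand.grid(lambda = lambda_grid, w = w_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$lambda, grid$w), , drop = FALSE]
  rownames(grid) <- NULL
  grid$cv_accuracy <- NA_real_
  for (i in seq_len(nrow(grid)))
    grid$cv_accuracy[i] <- cv_acc(
      encode_psednc(seqset, lambda = grid$lambda[i], w = grid$w[i]))
  grid$best <- seq_len(nrow(grid)) ==
    order(-grid$cv_accuracy, grid$lambda, grid$w)[1L]
  list(ksnpf = ks, psednc = grid)
}

# --- bundle persistence (plain JSON, documented layout) ------------------

#' Save / load a trained pipeline bundle
#'
#' The bundle persists as a directory of plain JSON files:
#' `manifest.json`, `encoder_params.json`, `propensity.json` (both Z
#' matrices), `selection.json` (coefficients + standardization) and
#' `dnn.json` (architecture and full-precision weights).
#'
#' @param bundle an `m6aBundle`.
#' @param dir target / source directory.
#' @return `save_bundle()` returns `dir` invisibly; `load_bundle()` returns
#'   the reconstructed `m6aBundle` (without the CV report, which is a
#'   training-time artifact).
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "m6aBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f)
    jsonlite::write_json(x, file.path(dir, f), auto_unbox = TRUE,
                         digits = NA, null = "null")
  wj(bundle$manifest, "manifest.json")
  wj(bundle$params, "encoder_params.json")
  wj(list(psnp = list(order = 1L, L = bundle$psnp_model$L,
                      Z = bundle$psnp_model$Z),
          psdp = list(order = 2L, L = bundle$psdp_model$L,
                      Z = bundle$psdp_model$Z)),
     "propensity.json")
  sm <- bundle$selection_model
  wj(if (is.null(sm)) NULL else
       list(alpha = sm$alpha, beta = sm$beta, coef = unname(sm$coef),
            feature_names = names(sm$coef), intercept = sm$intercept,
            selected = sm$selected, center = sm$center, scale = sm$scale,
            standardize = sm$standardize),
     "selection.json")
  cfg <- bundle$config
  wj(list(config = unclass(cfg), input_dim = bundle$dnn$input_dim,
          W = bundle$dnn$W, b = bundle$dnn$b,
          loss_trace = bundle$dnn$loss_trace),
     "dnn.json")
  wj(as.data.frame(bundle$cv$mean), "cv_metrics.json")
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  rj <- function(f) jsonlite::read_json(file.path(dir, f),
                                        simplifyVector = TRUE)
  needed <- c("manifest.json", "encoder_params.json", "propensity.json",
              "selection.json", "dnn.json")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing))
    stop(sprintf("incomplete bundle %s: missing %s", dir,
                 paste(missing, collapse = ", ")))
  manifest <- rj("manifest.json")
  params <- rj("encoder_params.json")
  params$k_max <- as.integer(params$k_max)
  params$enac_window <- as.integer(params$enac_window)
  params$lambda <- as.integer(params$lambda)
  prop <- rj("propensity.json")
  mk_prop <- function(p, rn) {
    Z <- as.matrix(p$Z)
    rownames(Z) <- rn
    structure(list(order = as.integer(p$order), L = as.integer(p$L), Z = Z),
              class = "m6aPropensity")
  }
  psnp <- mk_prop(prop$psnp, RNA_BASES)
  psdp <- mk_prop(prop$psdp, RNA_DINUCS)
  selj <- rj("selection.json")
  sel <- NULL
  if (!is.null(selj) && length(selj)) {
    coefs <- as.numeric(selj$coef)
    names(coefs) <- selj$feature_names
    sel <- structure(list(alpha = selj$alpha, beta = selj$beta,
                          coef = coefs, intercept = selj$intercept,
                          selected = as.integer(selj$selected),
                          center = as.numeric(selj$center),
                          scale = as.numeric(selj$scale),
                          standardize = isTRUE(selj$standardize),
                          converged = TRUE, n_iter = NA_integer_,
                          objective_trace = NULL),
                     class = "m6aSelection")
  }
  dnj <- rj("dnn.json")
  cfg_list <- dnj$config
  cfg <- do.call(dnn_config, cfg_list[!vapply(cfg_list, is.null,
                                              logical(1))])
  net <- structure(list(W = lapply(dnj$W, as.matrix),
                        b = lapply(dnj$b, as.numeric),
                        config = cfg,
                        input_dim = as.integer(dnj$input_dim),
                        trained = TRUE,
                        loss_trace = as.numeric(dnj$loss_trace)),
                   class = "m6aDnn")
  structure(list(params = params, psnp_model = psnp, psdp_model = psdp,
                 selection_model = sel, dnn = net, cv = NULL, config = cfg,
                 manifest = manifest),
            class = "m6aBundle")
}
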