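#' Fold-safe stratified cross-validation of the full pipeline
#'
#' For each fold: the label-dependent components — the PSNP/PSDP propensity
#' matrices and the elastic-net selection model — are refitted on the
#' training portion only, the DNN is trained on the selected training
#' features, and the held-out portion is scored.  The label-independent
#' encoders (BE, KSNPF, ENAC, NCP, PseDNC, TNC) are computed once up front.
#' Reported metrics are per-fold plus their fold-mean (confusion counts
#' summed, rates averaged); pooled metrics over the concatenated held-out
#' predictions are also available.
#'
#' @param seqset an [m6a_seqset()].
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment (default 1).
#' @param params encoder parameters ([encoder_params()]).
#' @param selection `NULL` to skip feature selection, otherwise a list with
#'   `alpha` and `beta` (default `alpha = 0.05`, `beta = 0.5`).
#' @param config the [dnn_config()] to train per fold.
#' @param folds optional precomputed [stratified_kfold()] assignment
#'   (overrides `k`/`seed`).
#' @param fold_safe refit propensity matrices per training fold (default
#'   `TRUE`).  `FALSE` reproduces the optimistic whole-dataset protocol and
#'   exists only for comparison.
#' @param threshold classification threshold (default 0.5).
#' @return an `m6aCv` object: `per_fold` (list of [compute_metrics()]
#'   reports), `mean` (fold-averaged report), `pooled` (metrics on pooled
#'   predictions), `predictions` (data frame id/label/fold/score) and
#'   `folds`.
#' @export
cross_validate <- function(seqset, k = 5L, seed = 1L,
                           params = encoder_params(),
                           selection = list(alpha = 0.05, beta = 0.5),
                           config = dnn_config(), folds = NULL,
                           fold_safe = TRUE, threshold = 0.5) {
  stopifnot(inherits(seqset, "m6aSeqSet"))
  y <- seqset$labels
  if (is.null(folds)) folds <- stratified_kfold(y, k = k, seed = seed)
  stopifnot(inherits(folds, "m6aFolds"))
  static <- encode_static(seqset, params)
  if (!fold_safe) {
    p1_all <- fit_propensity(seqset, 1L)
    p2_all <- fit_propensity(seqset, 2L)
  }
  per_fold <- vector("list", folds$k)
  pred <- data.frame(id = seqset$ids, label = y, fold = folds$fold,
                     score = NA_real_)
  for (f in seq_len(folds$k)) {
    test_idx <- which(folds$fold == f)
    train_idx <- which(folds$fold != f)
    train_set <- seqset[train_idx]
    res <- tryCatch({
      if (fold_safe) {
        p1 <- fit_propensity(train_set, 1L)
        p2 <- fit_propensity(train_set, 2L)
      } else {
        p1 <- p1_all
        p2 <- p2_all
      }
      psnp <- encode_psnp(seqset, p1)
      psdp <- encode_psdp(seqset, p2)
      X <- fuse(c(static, list(psnp, psdp)))
      Xtr <- X[train_idx, , drop = FALSE]
      Xte <- X[test_idx, , drop = FALSE]
      if (!is.null(selection)) {
        sel <- fit_elastic_net(Xtr, y[train_idx], alpha = selection$alpha,
                               beta = selection$beta)
        if (length(sel$selected) == 0L) {
          warning(sprintf(
            "fold %d: selection retained no features; scoring at chance", f))
          list(scores = rep(0.5, length(test_idx)))
        } else {
          Xtr <- apply_selection(Xtr, sel)
          Xte <- apply_selection(Xte, sel)
          net <- train_dnn(build_dnn(config, ncol(Xtr)), Xtr, y[train_idx])
          list(scores = predict_proba(net, Xte))
        }
      } else {
        net <- train_dnn(build_dnn(config, ncol(Xtr)), Xtr, y[train_idx])
        list(scores = predict_proba(net, Xte))
      }
    }, error = function(e)
      stop(sprintf("fold %d: %s", f, conditionMessage(e)), call. = FALSE))
    pred$score[test_idx] <- res$scores
    per_fold[[f]] <- compute_metrics(y[test_idx], res$scores, threshold)
  }
  structure(list(per_fold = per_fold,
                 mean = mean_metrics(per_fold),
                 pooled = compute_metrics(pred$label, pred$score, threshold),
                 predictions = pred, folds = folds),
            class = "m6aCv")
}

# BE, KSNPF, ENAC, NCP, PseDNC, TNC in canonical fusion order (PSNP/PSDP
# are appended per fold).
encode_static <- function(seqset, params) {
  list(encode_be(seqset),
       encode_ksnpf(seqset, k_max = params$k_max),
       encode_enac(seqset, window = params$enac_window),
       encode_ncp(seqset),
       encode_psednc(seqset, lambda = params$lambda, w = params$w),
       encode_tnc(seqset))
}

mean_metrics <- function(reports) {
  agg <- function(field) mean(vapply(reports, `[[`, numeric(1), field))
  tot <- function(field) sum(vapply(reports, `[[`, numeric(1), field))
  structure(list(TP = tot("TP"), TN = tot("TN"), FP = tot("FP"),
                 FN = tot("FN"), Sn = agg("Sn"), Sp = agg("Sp"),
                 ACC = agg("ACC"), MCC = agg("MCC"), AUC = agg("AUC"),
                 threshold = reports[[1L]]$threshold),
            class = "m6aMetrics")
}

#' @export
print.m6aCv <- function(x, ...) {
  cat(sprintf("m6aCv: %d folds\n  fold-mean: ", length(x$per_fold)))
  print(x$mean)
  invisible(x)
}
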