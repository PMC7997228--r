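#' Hyper-parameter search-space constructors
#'
#' A search space is an ordered list of dimensions.  Numeric dimensions may
#' be searched on a log scale and quantized to a step; categorical
#' dimensions carry an explicit value set.  A dimension may be conditional
#' on the value of an earlier (parent) dimension — the tree structure that
#' gives the tree-structured Parzen estimator its name: conditional
#' dimensions contribute to the density models only for trials in which
#' they were active.
#'
#' @param name dimension name.
#' @param lower,upper numeric bounds (inclusive).
#' @param step quantization step for integer dimensions (default 1).
#' @param log search in log space (continuous dimensions).
#' @param values categorical value set.
#' @param condition `NULL`, or `list(parent = <name>, value = <value>)`:
#'   the dimension exists only when the parent dimension equals `value`.
#' @return a dimension description (`sp_int`, `sp_float`, `sp_cat`) or a
#'   `m6aSearchSpace` (`search_space`).
#' @name search_space
NULL

#' @rdname search_space
#' @export
sp_int <- function(name, lower, upper, step = 1L, condition = NULL) {
  stopifnot(upper >= lower)
  list(name = name, type = "int", lower = as.numeric(lower),
       upper = as.numeric(upper), step = as.numeric(step),
       log = FALSE, condition = condition)
}

#' @rdname search_space
#' @export
sp_float <- function(name, lower, upper, log = FALSE, condition = NULL) {
  stopifnot(upper > lower)
  list(name = name, type = "float", lower = as.numeric(lower),
       upper = as.numeric(upper), log = log, condition = condition)
}

#' @rdname search_space
#' @export
sp_cat <- function(name, values, condition = NULL) {
  if (length(values) == 0L) stop("empty categorical dimension")
  list(name = name, type = "cat", values = values, condition = condition)
}

#' @rdname search_space
#' @param ... dimensions built with `sp_int()`, `sp_float()`, `sp_cat()`.
#' @export
search_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 0L) stop("empty search space")
  names(dims) <- vapply(dims, `[[`, character(1), "name")
  structure(dims, class = "m6aSearchSpace")
}

#' Default DNN hyper-parameter search space
#'
#' The canonical mixed search space for the classifier: number of hidden
#' layers (2 or 3, with the third width conditional on `layers = 3`), layer
#' widths, seven activations, seven optimizers, learning rate (log scale),
#' seven weight initializers, dropout rate, epochs in steps of 10 and five
#' batch sizes.
#'
#' @return an `m6aSearchSpace`.
#' @export
default_search_space <- function() {
  search_space(
    sp_cat("layers", c(2L, 3L)),
    sp_int("hidden_1", 100, 800),
    sp_int("hidden_2", 50, 700),
    sp_int("hidden_3", 25, 600,
           condition = list(parent = "layers", value = 3L)),
    sp_cat("activation", DNN_ACTIVATIONS),
    sp_cat("optimizer", DNN_OPTIMIZERS),
    sp_float("learning_rate", 0.001, 0.09, log = TRUE),
    sp_cat("kernel_initializer", DNN_INITIALIZERS),
    sp_float("dropout", 0.1, 0.6),
    sp_int("epochs", 10, 100, step = 10),
    sp_int("batch_size", 40, 80, step = 10))
}

dim_active <- function(dim, config) {
  is.null(dim$condition) ||
    identical(config[[dim$condition$parent]], dim$condition$value)
}

sample_dim_prior <- function(dim, rng) {
  if (dim$type == "cat")
    return(dim$values[[rng$sample_int(length(dim$values), 1L)]])
  lo <- if (dim$log) log(dim$lower) else dim$lower
  hi <- if (dim$log) log(dim$upper) else dim$upper
  x <- rng$runif(1L, lo, hi)
  if (dim$log) x <- exp(x)
  if (dim$type == "int") x <- quantize(x, dim)
  x
}

quantize <- function(x, dim) {
  x <- round(x / dim$step) * dim$step
  x <- min(max(x, dim$lower), dim$upper)
  if (dim$step == round(dim$step)) x <- as.integer(round(x))
  x
}

sample_prior <- function(space, rng) {
  cfg <- list()
  for (dim in space)
    if (dim_active(dim, cfg))
      cfg[[dim$name]] <- sample_dim_prior(dim, rng)
  cfg
}

# --- Parzen density machinery -------------------------------------------

# Truncated-Gaussian mixture over [lo, hi] with one uniform prior
# component; bandwidths from neighbor spacing (standard TPE practice).
make_parzen <- function(obs, lo, hi) {
  range <- hi - lo
  k <- length(obs)
  if (k == 0L)
    return(list(centers = numeric(0), bw = numeric(0),
                w = 1, lo = lo, hi = hi))
  ord <- order(obs)
  srt <- obs[ord]
  gaps <- diff(c(lo, srt, hi))
  bw <- pmax(gaps[-length(gaps)], gaps[-1L])
  bw <- pmin(pmax(bw, range / min(100, max(k, 1))), range)
  bw_out <- numeric(k)
  bw_out[ord] <- bw
  list(centers = obs, bw = bw_out,
       w = rep(1 / (k + 1), k + 1L),  # last weight = uniform prior
       lo = lo, hi = hi)
}

dparzen <- function(x, pz) {
  range <- pz$hi - pz$lo
  if (length(pz$centers) == 0L) return(rep(1 / range, length(x)))
  dens <- rep(pz$w[length(pz$w)] / range, length(x))
  for (i in seq_along(pz$centers)) {
    mu <- pz$centers[i]
    s <- pz$bw[i]
    zmass <- stats::pnorm(pz$hi, mu, s) - stats::pnorm(pz$lo, mu, s)
    dens <- dens + pz$w[i] * stats::dnorm(x, mu, s) / max(zmass, 1e-12)
  }
  dens
}

rparzen <- function(n, pz, rng) {
  k <- length(pz$centers)
  if (k == 0L) return(rng$runif(n, pz$lo, pz$hi))
  comp <- rng$sample_int(k + 1L, n, replace = TRUE, prob = pz$w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (comp[i] > k) {
      out[i] <- rng$runif(1L, pz$lo, pz$hi)
    } else {
      mu <- pz$centers[comp[i]]
      s <- pz$bw[comp[i]]
      plo <- stats::pnorm(pz$lo, mu, s)
      phi <- stats::pnorm(pz$hi, mu, s)
      out[i] <- stats::qnorm(rng$runif(1L, plo, phi), mu, s)
    }
  }
  pmin(pmax(out, pz$lo), pz$hi)
}

# Laplace-smoothed categorical model.
make_cat_model <- function(obs_idx, n_values) {
  counts <- tabulate(obs_idx, nbins = n_values) + 1
  counts / sum(counts)
}

build_dim_model <- function(dim, configs) {
  vals <- lapply(configs, function(cfg)
    if (dim_active(dim, cfg)) cfg[[dim$name]] else NULL)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (dim$type == "cat") {
    idx <- vapply(vals, function(v)
      which(vapply(dim$values, identical, logical(1), v)), integer(1))
    list(type = "cat", prob = make_cat_model(idx, length(dim$values)))
  } else {
    x <- as.numeric(unlist(vals))
    if (dim$log) x <- log(x)
    lo <- if (dim$log) log(dim$lower) else dim$lower
    hi <- if (dim$log) log(dim$upper) else dim$upper
    list(type = "num", pz = make_parzen(x, lo, hi))
  }
}

sample_dim_model <- function(dim, model, rng) {
  if (model$type == "cat")
    return(dim$values[[rng$sample_int(length(dim$values), 1L,
                                      prob = model$prob)]])
  x <- rparzen(1L, model$pz, rng)
  if (dim$log) x <- exp(x)
  if (dim$type == "int") x <- quantize(x, dim)
  x
}

#' Suggest the next configuration with the tree-structured Parzen estimator
#'
#' Below the startup count the suggestion is a prior draw.  Otherwise the
#' history is split at the gamma-quantile of the observed losses into a
#' "good" and a "bad" set; per dimension a kernel (numeric) or
#' Laplace-smoothed categorical density is fitted to each set, candidates
#' are drawn from the good model `l`, and the candidate maximizing
#' `l(x)/g(x)` — equivalent to maximizing expected improvement — is
#' returned.
#'
#' @param history list of trials, each `list(config = <named list>,
#'   loss = <numeric>)`.
#' @param space an `m6aSearchSpace`.
#' @param n_candidates candidates drawn from the good model (default 24).
#' @param rng_seed integer seed for this suggestion.
#' @param gamma quantile defining the good set (default 0.25).
#' @param n_startup prior draws before the model kicks in (default 10).
#' @return a configuration (named list) inside the declared domains.
#' @export
tpe_suggest <- function(history, space, n_candidates = 24L, rng_seed = 1L,
                        gamma = 0.25, n_startup = 10L) {
  stopifnot(inherits(space, "m6aSearchSpace"))
  rng <- local_rng(rng_seed)
  n <- length(history)
  if (n < n_startup) return(sample_prior(space, rng))
  losses <- vapply(history, `[[`, numeric(1), "loss")
  n_good <- max(1L, ceiling(gamma * n))
  ord <- order(losses)            # ties broken by trial order
  good <- lapply(history[ord[seq_len(n_good)]], `[[`, "config")
  bad <- lapply(history[ord[-seq_len(n_good)]], `[[`, "config")
  l_models <- lapply(space, build_dim_model, configs = good)
  g_models <- lapply(space, build_dim_model, configs = bad)
  cands <- vector("list", n_candidates)
  for (ci in seq_len(n_candidates)) {
    cfg <- list()
    for (dim in space)
      if (dim_active(dim, cfg))
        cfg[[dim$name]] <- sample_dim_model(dim, l_models[[dim$name]], rng)
    cands[[ci]] <- cfg
  }
  # score log l(x) - log g(x), vectorized per dimension over candidates
  scores <- numeric(n_candidates)
  for (dim in space) {
    active <- vapply(cands, function(cfg) !is.null(cfg[[dim$name]]),
                     logical(1))
    if (!any(active)) next
    vals <- lapply(cands[active], `[[`, dim$name)
    scores[active] <- scores[active] +
      log_dens_vec(dim, l_models[[dim$name]], vals) -
      log_dens_vec(dim, g_models[[dim$name]], vals)
  }
  cands[[which.max(scores)]]
}

log_dens_vec <- function(dim, model, vals) {
  if (model$type == "cat") {
    idx <- vapply(vals, function(v)
      which(vapply(dim$values, identical, logical(1), v)), integer(1))
    return(log(model$prob[idx]))
  }
  x <- as.numeric(unlist(vals))
  if (dim$log) x <- log(x)
  log(pmax(dparzen(x, model$pz), 1e-300))
}

#' Sequential model-based optimization with TPE
#'
#' Evaluates `n_trials` suggested configurations and returns the best
#' observed one (not the last).  An objective error is recorded as a failed
#' trial with infinite loss and the optimization continues.  Identical seed
#' and a deterministic objective give an identical history.
#'
#' @param objective `function(config) -> scalar loss` (to minimize; for the
#'   classifier, `1 - mean CV accuracy`).
#' @param space an `m6aSearchSpace` (default [default_search_space()]).
#' @param n_trials trial budget (default 100).
#' @param seed integer master seed.
#' @param gamma,n_startup,n_candidates TPE controls (see [tpe_suggest()]).
#' @param log_file optional path: trials are appended as JSON lines
#'   (configuration, loss, status).
#' @param verbose print per-trial progress.
#' @return list with `best_config`, `best_loss` and `history`.
#' @export
tpe_optimize <- function(objective, space = default_search_space(),
                         n_trials = 100L, seed = 1L, gamma = 0.25,
                         n_startup = 10L, n_candidates = 24L,
                         log_file = NULL, verbose = FALSE) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  history <- vector("list", 0L)
  for (tr in seq_len(n_trials)) {
    trial_seed <- as.integer((as.numeric(seed) * 10007 + tr) %%
                               .Machine$integer.max)
    cfg <- tpe_suggest(history, space, n_candidates = n_candidates,
                       rng_seed = trial_seed, gamma = gamma,
                       n_startup = n_startup)
    res <- tryCatch(list(loss = objective(cfg), status = "ok"),
                    error = function(e)
                      list(loss = Inf, status = conditionMessage(e)))
    if (!is.finite(res$loss) && res$status == "ok")
      res$status <- "non-finite loss"
    history[[tr]] <- list(config = cfg, loss = res$loss,
                          status = res$status)
    if (!is.null(log_file))
      cat(jsonlite::toJSON(list(trial = tr, config = cfg, loss = res$loss,
                                status = res$status),
                           auto_unbox = TRUE, digits = NA), "\n",
          file = log_file, append = TRUE)
    if (verbose)
      message(sprintf("trial %d/%d: loss %.5f", tr, n_trials, res$loss))
  }
  losses <- vapply(history, `[[`, numeric(1), "loss")
  best <- which.min(losses)
  list(best_config = history[[best]]$config, best_loss = losses[best],
       history = history)
}

#' Random-search baseline at equal budget
#'
#' Draws `n_trials` configurations from the prior; the comparison baseline
#' for [tpe_optimize()].
#'
#' @inheritParams tpe_optimize
#' @return list with `best_config`, `best_loss` and `history`.
#' @export
random_search <- function(objective, space = default_search_space(),
                          n_trials = 100L, seed = 1L) {
  rng <- local_rng(seed)
  history <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    cfg <- sample_prior(space, rng)
    loss <- tryCatch(objective(cfg), error = function(e) Inf)
    history[[tr]] <- list(config = cfg, loss = loss, status = "ok")
  }
  losses <- vapply(history, `[[`, numeric(1), "loss")
  best <- which.min(losses)
  list(best_config = history[[best]]$config, best_loss = losses[best],
       history = history)
}
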