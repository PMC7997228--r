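#' @name encoders
#' @title Sequence feature encoders
#'
#' @description Eight encoders turn a set of equal-length RNA sequences into
#' named numeric feature matrices (rows = sequences, columns = features):
#'
#' * `encode_be()` — per-position one-hot binary encoding, `4L` columns.
#' * `encode_tnc()` — tri-nucleotide composition, 64 columns summing to 1.
#' * `encode_enac()` — sliding-window mononucleotide composition,
#'   `4*(L-window+1)` columns; each window block sums to 1.
#' * `encode_ksnpf()` — K-spaced nucleotide pair frequencies for
#'   `K = 0..k_max`, `16*(k_max+1)` columns; each K layer sums to 1.
#' * `encode_ncp()` — nucleotide chemical properties (ring structure,
#'   functional group, hydrogen bonding), `3L` columns.
#' * `encode_psnp()` / `encode_psdp()` — position-specific (di)nucleotide
#'   propensities looked up from a class-conditional model fitted with
#'   [fit_propensity()]; `L` and `L-1` columns.
#' * `encode_psednc()` — pseudo dinucleotide composition, `16 + lambda`
#'   columns summing to 1.
#'
#' All encoders are deterministic.  Only PSNP/PSDP depend on labels (through
#' the fitted propensity model) and must be refitted per training fold.
#'
#' @param x an [m6a_seqset()] or character vector of equal-length RNA
#'   sequences.
NULL

tag_features <- function(m, tag, names) {
  colnames(m) <- names
  attr(m, "encoder_tags") <- rep(tag, ncol(m))
  m
}

#' Binary (one-hot) encoding
#'
#' Each base becomes four indicator bits, position-major:
#' `A -> 1000`, `C -> 0100`, `G -> 0010`, `U -> 0001`.  A 41-nt window
#' yields 164 features.
#'
#' @inheritParams encoders
#' @return numeric matrix, `4L` columns named `BE_p<j>_<base>`.
#' @export
encode_be <- function(x) {
  m <- seq_codes(x)
  L <- ncol(m)
  out <- matrix(0, nrow(m), 4L * L)
  for (j in seq_len(L))
    for (b in 1:4)
      out[, 4L * (j - 1L) + b] <- as.numeric(m[, j] == b)
  tag_features(out, "BE",
               paste0("BE_p", rep(seq_len(L), each = 4L), "_",
                      rep(RNA_BASES, L)))
}

#' Tri-nucleotide composition
#'
#' Frequency of each of the 64 overlapping trimers: count / (L - 2).
#'
#' @inheritParams encoders
#' @return numeric matrix with 64 columns named `TNC_<trimer>`; rows sum
#'   to 1.
#' @export
encode_tnc <- function(x) {
  m <- seq_codes(x)
  L <- ncol(m)
  if (L < 3L) stop("TNC requires sequences of length >= 3")
  n <- nrow(m)
  counts <- matrix(0, n, 64L)
  rows <- seq_len(n)
  for (j in seq_len(L - 2L)) {
    code <- 16L * (m[, j] - 1L) + 4L * (m[, j + 1L] - 1L) + m[, j + 2L]
    idx <- cbind(rows, code)
    counts[idx] <- counts[idx] + 1
  }
  tag_features(counts / (L - 2L), "TNC", paste0("TNC_", RNA_TRINUCS))
}

#' Enhanced nucleic acid composition
#'
#' Mononucleotide composition inside a window of fixed length sliding with
#' stride 1 from the 5' to the 3' end (no padding).  A 41-nt window with
#' `window = 5` yields `4 * 37 = 148` features.
#'
#' @inheritParams encoders
#' @param window sliding-window length (default 5).
#' @return numeric matrix, `4*(L-window+1)` columns named
#'   `ENAC_w<start>_<base>`; each 4-column block sums to 1.
#' @export
encode_enac <- function(x, window = 5L) {
  m <- seq_codes(x)
  L <- ncol(m)
  window <- as.integer(window)
  if (window < 1L || window > L) stop("window must be in [1, L]")
  n_win <- L - window + 1L
  out <- matrix(0, nrow(m), 4L * n_win)
  for (s in seq_len(n_win)) {
    block <- m[, s:(s + window - 1L), drop = FALSE]
    for (b in 1:4)
      out[, 4L * (s - 1L) + b] <- rowSums(block == b) / window
  }
  tag_features(out, "ENAC",
               paste0("ENAC_w", rep(seq_len(n_win), each = 4L), "_",
                      rep(RNA_BASES, n_win)))
}

#' K-spaced nucleotide pair frequencies
#'
#' For each spacing `K = 0..k_max` and each ordered base pair `N1 x{K} N2`
#' (the two bases separated by exactly K arbitrary bases), the count divided
#' by `L - K - 1` (the number of K-spaced pairs in the window).  With
#' `k_max = 5` a 41-nt window yields `16 * 6 = 96` features.
#'
#' @inheritParams encoders
#' @param k_max maximum spacing (default 5); requires `L >= k_max + 2`.
#' @return numeric matrix, `16*(k_max+1)` columns named
#'   `KSNPF_K<k>_<pair>`; each 16-column K layer sums to 1.
#' @export
encode_ksnpf <- function(x, k_max = 5L) {
  m <- seq_codes(x)
  L <- ncol(m)
  k_max <- as.integer(k_max)
  if (k_max < 0L || L < k_max + 2L)
    stop("k_max must satisfy 0 <= k_max <= L - 2")
  n <- nrow(m)
  out <- matrix(0, n, 16L * (k_max + 1L))
  for (K in 0:k_max) {
    npair <- L - K - 1L
    layer <- matrix(0, n, 16L)
    rows <- seq_len(n)
    for (j in seq_len(npair)) {
      code <- 4L * (m[, j] - 1L) + m[, j + K + 1L]
      idx <- cbind(rows, code)
      layer[idx] <- layer[idx] + 1
    }
    out[, 16L * K + 1:16] <- layer / npair
  }
  tag_features(out, "KSNPF",
               paste0("KSNPF_K", rep(0:k_max, each = 16L), "_",
                      rep(RNA_DINUCS, k_max + 1L)))
}

#' Nucleotide chemical property encoding
#'
#' Each base maps to three binary chemical coordinates (ring structure,
#' functional group, hydrogen bonding): `A -> (1,1,1)`, `C -> (0,1,0)`,
#' `G -> (1,0,0)`, `U -> (0,0,1)`.  A 41-nt window yields 123 features.
#'
#' @inheritParams encoders
#' @return numeric matrix, `3L` columns named `NCP_p<j>_<prop>`.
#' @export
encode_ncp <- function(x) {
  m <- seq_codes(x)
  L <- ncol(m)
  coords <- rbind(A = c(1, 1, 1), C = c(0, 1, 0),
                  G = c(1, 0, 0), U = c(0, 0, 1))
  out <- matrix(0, nrow(m), 3L * L)
  for (j in seq_len(L))
    out[, 3L * (j - 1L) + 1:3] <- coords[m[, j], , drop = FALSE]
  tag_features(out, "NCP",
               paste0("NCP_p", rep(seq_len(L), each = 3L), "_",
                      rep(c("ring", "func", "hbond"), L)))
}

#' Fit a position-specific propensity model
#'
#' Computes, per alphabet symbol (order 1: 4 bases; order 2: 16
#' dinucleotides) and per position, the difference between its frequency in
#' the positive and in the negative class: `z[i, j] = z+[i, j] - z-[i, j]`.
#' The model is label-dependent: fit it on training data only and apply it
#' to held-out sequences via [encode_psnp()] / [encode_psdp()].
#'
#' @param trainset an [m6a_seqset()] containing both classes.
#' @param order 1 (mononucleotide, PSNP) or 2 (dinucleotide, PSDP).
#' @return an `m6aPropensity` object: list with `order`, `L` and the
#'   `4 x L` (or `16 x (L-1)`) difference matrix `Z` (each column sums to 0,
#'   entries in `[-1, 1]`).
#' @export
fit_propensity <- function(trainset, order = 1L) {
  stopifnot(inherits(trainset, "m6aSeqSet"))
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  y <- trainset$labels
  if (length(unique(y)) < 2L)
    stop("propensity fitting requires both classes in the training set")
  m <- seq_codes(trainset)
  L <- ncol(m)
  if (order == 1L) {
    sym <- m
    n_sym <- 4L
    n_posn <- L
  } else {
    sym <- 4L * (m[, -L, drop = FALSE] - 1L) + m[, -1L, drop = FALSE]
    n_sym <- 16L
    n_posn <- L - 1L
  }
  freq <- function(rows) {
    s <- sym[rows, , drop = FALSE]
    f <- matrix(0, n_sym, n_posn)
    for (j in seq_len(n_posn))
      f[, j] <- tabulate(s[, j], nbins = n_sym) / length(rows)
    f
  }
  Z <- freq(which(y == 1L)) - freq(which(y == 0L))
  rownames(Z) <- if (order == 1L) RNA_BASES else RNA_DINUCS
  structure(list(order = order, L = L, Z = Z), class = "m6aPropensity")
}

#' @export
print.m6aPropensity <- function(x, ...) {
  cat(sprintf("m6aPropensity: order %d, L = %d, |z| max = %.3f\n",
              x$order, x$L, max(abs(x$Z))))
  invisible(x)
}

#' Position-specific nucleotide propensity encoding
#'
#' Feature `j` is the propensity difference `z[i, j]` of the base observed
#' at position `j`; `L` features.
#'
#' @inheritParams encoders
#' @param model an order-1 [fit_propensity()] model with matching `L`.
#' @return numeric matrix, `L` columns named `PSNP_p<j>`.
#' @export
encode_psnp <- function(x, model) {
  stopifnot(inherits(model, "m6aPropensity"), model$order == 1L)
  m <- seq_codes(x)
  L <- ncol(m)
  if (L != model$L) stop("sequence length does not match the fitted model")
  out <- matrix(0, nrow(m), L)
  for (j in seq_len(L))
    out[, j] <- model$Z[m[, j], j]
  tag_features(out, "PSNP", paste0("PSNP_p", seq_len(L)))
}

#' Position-specific dinucleotide propensity encoding
#'
#' Feature `j` is the propensity difference of the dinucleotide starting at
#' position `j`; `L - 1` features.
#'
#' @inheritParams encoders
#' @param model an order-2 [fit_propensity()] model with matching `L`.
#' @return numeric matrix, `L-1` columns named `PSDP_p<j>`.
#' @export
encode_psdp <- function(x, model) {
  stopifnot(inherits(model, "m6aPropensity"), model$order == 2L)
  m <- seq_codes(x)
  L <- ncol(m)
  if (L != model$L) stop("sequence length does not match the fitted model")
  out <- matrix(0, nrow(m), L - 1L)
  for (j in seq_len(L - 1L)) {
    code <- 4L * (m[, j] - 1L) + m[, j + 1L]
    out[, j] <- model$Z[code, j]
  }
  tag_features(out, "PSDP", paste0("PSDP_p", seq_len(L - 1L)))
}

#' RNA dinucleotide physicochemical property table
#'
#' Six structural/thermodynamic indices (Rise, Roll, Shift, Slide, Tilt,
#' Twist) for the 16 RNA dinucleotides, taken from the dinucleotide property
#' compilation commonly used for pseudo-composition encodings.  Shipped as a
#' plain-text table under `inst/extdata/`.  By convention the table is
#' standardized per index (mean 0, variance 1 over the 16 dinucleotides)
#' before use, which makes the correlation factors scale-free.
#'
#' @param standardize standardize each index row (default `TRUE`).
#' @return a `6 x 16` numeric matrix (indices x dinucleotides) with
#'   attribute `standardized`.
#' @export
rna_property_table <- function(standardize = TRUE) {
  path <- system.file("extdata", "rna_dinucleotide_properties.csv",
                      package = "m6aFuse", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  tab <- as.matrix(df)
  if (!identical(colnames(tab), RNA_DINUCS))
    stop("property table columns must be the 16 dinucleotides in order")
  if (standardize) {
    mu <- rowMeans(tab)
    sd_p <- sqrt(rowMeans((tab - mu)^2))  # population sd over 16 dinucleotides
    tab <- (tab - mu) / sd_p
  }
  attr(tab, "standardized") <- standardize
  tab
}

#' Pseudo dinucleotide composition
#'
#' Sixteen normalized (overlapping) dinucleotide-frequency terms plus
#' `lambda` tier-correlation terms.  Tier `j` averages, over all positions
#' `i`, the mean squared difference of the standardized physicochemical
#' index vectors of the dinucleotides at positions `i` and `i + j`.  The
#' weight `w` balances composition against correlation; all components are
#' jointly normalized, so the vector is non-negative and sums to 1.
#'
#' @inheritParams encoders
#' @param lambda number of correlation tiers (`1 <= lambda < L - 1`).
#' @param w weight factor in `[0, 1]` (default 0.5).
#' @param table property table from [rna_property_table()].
#' @param overlapping count overlapping dinucleotides (`L - 1` of them, the
#'   convention of the pseudo-composition lineage; default) or literal
#'   non-overlapping ones.
#' @return numeric matrix, `16 + lambda` columns named `PseDNC_f_<pair>` and
#'   `PseDNC_theta_<j>`; rows sum to 1.
#' @export
encode_psednc <- function(x, lambda = 30L, w = 0.5,
                          table = rna_property_table(),
                          overlapping = TRUE) {
  m <- seq_codes(x)
  L <- ncol(m)
  lambda <- as.integer(lambda)
  if (lambda < 1L || lambda >= L - 1L)
    stop("lambda must satisfy 1 <= lambda < L - 1")
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  if (!isTRUE(attr(table, "standardized")))
    warning("property table is not standardized; theta terms are scale-dependent")
  n <- nrow(m)
  # dinucleotide codes per position
  D <- 4L * (m[, -L, drop = FALSE] - 1L) + m[, -1L, drop = FALSE]
  # composition term
  f <- matrix(0, n, 16L)
  rows <- seq_len(n)
  if (overlapping) {
    for (j in seq_len(L - 1L)) {
      idx <- cbind(rows, D[, j])
      f[idx] <- f[idx] + 1
    }
  } else {
    for (j in seq(1L, L - 1L, by = 2L)) {
      idx <- cbind(rows, D[, j])
      f[idx] <- f[idx] + 1
    }
  }
  f <- f / rowSums(f)
  # pairwise mean squared index difference between dinucleotide types
  P <- table
  Theta16 <- matrix(0, 16L, 16L)
  for (a in 1:16)
    Theta16[a, ] <- colMeans((P[, a] - P)^2)
  theta <- matrix(0, n, lambda)
  for (j in seq_len(lambda)) {
    npos <- L - 1L - j
    acc <- numeric(n)
    for (i in seq_len(npos))
      acc <- acc + Theta16[cbind(D[, i], D[, i + j])]
    theta[, j] <- acc / npos
  }
  denom <- 1 + w * rowSums(theta)   # composition terms already sum to 1
  out <- cbind(f / denom, w * theta / denom)
  tag_features(out, "PseDNC",
               c(paste0("PseDNC_f_", RNA_DINUCS),
                 paste0("PseDNC_theta_", seq_len(lambda))))
}

#' Fuse encoder outputs into one feature matrix
#'
#' Column-binds feature matrices produced by the encoders, preserving
#' feature names and per-column encoder tags.  The canonical pipeline order
#' is BE, KSNPF, ENAC, NCP, PseDNC, TNC, PSNP, PSDP.
#'
#' @param features non-empty list of matrices with equal row counts.
#' @return single numeric matrix with unique column names and an
#'   `encoder_tags` attribute.
#' @export
fuse <- function(features) {
  if (!is.list(features) || length(features) == 0L)
    stop("features must be a non-empty list of matrices")
  ns <- vapply(features, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop(sprintf("sample counts differ across encoders: %s",
                 paste(ns, collapse = ", ")))
  tags <- unlist(lapply(features, function(f) {
    t <- attr(f, "encoder_tags")
    if (is.null(t)) rep(NA_character_, ncol(f)) else t
  }))
  out <- do.call(cbind, features)
  if (anyDuplicated(colnames(out)))
    stop("duplicate feature names after fusion")
  if (anyNA(out)) stop("fused feature matrix contains missing values")
  attr(out, "encoder_tags") <- unname(tags)
  out
}

#' Encode the full fused feature matrix
#'
#' Runs all eight encoders with the given parameters and fuses them in the
#' canonical order.  Propensity models (label-dependent) must be supplied
#' explicitly; fit them on training data only.
#'
#' @inheritParams encoders
#' @param params list of encoder parameters: `k_max`, `enac_window`,
#'   `lambda`, `w` (see [encoder_params()]).
#' @param psnp_model,psdp_model propensity models from [fit_propensity()].
#' @return fused numeric feature matrix (722 columns for L = 41 with the
#'   default parameters).
#' @export
encode_all <- function(x, params = encoder_params(),
                       psnp_model, psdp_model) {
  fuse(list(
    encode_be(x),
    encode_ksnpf(x, k_max = params$k_max),
    encode_enac(x, window = params$enac_window),
    encode_ncp(x),
    encode_psednc(x, lambda = params$lambda, w = params$w),
    encode_tnc(x),
    encode_psnp(x, psnp_model),
    encode_psdp(x, psdp_model)))
}

#' Write a feature matrix as TSV
#'
#' Tab-separated export with a header row of feature names and an `id`
#' column from the matrix row names (if any).
#'
#' @param X a feature matrix from the encoders or [fuse()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(X, path) {
  df <- as.data.frame(X)
  if (!is.null(rownames(X))) df <- cbind(id = rownames(X), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Encoder parameter block
#'
#' @param k_max KSNPF maximum spacing (default 5).
#' @param enac_window ENAC window length (default 5).
#' @param lambda PseDNC correlation tiers (default 30).
#' @param w PseDNC weight factor (default 0.5).
#' @return a named list.
#' @export
encoder_params <- function(k_max = 5L, enac_window = 5L,
                           lambda = 30L, w = 0.5) {
  list(k_max = as.integer(k_max), enac_window = as.integer(enac_window),
       lambda = as.integer(lambda), w = w)
}
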