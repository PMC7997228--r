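# Independent brute-force oracles and fixture builders.  These deliberately
# re-derive every quantity from string operations / exhaustive enumeration,
# sharing no code with the package internals they check.

BASES <- c("A", "C", "G", "U")

random_rna <- function(n, L = 41L, seed = 1L, center_a = TRUE) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    b <- sample(BASES, L, replace = TRUE)
    if (center_a && L %% 2L == 1L) b[(L + 1L) %/% 2L] <- "A"
    paste(b, collapse = "")
  }, character(1))
  seqs
}

tiny_seqset <- function(n_per_class = 30L, seed = 5L, L = 41L,
                        motif_strength = 0.8) {
  generate_synthetic(synthetic_config(n_pos = n_per_class,
                                      n_neg = n_per_class, L = L,
                                      motif_strength = motif_strength,
                                      seed = seed))
}

# k-mer frequencies by literal substring extraction
oracle_tnc <- function(seq) {
  L <- nchar(seq)
  kmers <- vapply(seq_len(L - 2L), function(i) substr(seq, i, i + 2L),
                  character(1))
  all3 <- apply(expand.grid(BASES, BASES, BASES)[, 3:1], 1L, paste,
                collapse = "")
  counts <- vapply(sort(all3), function(k) sum(kmers == k), numeric(1))
  counts / (L - 2L)
}

oracle_enac <- function(seq, window = 5L) {
  L <- nchar(seq)
  out <- numeric(0)
  for (s in seq_len(L - window + 1L)) {
    win <- strsplit(substr(seq, s, s + window - 1L), "")[[1]]
    out <- c(out, vapply(BASES, function(b) sum(win == b) / window,
                         numeric(1)))
  }
  unname(out)
}

oracle_ksnpf <- function(seq, k_max = 5L) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(0)
  for (K in 0:k_max) {
    pairs <- paste0(ch[seq_len(L - K - 1L)], ch[seq_len(L - K - 1L) + K + 1L])
    all2 <- paste0(rep(BASES, each = 4L), rep(BASES, 4L))
    out <- c(out, vapply(all2, function(p) sum(pairs == p) / (L - K - 1L),
                         numeric(1)))
  }
  unname(out)
}

# confusion metrics by direct enumeration
oracle_metrics <- function(y, s, thr = 0.5) {
  pred <- ifelse(s >= thr, 1L, 0L)
  TP <- sum(y == 1 & pred == 1); TN <- sum(y == 0 & pred == 0)
  FP <- sum(y == 0 & pred == 1); FN <- sum(y == 1 & pred == 0)
  den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / den
  # AUC: all positive/negative pairs, ties half
  pos <- s[y == 1]; neg <- s[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       Sn = TP / (TP + FN), Sp = TN / (TN + FP),
       ACC = (TP + TN) / length(y), MCC = mcc, AUC = mean(cmp))
}

write_fasta_lines <- function(seqs, ids, path, wrap = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    if (is.null(wrap)) writeLines(s, con)
    else writeLines(substring(s, seq(1, nchar(s), wrap),
                              pmin(seq(1, nchar(s), wrap) + wrap - 1,
                                   nchar(s))), con)
  }
  path
}
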