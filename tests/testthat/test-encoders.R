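test_that("binary encoding matches the documented bit layout", {
  # 'GGAUUCGA' column layout: G,G,A,U,U,C,G,A position-major one-hot
  v <- as.numeric(encode_be("GGAUUCGA"))
  expected <- c(0,0,1,0, 0,0,1,0, 1,0,0,0, 0,0,0,1,
                0,0,0,1, 0,1,0,0, 0,0,1,0, 1,0,0,0)
  expect_equal(v, expected)
  be41 <- encode_be(random_rna(1, 41, seed = 4))
  expect_equal(ncol(be41), 164L)
  expect_equal(sum(be41), 41)  # one-hot: exactly L ones
})

test_that("TNC matches hand counts and sums to one", {
  v <- encode_tnc("AAAA")
  expect_equal(unname(v[1, "TNC_AAA"]), 1.0)
  expect_equal(sum(v), 1)
  v2 <- encode_tnc("ACGU")
  expect_equal(unname(v2[1, c("TNC_ACG", "TNC_CGU")]), c(0.5, 0.5))
  expect_equal(sum(v2 != 0), 2L)
  expect_equal(ncol(encode_tnc(random_rna(1, 41, seed = 1))), 64L)
  expect_error(encode_tnc("AC"), "length")
})

test_that("ENAC matches hand counts per window", {
  v <- encode_enac("ACGUA", window = 5)
  expect_equal(as.numeric(v), c(0.4, 0.2, 0.2, 0.2))
  allA <- encode_enac(strrep("A", 41))
  expect_true(all(allA[, seq(1, 148, by = 4)] == 1))
  expect_equal(ncol(allA), 148L)
  expect_error(encode_enac("ACGUA", window = 6), "window")
})

test_that("KSNPF matches hand counts with the L-K-1 denominator", {
  v <- encode_ksnpf("ACA", k_max = 1)
  k0 <- v[1, 1:16]
  expect_equal(unname(k0[c("KSNPF_K0_AC", "KSNPF_K0_CA")]), c(0.5, 0.5))
  expect_equal(sum(k0), 1)
  k1 <- v[1, 17:32]
  expect_equal(unname(k1["KSNPF_K1_AA"]), 1.0)
  expect_equal(ncol(encode_ksnpf(random_rna(1, 41, seed = 2), 5)), 96L)
  expect_error(encode_ksnpf("ACA", k_max = 2), "k_max")
})

test_that("NCP uses the chemical-property coordinates", {
  expect_equal(as.numeric(encode_ncp("A")), c(1, 1, 1))
  expect_equal(as.numeric(encode_ncp("CGU")),
               c(0, 1, 0, 1, 0, 0, 0, 0, 1))
  expect_equal(ncol(encode_ncp(random_rna(1, 41, seed = 3))), 123L)
})

test_that("count-based encoders equal brute-force enumeration", {
  seqs <- random_rna(200, 41, seed = 10)
  tnc <- encode_tnc(seqs)
  enac <- encode_enac(seqs)
  ks <- encode_ksnpf(seqs, 5)
  for (i in c(1, 57, 200)) {
    expect_equal(as.numeric(tnc[i, ]), unname(oracle_tnc(seqs[i])))
    expect_equal(as.numeric(enac[i, ]), oracle_enac(seqs[i]))
    expect_equal(as.numeric(ks[i, ]), oracle_ksnpf(seqs[i]))
  }
})

test_that("propensity models difference class frequencies position-wise", {
  # positives all A at position 2, negatives never A there
  pos <- c("AAG", "CAG", "GAU")
  neg <- c("ACG", "CGU", "GUU")
  s <- m6a_seqset(c(pos, neg), rep(c(1, 0), each = 3), check_center = FALSE)
  m1 <- fit_propensity(s, 1)
  expect_equal(unname(m1$Z["A", 2]), 1)
  expect_true(all(abs(colSums(m1$Z)) < 1e-12))
  expect_true(all(m1$Z >= -1 & m1$Z <= 1))
  # identical classes give an all-zero matrix
  s2 <- m6a_seqset(c(pos, pos), rep(c(1, 0), each = 3),
                   check_center = FALSE)
  expect_true(all(fit_propensity(s2, 1)$Z == 0))
  expect_true(all(fit_propensity(s2, 2)$Z == 0))
  m2 <- fit_propensity(s, 2)
  expect_equal(dim(m2$Z), c(16L, 2L))
  expect_true(all(abs(colSums(m2$Z)) < 1e-12))
  expect_error(fit_propensity(s[1:3], 1), "both classes")
})

test_that("PSNP/PSDP encode by direct matrix lookup", {
  Z <- matrix(0, 4, 2, dimnames = list(c("A", "C", "G", "U"), NULL))
  Z["A", 1] <- 0.3
  Z["C", 2] <- -0.1
  model <- structure(list(order = 1L, L = 2L, Z = Z),
                     class = "m6aPropensity")
  expect_equal(as.numeric(encode_psnp("AC", model)), c(0.3, -0.1))
  Z2 <- matrix(0, 16, 2, dimnames = list(RNA_DINUCS <- paste0(
    rep(BASES, each = 4), rep(BASES, 4)), NULL))
  Z2["AC", 1] <- 0.2
  Z2["CG", 2] <- -0.4
  model2 <- structure(list(order = 2L, L = 3L, Z = Z2),
                      class = "m6aPropensity")
  expect_equal(as.numeric(encode_psdp("ACG", model2)), c(0.2, -0.4))
  expect_error(encode_psnp("ACGU", model), "length")
  # dimension contract on the training data scale
  s <- tiny_seqset(20, seed = 8)
  expect_equal(ncol(encode_psnp(s, fit_propensity(s, 1))), 41L)
  expect_equal(ncol(encode_psdp(s, fit_propensity(s, 2))), 40L)
})

test_that("fold-safe propensity refits shrink to zero under permuted labels", {
  mean_absz <- function(n) {
    s <- generate_synthetic(synthetic_config(n_pos = n, n_neg = n,
                                             motif_strength = 0, seed = 40))
    mean(abs(fit_propensity(s, 1)$Z))
  }
  expect_lt(mean_absz(4000), mean_absz(100))
})

test_that("PseDNC is a normalized composition + correlation vector", {
  seqs <- random_rna(50, 41, seed = 20)
  v <- encode_psednc(seqs, lambda = 30, w = 0.5)
  expect_equal(ncol(v), 46L)
  expect_true(all(v >= 0))
  expect_equal(rowSums(v), rep(1, 50), tolerance = 1e-12)
  # identical property values for all dinucleotides kill the theta terms
  flat <- matrix(1, 6, 16,
                 dimnames = list(paste0("i", 1:6),
                                 paste0(rep(BASES, each = 4),
                                        rep(BASES, 4))))
  attr(flat, "standardized") <- TRUE
  v0 <- encode_psednc(seqs[1], lambda = 5, w = 0.5, table = flat)
  expect_true(all(v0[, 17:21] == 0))
  expect_equal(sum(v0), 1)
  expect_error(encode_psednc("ACGUA", lambda = 4), "lambda")
})

test_that("property table standardizes to mean 0 variance 1 per index", {
  tab <- rna_property_table()
  expect_equal(dim(tab), c(6L, 16L))
  expect_true(all(abs(rowMeans(tab)) < 1e-9))
  expect_true(all(abs(rowMeans(tab^2) - 1) < 1e-9))
  raw <- rna_property_table(standardize = FALSE)
  expect_false(isTRUE(all.equal(rowMeans(raw), rep(0, 6))))
})

test_that("fusion concatenates in order with tags, names and checks", {
  s <- tiny_seqset(15, seed = 12)
  p1 <- fit_propensity(s, 1)
  p2 <- fit_propensity(s, 2)
  X <- encode_all(s, psnp_model = p1, psdp_model = p2)
  expect_equal(ncol(X), 164 + 96 + 148 + 123 + 46 + 64 + 41 + 40)
  tags <- attr(X, "encoder_tags")
  expect_equal(rle(tags)$values,
               c("BE", "KSNPF", "ENAC", "NCP", "PseDNC", "TNC", "PSNP",
                 "PSDP"))
  expect_false(anyDuplicated(colnames(X)) > 0)
  single <- encode_be(s)
  expect_equal(fuse(list(single)), single, ignore_attr = FALSE)
  expect_error(fuse(list(encode_be(s), encode_tnc(s[1:3]))), "sample")
  expect_error(fuse(list()), "non-empty")
})

test_that("feature matrices export to TSV with named header", {
  s <- tiny_seqset(5, seed = 14)
  X <- encode_tnc(s)
  f <- tempfile(fileext = ".tsv")
  write_features(X, f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(colnames(back), colnames(X))
  expect_equal(as.matrix(back), X, ignore_attr = TRUE)
})

test_that("encoders are deterministic and per-block normalized", {
  seqs <- random_rna(40, 41, seed = 30)
  expect_identical(encode_ksnpf(seqs), encode_ksnpf(seqs))
  enac <- encode_enac(seqs)
  for (b in seq(1, ncol(enac), by = 4))
    expect_equal(rowSums(enac[, b:(b + 3)]), rep(1, 40), tolerance = 1e-12)
  ks <- encode_ksnpf(seqs, 5)
  for (K in 0:5)
    expect_equal(rowSums(ks[, (16 * K + 1):(16 * K + 16)]), rep(1, 40),
                 tolerance = 1e-12)
  expect_equal(rowSums(encode_tnc(seqs)), rep(1, 40), tolerance = 1e-12)
})
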