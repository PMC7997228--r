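RNA_BASES <- c("A", "C", "G", "U")

# lexicographic AA, AC, ..., UU / AAA ... UUU; code of "XY" is 4*(x-1)+y
RNA_DINUCS <- paste0(rep(RNA_BASES, each = 4L), rep(RNA_BASES, 4L))

RNA_TRINUCS <- paste0(rep(RNA_BASES, each = 16L),
                      rep(rep(RNA_BASES, each = 4L), 4L),
                      rep(RNA_BASES, 16L))

#' Labeled RNA sequence set
#'
#' The universal pipeline input: equal-length RNA sequences over `{A,C,G,U}`
#' with a binary m6A label per sequence (1 = methylated positive).  DNA input
#' is accepted and normalized (upper case, `T -> U`); ambiguity codes are
#' rejected because every downstream encoder assumes a 4-letter alphabet.
#'
#' @param sequences character vector of RNA (or DNA) sequences, all the same
#'   length.
#' @param labels integer/numeric vector of 0/1 labels, one per sequence.
#' @param ids optional record identifiers; defaults to `seq_1 ... seq_n`.
#' @param check_center validate that the central base (position
#'   `ceiling(L/2)`, 1-based) is adenine.  Defaults to `TRUE` when the common
#'   length `L` is odd, `FALSE` otherwise.
#' @return an object of class `m6aSeqSet` with fields `sequences`, `labels`,
#'   `ids` and `L`.
#' @examples
#' s <- m6a_seqset(c("GGAUUCGAUCCGGAUACGAUAACGGGAUUACGGAUAACGGG",
#'                   "CCGGAUUACGGAUAACGGGAAAUUCCGGAUACCGAUAACGG"),
#'                 labels = c(1, 0))
#' s$L
#' @export
m6a_seqset <- function(sequences, labels, ids = NULL, check_center = NULL) {
  sequences <- normalize_rna(sequences)
  if (length(sequences) == 0L) stop("empty sequence set")
  lens <- nchar(sequences)
  L <- lens[1L]
  if (is.null(ids)) ids <- paste0("seq_", seq_along(sequences))
  ids <- as.character(ids)
  if (length(ids) != length(sequences))
    stop("ids and sequences differ in length")
  if (any(lens != L)) {
    bad <- ids[lens != L]
    stop(sprintf("sequences with length != %d: %s", L,
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  labels <- as.integer(labels)
  if (length(labels) != length(sequences) || any(!labels %in% c(0L, 1L)))
    stop("labels must be a 0/1 vector, one per sequence")
  obj <- structure(list(sequences = sequences, labels = labels,
                        ids = ids, L = L),
                   class = "m6aSeqSet")
  if (is.null(check_center)) check_center <- (L %% 2L == 1L)
  if (check_center) validate_center(obj) else obj
}

#' @export
print.m6aSeqSet <- function(x, ...) {
  cat(sprintf("m6aSeqSet: %d sequences of length %d (%d positive, %d negative)\n",
              length(x$sequences), x$L, sum(x$labels == 1L),
              sum(x$labels == 0L)))
  invisible(x)
}

#' @export
length.m6aSeqSet <- function(x) length(x$sequences)

# Uppercase, map DNA thymine to uracil, reject anything outside {A,C,G,U}.
normalize_rna <- function(sequences) {
  sequences <- chartr("t", "u", toupper(as.character(sequences)))
  sequences <- chartr("T", "U", sequences)
  bad <- grepl("[^ACGU]", sequences)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGU]", "", sequences[bad]), "")))
    stop(sprintf("invalid characters outside {A,C,G,U,T}: %s (in %d record(s))",
                 paste(ch, collapse = " "), sum(bad)))
  }
  sequences
}

#' Subset a sequence set
#'
#' @param x an [m6a_seqset()].
#' @param i index vector of records to keep.
#' @param ... unused.
#' @return an `m6aSeqSet` restricted to `i` (center check skipped: records
#'   were already validated on construction).
#' @export
`[.m6aSeqSet` <- function(x, i, ...) {
  structure(list(sequences = x$sequences[i], labels = x$labels[i],
                 ids = x$ids[i], L = x$L),
            class = "m6aSeqSet")
}

#' Read paired positive/negative FASTA sample files
#'
#' Positive and negative samples live in two FASTA files of equal-length
#' windows (the benchmark convention: 41-nt, adenine-centered).  Records are
#' uppercased and `T` is mapped to `U`; labels are 1 for the positive file
#' and 0 for the negative file, order positive-then-negative.
#'
#' @param pos_path,neg_path FASTA files of positive / negative samples.
#' @param expected_length required window length (default 41).
#' @param check_center validate the central adenine (default `TRUE` for odd
#'   lengths).
#' @return an [m6a_seqset()].
#' @export
read_sample_files <- function(pos_path, neg_path, expected_length = 41L,
                              check_center = NULL) {
  pos <- read_fasta_records(pos_path, expected_length)
  neg <- read_fasta_records(neg_path, expected_length)
  m6a_seqset(c(pos$sequences, neg$sequences),
             labels = c(rep(1L, length(pos$sequences)),
                        rep(0L, length(neg$sequences))),
             ids = c(pos$ids, neg$ids),
             check_center = check_center)
}

read_fasta_records <- function(path, expected_length = NULL) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0L) stop(sprintf("no FASTA records in %s", path))
  seqs <- as.character(xs)
  ids <- sub("\\s.*$", "", names(xs))
  if (!is.null(expected_length)) {
    bad <- nchar(seqs) != expected_length
    if (any(bad))
      stop(sprintf("records with length != %d in %s: %s", expected_length,
                   path, paste(utils::head(ids[bad], 5L), collapse = ", ")))
  }
  list(sequences = unname(seqs), ids = ids)
}

#' Write a sequence set to FASTA (plus optional label TSV)
#'
#' @param seqset an [m6a_seqset()].
#' @param path output FASTA path.
#' @param labels_path optional path for a two-column (id, label) TSV.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqset, path, labels_path = NULL) {
  xs <- Biostrings::BStringSet(seqset$sequences)
  names(xs) <- seqset$ids
  Biostrings::writeXStringSet(xs, filepath = path)
  if (!is.null(labels_path))
    utils::write.table(data.frame(id = seqset$ids, label = seqset$labels),
                       labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Validate the central adenine convention
#'
#' m6A windows are centered on the candidate adenosine: for odd length `L`
#' the base at position `ceiling(L/2)` (1-based; 21 for L = 41) must be `A`
#' in every record.
#'
#' @param seqset an [m6a_seqset()].
#' @return `seqset`, unchanged, if all centers are adenine.
#' @export
validate_center <- function(seqset) {
  L <- seqset$L
  if (L %% 2L == 0L) stop("center validation requires odd sequence length")
  mid <- (L + 1L) %/% 2L
  centers <- substr(seqset$sequences, mid, mid)
  bad <- centers != "A"
  if (any(bad))
    stop(sprintf("non-adenine center base at position %d in: %s", mid,
                 paste(utils::head(seqset$ids[bad], 10L), collapse = ", ")))
  seqset
}

# n x L integer matrix of base codes A=1, C=2, G=3, U=4.
seq_codes <- function(x) {
  ids <- NULL
  if (inherits(x, "m6aSeqSet")) {
    ids <- x$ids
    x <- x$sequences
  }
  x <- normalize_rna(x)
  L <- nchar(x[1L])
  if (any(nchar(x) != L)) stop("sequences differ in length")
  m <- matrix(match(unlist(strsplit(x, "", fixed = TRUE)), RNA_BASES),
              nrow = length(x), ncol = L, byrow = TRUE)
  rownames(m) <- ids
  m
}

#' Stratified k-fold assignment
#'
#' Partitions samples into `k` folds so that within each class the fold
#' sizes differ by at most one.  Samples are shuffled within class with the
#' given seed, then dealt round-robin, so the assignment is invariant to
#' input order up to fold relabeling.
#'
#' @param labels 0/1 label vector, or an [m6a_seqset()].
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return an object of class `m6aFolds`: list with `k`, `fold` (fold index
#'   1..k per sample) and `seed`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  if (inherits(labels, "m6aSeqSet")) labels <- labels$labels
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab < k))
    stop(sprintf("each class needs >= k members (class sizes: %s)",
                 paste(tab, collapse = ", ")))
  fold <- integer(length(labels))
  rng <- local_rng(seed)
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample_int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(k = k, fold = fold, seed = as.integer(seed)),
            class = "m6aFolds")
}

# Self-contained RNG stream: avoids touching the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    force(expr)
  }
  list(
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    sample_int = function(n, size = n, replace = FALSE, prob = NULL)
      with_state(sample.int(n, size, replace = replace, prob = prob)),
    with = with_state
  )
}
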