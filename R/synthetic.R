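#' Configuration for the synthetic m6A benchmark generator
#'
#' Describes a position-weight world emulating the published m6A benchmark
#' sets: balanced positive/negative classes of 41-nt adenine-centered
#' windows in which positives carry position-specific nucleotide enrichment
#' at a handful of positions flanking the central adenosine.  Negatives are
#' uniform background.  `motif_strength = 0` makes both classes draws from
#' the same distribution (the null world); `motif_strength = 1` makes the
#' enriched base deterministic in positives.
#'
#' @param n_pos,n_neg class sizes (default 1000 each, the scale of the
#'   smaller published tissue sets).
#' @param L window length; odd, center adenine (default 41).
#' @param motif_strength per-position enrichment in `[0,1]`: the designated
#'   base is drawn with probability `0.25 + motif_strength * 0.75` in
#'   positives (default 0.6).
#' @param enriched_positions 1-based positions carrying the enrichment;
#'   default the eight positions `center +/- 1..4`.
#' @param enriched_bases designated base per enriched position (recycled);
#'   default `"G"`.
#' @param seed RNG seed; identical configurations and seeds give
#'   byte-identical output.
#' @return a `m6aSynthConfig` list.
#' @export
synthetic_config <- function(n_pos = 1000L, n_neg = 1000L, L = 41L,
                             motif_strength = 0.6,
                             enriched_positions = NULL,
                             enriched_bases = "G",
                             seed = 1L) {
  L <- as.integer(L)
  if (L < 1L || L %% 2L == 0L) stop("L must be a positive odd length")
  if (n_pos < 1L || n_neg < 1L) stop("class counts must be positive")
  if (motif_strength < 0 || motif_strength > 1)
    stop("motif_strength must be in [0, 1]")
  mid <- (L + 1L) %/% 2L
  if (is.null(enriched_positions))
    enriched_positions <- setdiff(seq(mid - 4L, mid + 4L), mid)
  enriched_positions <- as.integer(enriched_positions)
  if (any(enriched_positions < 1L | enriched_positions > L))
    stop("enriched_positions out of range")
  if (mid %in% enriched_positions)
    stop("the center position is fixed to A and cannot be enriched")
  enriched_bases <- rep_len(toupper(enriched_bases),
                            length(enriched_positions))
  if (any(!enriched_bases %in% RNA_BASES))
    stop("enriched_bases must be A, C, G or U")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 L = L, motif_strength = motif_strength,
                 enriched_positions = enriched_positions,
                 enriched_bases = enriched_bases,
                 seed = as.integer(seed)),
            class = "m6aSynthConfig")
}

#' Generate a synthetic labeled sequence set
#'
#' @param config a [synthetic_config()].
#' @return an [m6a_seqset()] with `n_pos` positives followed by `n_neg`
#'   negatives, all length `L` with central adenine.
#' @examples
#' s <- generate_synthetic(synthetic_config(n_pos = 50, n_neg = 50, seed = 7))
#' table(s$labels)
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "m6aSynthConfig"))
  rng <- local_rng(config$seed)
  n <- config$n_pos + config$n_neg
  L <- config$L
  mid <- (L + 1L) %/% 2L
  # base codes drawn column-wise: uniform background everywhere
  m <- matrix(rng$sample_int(4L, n * L, replace = TRUE), nrow = n, ncol = L)
  m[, mid] <- 1L  # central adenosine
  s <- config$motif_strength
  if (s > 0 && config$n_pos > 0L) {
    p_hit <- 0.25 + s * 0.75
    for (k in seq_along(config$enriched_positions)) {
      j <- config$enriched_positions[k]
      b <- match(config$enriched_bases[k], RNA_BASES)
      others <- setdiff(1:4, b)
      draw <- rng$sample_int(4L, config$n_pos, replace = TRUE,
                             prob = c(p_hit, rep((1 - p_hit) / 3, 3L))[
                               order(c(b, others))])
      m[seq_len(config$n_pos), j] <- draw
    }
  }
  seqs <- apply(m, 1L, function(r) paste(RNA_BASES[r], collapse = ""))
  labels <- c(rep(1L, config$n_pos), rep(0L, config$n_neg))
  ids <- c(paste0("pos_", seq_len(config$n_pos)),
           paste0("neg_", seq_len(config$n_neg)))
  m6a_seqset(seqs, labels, ids, check_center = TRUE)
}
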