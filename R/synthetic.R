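# Seeded synthetic benchmark generator.
#
# Emulates the structure of the ac4C benchmark so the whole pipeline is
# testable without external downloads: fixed-width windows (default 415 nt)
# whose center carries five consecutive CXX motifs, a 1:9 site/non-site
# imbalance, and positives whose composition is tilted toward G/C runs so
# that the GGG/CGG/GGC/CCC trinucleotide frequencies are elevated. The
# enrichment is a position-wise first-order composition bias, not pasted
# motifs, so the discriminative signal is distributed along the window the
# way a global composition feature (PseEIIP) can pick up.

#' Generate a synthetic ac4C benchmark dataset
#'
#' Negatives are drawn uniformly over \{A, C, G, T\}; positives from a
#' first-order chain in which C/G carry sampling weight sqrt(enrichment)
#' after an A/T and weight `enrichment` after a C/G (so G/C runs form).
#' `enrichment = 1` makes both classes identically distributed — the null
#' control. Every window then has C forced at the five central CXX anchor
#' positions, so all generated sequences satisfy
#' [has_central_cxx_block()]. Output is a pure function of the arguments
#' (fixed Mersenne-Twister RNG).
#'
#' @param n_pos Number of positive windows (default 120).
#' @param n_neg Number of negative windows (default 1080, i.e. 1:9).
#' @param length Odd window width >= 15 (default 415).
#' @param enrichment G/C composition weight for positives, >= 1 (default 4).
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector, positives first)
#'   and `labels` (integer 0/1).
#' @export
simulate_ac4c <- function(n_pos = 120L, n_neg = 1080L, length = 415L,
                          enrichment = 4, seed = 42L) {
  if (length %% 2L == 0L || length < 15L)
    abort_validation("window length must be odd and >= 15")
  if (enrichment < 1) abort_validation("enrichment must be >= 1")
  c0 <- central_position(length)
  forced <- c0 + c(-6L, -3L, 0L, 3L, 6L)
  with_seed(seed, {
    pos <- sample_markov(n_pos, length, enrichment)
    neg <- sample_markov(n_neg, length, 1)
  })
  force_c <- function(m) { m[, forced] <- "C"; m }
  seqs <- c(
    apply(force_c(pos), 1L, paste0, collapse = ""),
    apply(force_c(neg), 1L, paste0, collapse = "")
  )
  names(seqs) <- c(sprintf("pos_%d", seq_len(n_pos)),
                   sprintf("neg_%d", seq_len(n_neg)))
  list(sequences = seqs, labels = c(rep(1L, n_pos), rep(0L, n_neg)))
}

# n sequences of width L as a character matrix, sampled position by position:
# P(base | previous in {C,G}) ~ (1, w, w, 1); otherwise (1, sqrt(w), sqrt(w), 1)
sample_markov <- function(n, L, w) {
  if (n == 0L) return(matrix(character(0), nrow = 0L, ncol = L))
  out <- matrix("", nrow = n, ncol = L)
  p_at <- c(1, sqrt(w), sqrt(w), 1); p_at <- p_at / sum(p_at)
  p_gc <- c(1, w, w, 1); p_gc <- p_gc / sum(p_gc)
  cum_at <- cumsum(p_at); cum_gc <- cumsum(p_gc)
  out[, 1] <- NUCLEOTIDES[findInterval(stats::runif(n), cum_at,
                                       rightmost.closed = TRUE) + 1L]
  for (i in seq_len(L - 1L) + 1L) {
    gc_prev <- out[, i - 1L] %in% c("C", "G")
    u <- stats::runif(n)
    idx <- integer(n)
    idx[gc_prev] <- findInterval(u[gc_prev], cum_gc, rightmost.closed = TRUE) + 1L
    idx[!gc_prev] <- findInterval(u[!gc_prev], cum_at, rightmost.closed = TRUE) + 1L
    out[, i] <- NUCLEOTIDES[pmin(idx, 4L)]
  }
  out
}

#' Write a generated dataset as CLI-ready files
#'
#' Emits `pos.fa`, `neg.fa` and `labels.tsv` (id, label) into `dir`; the
#' files round-trip through [read_fasta()] / [read_labelled()] exactly.
#'
#' @param seqs Named character vector of sequences.
#' @param labels Aligned 0/1 labels.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three written paths.
#' @export
write_fixture <- function(seqs, labels, dir) {
  if (length(seqs) != length(labels))
    abort_validation("sequences and labels must be aligned")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pos_path <- file.path(dir, "pos.fa")
  neg_path <- file.path(dir, "neg.fa")
  lab_path <- file.path(dir, "labels.tsv")
  write_fasta(seqs[labels == 1], pos_path)
  write_fasta(seqs[labels == 0], neg_path)
  utils::write.table(
    data.frame(id = names(seqs), label = as.integer(labels)),
    lab_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  c(pos = pos_path, neg = neg_path, labels = lab_path)
}
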