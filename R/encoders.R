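# Sequence feature encodings.
#
# Conventions fixed package-wide:
#  * one-hot channel order is (A, T, G, C): A=(1,0,0,0), T=(0,1,0,0),
#    G=(0,0,1,0), C=(0,0,0,1);
#  * k-mers are ordered lexicographically over (A, C, G, T) within each block;
#  * k-mer and trinucleotide frequencies are counts over the (L-k+1)
#    overlapping windows divided by the window count;
#  * nucleotide density at position i is the prefix count of the resident
#    base divided by i.

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Electron-ion interaction pseudopotential values
#'
#' Fixed per-nucleotide pseudopotentials describing the distribution of free
#' electron energies along the sequence: A = 0.1260, C = 0.1340, G = 0.0806,
#' T = 0.1335 (T stands in for U).
#'
#' @return Named numeric vector of length 4.
#' @export
eiip_values <- function() {
  c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
}

#' Supported encoding schemes
#'
#' @return Character vector of scheme names accepted by [encode_sequence()]
#'   and [encode_dataset()].
#' @export
encoding_schemes <- function() {
  c("onehot", "ncp", "nd", "ncp_nd", "kmer", "eiip", "pseeiip", "eiip_pseeiip")
}

# closed-form output dimension of a scheme for a length-L sequence
scheme_dim <- function(scheme, L) {
  switch(scheme,
    onehot = 4L * L, ncp = 3L * L, nd = L, ncp_nd = 4L * L,
    kmer = 84L, eiip = L, pseeiip = 64L, eiip_pseeiip = L + 64L,
    abort_validation(sprintf("unknown encoding scheme '%s'", scheme))
  )
}

# TRUE for schemes whose dimension depends on L (so a dataset must be
# length-uniform to share one matrix)
scheme_positionwise <- function(scheme) {
  !scheme %in% c("kmer", "pseeiip")
}

all_kmers <- function(k) {
  if (k == 1L) return(NUCLEOTIDES)
  grid <- expand.grid(rev(replicate(k, NUCLEOTIDES, simplify = FALSE)),
                      stringsAsFactors = FALSE)
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

check_min_length <- function(seq, min_len, what) {
  if (nchar(seq) < min_len)
    abort_validation(sprintf("%s requires length >= %d (got %d)",
                             what, min_len, nchar(seq)))
}

#' One-hot encoding
#'
#' Each position becomes a 4-bit indicator in channel order (A, T, G, C);
#' tuples are concatenated in sequence order, giving a 4L-vector.
#'
#' @param seq Normalized sequence (character scalar over A/C/G/T).
#' @return Numeric vector of length `4 * nchar(seq)`.
#' @export
encode_onehot <- function(seq) {
  chars <- seq_chars(seq)
  M <- diag(4)[, match(chars, c("A", "T", "G", "C")), drop = FALSE]
  as.vector(M)
}

#' Nucleotide chemical property (NCP) encoding
#'
#' Each base is a chemical-property triple (x, y, z): x = 1 for amino-group
#' bases \{A, C\}, y = 1 for purines (two-ring) \{A, G\}, z = 1 for
#' strong-hydrogen-bond pairs \{A, T\}; so A=(1,1,1), C=(1,0,0), G=(0,1,0),
#' T=(0,0,1). Triples are concatenated in order, giving a 3L-vector.
#'
#' @inheritParams encode_onehot
#' @return Numeric vector of length `3 * nchar(seq)`.
#' @export
encode_ncp <- function(seq) {
  chars <- seq_chars(seq)
  ncp_table <- cbind(A = c(1, 1, 1), C = c(1, 0, 0), G = c(0, 1, 0), T = c(0, 0, 1))
  as.vector(ncp_table[, match(chars, NUCLEOTIDES), drop = FALSE])
}

#' Nucleotide density (ND) encoding
#'
#' Position i carries the prefix density of its own base: the number of
#' occurrences of the base at position i within positions 1..i, divided by i.
#' This couples composition with location, so the same base contributes
#' different values at different positions.
#'
#' @inheritParams encode_onehot
#' @return Numeric vector of length `nchar(seq)`.
#' @export
encode_nd <- function(seq) {
  chars <- seq_chars(seq)
  L <- length(chars)
  prefix <- vapply(NUCLEOTIDES, function(n) cumsum(chars == n), numeric(L))
  if (L == 1L) prefix <- matrix(prefix, nrow = 1L, dimnames = list(NULL, NUCLEOTIDES))
  prefix[cbind(seq_len(L), match(chars, NUCLEOTIDES))] / seq_len(L)
}

#' NCP + ND combined encoding
#'
#' Concatenation of [encode_ncp()] and [encode_nd()], giving a 4L-vector.
#'
#' @inheritParams encode_onehot
#' @return Numeric vector of length `4 * nchar(seq)`.
#' @export
encode_ncp_nd <- function(seq) c(encode_ncp(seq), encode_nd(seq))

# normalized frequencies of all 4^k overlapping k-mers, lexicographic order
kmer_frequencies <- function(seq, k) {
  L <- nchar(seq)
  n_win <- L - k + 1L
  windows <- substring(seq, seq_len(n_win), seq_len(n_win) + k - 1L)
  counts <- table(factor(windows, levels = all_kmers(k)))
  as.numeric(counts) / n_win
}

#' k-mer composition encoding (k = 1, 2, 3)
#'
#' Normalized frequencies of all mono-, di- and tri-nucleotides over the
#' overlapping windows of the sequence; each block is ordered
#' lexicographically over (A, C, G, T), giving 4 + 16 + 64 = 84 features.
#'
#' @inheritParams encode_onehot
#' @return Numeric vector of length 84.
#' @export
encode_kmer <- function(seq) {
  check_min_length(seq, 3L, "k-mer encoding")
  c(kmer_frequencies(seq, 1L), kmer_frequencies(seq, 2L), kmer_frequencies(seq, 3L))
}

#' EIIP encoding
#'
#' Per-position substitution of the base's electron-ion interaction
#' pseudopotential (see [eiip_values()]), giving an L-vector.
#'
#' @inheritParams encode_onehot
#' @return Numeric vector of length `nchar(seq)`.
#' @export
encode_eiip <- function(seq) {
  unname(eiip_values()[seq_chars(seq)])
}

#' PseEIIP encoding (trinucleotide pseudo-EIIP)
#'
#' For each of the 64 trinucleotides xyz (lexicographic over A, C, G, T) the
#' feature is (EIIP_x + EIIP_y + EIIP_z) * f_xyz, where f_xyz is the
#' trinucleotide's normalized frequency over the L-2 overlapping windows.
#'
#' @inheritParams encode_onehot
#' @return Numeric vector of length 64.
#' @export
encode_pseeiip <- function(seq) {
  check_min_length(seq, 3L, "PseEIIP encoding")
  tri <- all_kmers(3L)
  e <- eiip_values()
  weight <- e[substr(tri, 1, 1)] + e[substr(tri, 2, 2)] + e[substr(tri, 3, 3)]
  unname(weight) * kmer_frequencies(seq, 3L)
}

#' EIIP + PseEIIP combined encoding
#'
#' Concatenation of [encode_eiip()] and [encode_pseeiip()], giving an
#' (L + 64)-vector. This is the representation the boosted-tree classifier
#' performs best with and the package default.
#'
#' @inheritParams encode_onehot
#' @return Numeric vector of length `nchar(seq) + 64`.
#' @export
encode_eiip_pseeiip <- function(seq) c(encode_eiip(seq), encode_pseeiip(seq))

#' Encode one sequence under a named scheme
#'
#' @inheritParams encode_onehot
#' @param scheme One of [encoding_schemes()].
#' @return Numeric feature vector.
#' @export
encode_sequence <- function(seq, scheme = "eiip_pseeiip") {
  scheme <- match.arg(scheme, encoding_schemes())
  switch(scheme,
    onehot = encode_onehot(seq), ncp = encode_ncp(seq), nd = encode_nd(seq),
    ncp_nd = encode_ncp_nd(seq), kmer = encode_kmer(seq),
    eiip = encode_eiip(seq), pseeiip = encode_pseeiip(seq),
    eiip_pseeiip = encode_eiip_pseeiip(seq)
  )
}

#' Feature names for a scheme
#'
#' Deterministic human-readable names: position features are "N\{i\}"
#' (1-based) with a channel suffix where a position yields several values
#' ("N12_A" for one-hot channels, "N12_x"/"N12_y"/"N12_z" for NCP, "N12_d"
#' for the density channel inside ncp_nd); k-mer features are named by their
#' k-mer string; PseEIIP features are "EIIP_" plus the trinucleotide.
#'
#' @param scheme One of [encoding_schemes()].
#' @param L Sequence length the names are for (ignored by length-free
#'   schemes).
#' @return Character vector whose length is the scheme's dimension.
#' @export
feature_names <- function(scheme, L) {
  scheme <- match.arg(scheme, encoding_schemes())
  pos <- function(suffixes) {
    as.vector(vapply(seq_len(L), function(i) paste0("N", i, "_", suffixes),
                     character(length(suffixes))))
  }
  switch(scheme,
    onehot = pos(c("A", "T", "G", "C")),
    ncp = pos(c("x", "y", "z")),
    nd = paste0("N", seq_len(L), "_d"),
    ncp_nd = c(feature_names("ncp", L), feature_names("nd", L)),
    kmer = c(all_kmers(1L), all_kmers(2L), all_kmers(3L)),
    eiip = paste0("N", seq_len(L)),
    pseeiip = paste0("EIIP_", all_kmers(3L)),
    eiip_pseeiip = c(feature_names("eiip", L), feature_names("pseeiip", L))
  )
}

#' Encode a set of sequences into a feature matrix
#'
#' Rows follow input order and are named by sequence id; columns carry
#' [feature_names()]. Position-wise schemes require all sequences to share
#' one length.
#'
#' @param seqs Named character vector of normalized sequences.
#' @param scheme One of [encoding_schemes()].
#' @return Numeric matrix with a `"scheme"` attribute.
#' @export
encode_dataset <- function(seqs, scheme = "eiip_pseeiip") {
  scheme <- match.arg(scheme, encoding_schemes())
  lens <- nchar(seqs)
  if (length(seqs) && scheme_positionwise(scheme) && length(unique(lens)) > 1L)
    abort_validation(sprintf(
      "scheme '%s' is position-wise; sequences must share one length (saw %s)",
      scheme, paste(utils::head(unique(lens)), collapse = ", ")))
  L <- if (length(seqs)) lens[[1]] else 0L
  p <- if (length(seqs)) scheme_dim(scheme, L) else scheme_dim(scheme, 1L)
  X <- matrix(numeric(0), nrow = 0L, ncol = p)
  if (length(seqs))
    X <- t(vapply(seqs, encode_sequence, numeric(p), scheme = scheme))
  colnames(X) <- if (length(seqs)) feature_names(scheme, L) else NULL
  rownames(X) <- names(seqs)
  structure(X, scheme = scheme)
}

#' Write a feature matrix to CSV
#'
#' Header row holds feature names; the first column holds sequence ids.
#' @param X Matrix from [encode_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(id = rownames(X) %||% seq_len(nrow(X)), X,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @param scheme Optional scheme name to attach.
#' @return Numeric matrix with ids as rownames.
#' @export
read_feature_matrix <- function(path, scheme = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- df[[1]]
  if (!is.null(scheme)) attr(X, "scheme") <- scheme
  X
}
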