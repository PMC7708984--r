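#' Normalize a candidate mRNA window
#'
#' Uppercases the sequence and maps U to T so that downstream encoders operate
#' on the DNA alphabet \{A, C, G, T\}. Any other character (including IUPAC
#' ambiguity codes such as N, R, Y) is rejected: the encoders assign no value
#' to ambiguous bases, so imputation would silently fabricate features.
#'
#' @param raw Character scalar, the raw sequence (RNA or DNA, any case).
#' @param id Character scalar identifier used in error messages.
#' @return A character scalar over \{A,C,G,T\}, named by `id`.
#' @examples
#' normalize_sequence("acgu", "s1")  # "ACGT"
#' @export
normalize_sequence <- function(raw, id = "seq") {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || nchar(raw) == 0L)
    abort_validation(sprintf("sequence '%s': empty or non-character input", id))
  s <- chartr("u", "t", tolower(raw))
  s <- toupper(s)
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L) {
    abort_validation(sprintf(
      "sequence '%s': invalid character '%s' at position %d (allowed: A, C, G, T, U, any case)",
      id, substr(s, bad, bad), bad
    ))
  }
  names(s) <- id
  s
}

#' Read candidate windows from a FASTA file
#'
#' Parses a standard FASTA file (wrapped or unwrapped lines) and normalizes
#' every record through [normalize_sequence()]. An empty file yields an empty
#' vector.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of normalized sequences; names are the FASTA
#'   record ids (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    abort_validation(sprintf("FASTA file not found: %s", path))
  if (file.size(path) == 0L) return(character(0))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(character(0))
  raw <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) ids[!nzchar(ids)] <- sprintf("record_%d", which(!nzchar(ids)))
  out <- vapply(seq_along(raw), function(i) normalize_sequence(raw[[i]], ids[[i]]),
                character(1))
  names(out) <- ids
  out
}

#' Write normalized sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path; lines are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) && is.null(names(seqs)))
    names(seqs) <- sprintf("seq_%d", seq_along(seqs))
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Central position of an odd-length window
#'
#' For an odd length L the modified cytidine is taken to sit at
#' c = (L + 1) / 2 (1-based).
#' @param length Odd positive integer.
#' @return Integer position.
#' @export
central_position <- function(length) {
  if (length %% 2L == 0L)
    abort_validation("central position is defined for odd-length windows only")
  (length + 1L) %/% 2L
}

#' Test for the benchmark's central CXX block
#'
#' Benchmark windows carry five consecutive CXX motifs (C followed by any two
#' bases) at their center. With the central C assigned to the third motif, the
#' five required C positions are c-6, c-3, c, c+3, c+6 where c is the central
#' position; `offset` shifts the block (0 places the central C on motif 3,
#' -6 on motif 1).
#'
#' @param seqs Character vector of normalized sequences (equal odd length).
#' @param offset Integer shift of the block relative to the center, default 0.
#' @return Logical vector, one value per sequence.
#' @export
has_central_cxx_block <- function(seqs, offset = 0L) {
  if (length(seqs) == 0L) return(logical(0))
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    abort_validation("sequences must share one length for the central-motif check")
  if (L < 15L)
    abort_validation("central CXX block requires length >= 15")
  c0 <- central_position(L) + offset
  pos <- c0 + c(-6L, -3L, 0L, 3L, 6L)
  if (pos[1] < 1L || pos[5] > L)
    abort_validation("offset places the CXX block outside the sequence")
  out <- rep(TRUE, length(seqs))
  for (p in pos) out <- out & (substr(seqs, p, p) == "C")
  unname(out)
}

#' Check a labelled sequence set against the central-motif convention
#'
#' Dataset-construction hygiene: the benchmark applies the CXX constraint when
#' building datasets, not at prediction time, so by default violations are a
#' warning; `strict = TRUE` upgrades them to an error.
#'
#' @param seqs Named character vector of sequences.
#' @param strict Logical; error instead of warn on violations.
#' @return Invisibly, the logical vector of per-sequence results.
#' @export
check_central_motif <- function(seqs, strict = FALSE) {
  ok <- has_central_cxx_block(seqs)
  if (!all(ok)) {
    offenders <- names(seqs)[!ok] %||% which(!ok)
    msg <- sprintf("%d sequence(s) lack the central CXX block (e.g. %s)",
                   sum(!ok), paste(utils::head(offenders, 3), collapse = ", "))
    if (strict) abort_validation(msg) else warning(msg, call. = FALSE)
  }
  invisible(ok)
}

#' Read labelled sequences from paired FASTA files or a label table
#'
#' Either supply `pos` and `neg` FASTA paths (labels 1 and 0 respectively), or
#' one `fasta` plus a two-column tab-separated `labels` file (id, label in
#' \{0,1\}).
#'
#' @param pos,neg Paths to positive / negative FASTA files.
#' @param fasta Path to a single FASTA file.
#' @param labels Path to a TSV with columns id and label.
#' @return List with `sequences` (named character) and `labels` (integer 0/1).
#' @export
read_labelled <- function(pos = NULL, neg = NULL, fasta = NULL, labels = NULL) {
  if (!is.null(pos) && !is.null(neg)) {
    p <- read_fasta(pos); n <- read_fasta(neg)
    return(list(sequences = c(p, n),
                labels = c(rep(1L, length(p)), rep(0L, length(n)))))
  }
  if (!is.null(fasta) && !is.null(labels)) {
    s <- read_fasta(fasta)
    tab <- utils::read.table(labels, header = FALSE, sep = "\t",
                             col.names = c("id", "label"),
                             colClasses = c("character", "integer"))
    if (!all(names(s) %in% tab$id))
      abort_validation("label table is missing ids present in the FASTA file")
    y <- tab$label[match(names(s), tab$id)]
    if (!all(y %in% c(0L, 1L)))
      abort_validation("labels must be 0 or 1")
    return(list(sequences = s, labels = y))
  }
  abort_validation("supply either pos+neg FASTA paths or fasta+labels paths")
}

#' Convert a PACES-style dataset layout to this package's inputs
#'
#' The published ac4C benchmark distributes positive and negative sequence
#' windows as separate FASTA files (RNA or DNA alphabet). This convenience
#' converter normalizes them and writes the `pos.fa` / `neg.fa` /
#' `labels.tsv` trio the rest of the tooling consumes. It performs no
#' downloading.
#'
#' @param pos_fasta,neg_fasta Paths to the source positive / negative FASTA.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the three written paths.
#' @export
paces_import <- function(pos_fasta, neg_fasta, out_dir) {
  p <- read_fasta(pos_fasta)
  n <- read_fasta(neg_fasta)
  write_fixture(c(p, n), c(rep(1L, length(p)), rep(0L, length(n))), out_dir)
}
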