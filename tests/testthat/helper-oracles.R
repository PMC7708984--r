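# Independent brute-force oracles, deliberately naive so they share no code
# with the package's encoders and metrics.

oracle_random_seq <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

oracle_onehot <- function(seq) {
  map <- list(A = c(1, 0, 0, 0), T = c(0, 1, 0, 0),
              G = c(0, 0, 1, 0), C = c(0, 0, 0, 1))
  unlist(lapply(strsplit(seq, "")[[1]], function(ch) map[[ch]]), use.names = FALSE)
}

oracle_ncp <- function(seq) {
  out <- c()
  for (ch in strsplit(seq, "")[[1]]) {
    out <- c(out, as.numeric(ch %in% c("A", "C")), as.numeric(ch %in% c("A", "G")),
             as.numeric(ch %in% c("A", "T")))
  }
  out
}

oracle_nd <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  vapply(seq_along(chars),
         function(i) sum(chars[1:i] == chars[i]) / i, numeric(1))
}

oracle_kmer_block <- function(seq, k) {
  kmers <- sort(apply(expand.grid(replicate(k, c("A","C","G","T"),
                                            simplify = FALSE)), 1,
                      function(r) paste0(rev(r), collapse = "")))
  L <- nchar(seq)
  wins <- vapply(1:(L - k + 1), function(i) substr(seq, i, i + k - 1), character(1))
  vapply(kmers, function(km) sum(wins == km) / length(wins), numeric(1))
}

oracle_eiip <- function(seq) {
  tab <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
  unname(tab[strsplit(seq, "")[[1]]])
}

oracle_pseeiip <- function(seq) {
  tab <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
  f <- oracle_kmer_block(seq, 3)
  w <- vapply(names(f), function(km) {
    sum(tab[strsplit(km, "")[[1]]])
  }, numeric(1))
  unname(w * f)
}

# pairwise-comparison AUROC oracle: fraction of pos/neg pairs ranked
# correctly, ties count one half
oracle_auroc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# standard-formula MCC oracle from TP/TN/FP/FN
oracle_mcc <- function(n_pos, n_neg, fn, fp) {
  tp <- n_pos - fn; tn <- n_neg - fp
  den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / den
}

# small shared fixture: quick separable dataset + fast training config
quick_dataset <- function(n_pos = 25, n_neg = 75, length = 51, enrichment = 5,
                          seed = 11) {
  simulate_ac4c(n_pos, n_neg, length = length, enrichment = enrichment,
                seed = seed)
}

quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_estimators = 60, learning_rate = 0.3, min_child_weight = 1,
         gamma = 0, scale_pos_weight = 3),
    list(...))
  do.call(ac4c_config, args)
}
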