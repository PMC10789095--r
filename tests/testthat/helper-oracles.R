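# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (enumeration, pairwise counting, literal
# rule transcription) rather than calling the implementation under test.

# --- kappa oracle: brute-force enumeration over all charge arrangements ----

oracle_sigma <- function(fp, fm) {
  if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
}

oracle_delta <- function(ch) {
  L <- length(ch)
  fp <- sum(ch == 1) / L
  fm <- sum(ch == -1) / L
  sg <- oracle_sigma(fp, fm)
  out <- 0
  for (g in c(5, 6)) {
    n <- L - g + 1
    acc <- 0
    for (i in seq_len(n)) {
      w <- ch[i:(i + g - 1)]
      acc <- acc + (oracle_sigma(sum(w == 1) / g, sum(w == -1) / g) - sg)^2
    }
    out <- out + acc / n
  }
  out / 2
}

# all distinct arrangements of (np +1s, nm -1s, n0 zeros), recursively
oracle_arrangements <- function(np, nm, n0) {
  res <- list()
  rec <- function(prefix, a, b, cc) {
    if (a + b + cc == 0) {
      res[[length(res) + 1]] <<- prefix
      return(invisible())
    }
    if (a > 0) rec(c(prefix, 1), a - 1, b, cc)
    if (b > 0) rec(c(prefix, -1), a, b - 1, cc)
    if (cc > 0) rec(c(prefix, 0), a, b, cc - 1)
  }
  rec(numeric(0), np, nm, n0)
  res
}

oracle_dmax_cache <- new.env(parent = emptyenv())

oracle_kappa <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) < 6) return(-1)
  ch <- ifelse(chars %in% c("K", "R"), 1, ifelse(chars %in% c("D", "E"), -1, 0))
  np <- sum(ch == 1)
  nm <- sum(ch == -1)
  n0 <- length(ch) - np - nm
  if (np + nm == 0) return(-1)
  key <- paste(np, nm, n0)
  dmax <- oracle_dmax_cache[[key]]
  if (is.null(dmax)) {
    dmax <- max(vapply(oracle_arrangements(np, nm, n0), oracle_delta, 0))
    oracle_dmax_cache[[key]] <- dmax
  }
  if (dmax <= 0) return(-1)
  oracle_delta(ch) / dmax
}

# --- AUC oracle: exhaustive pairwise comparison ----------------------------

oracle_pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# --- SEG window-entropy oracle ---------------------------------------------

oracle_window_entropy <- function(seq, i, window = 12) {
  chars <- strsplit(seq, "")[[1]][i:(i + window - 1)]
  tab <- table(chars[chars != "X"])
  p <- as.numeric(tab) / window
  -sum(p * log2(p))
}

# --- misc helpers ----------------------------------------------------------

random_aa_seq <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

tmp_write_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
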