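# Internal helpers shared across modules.

AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_ALLOWED <- c(AA_CANONICAL, "X")
STOP_CODONS <- c("TAA", "TAG", "TGA")

abort_ps <- function(msg, class) {
  rlang::abort(msg, class = c(class, "psdosage_error"))
}

check_sequence <- function(seq, id = "<sequence>") {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq) || nchar(seq) < 1) {
    abort_ps(sprintf("record '%s': sequence must be a non-empty string", id),
             "psdosage_validation_error")
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALLOWED)
  if (length(bad) > 0) {
    abort_ps(sprintf(
      "record '%s': sequence contains non-canonical residue(s): %s",
      id, paste(bad, collapse = ", ")), "psdosage_validation_error")
  }
  invisible(chars)
}

# Derive a stream of distinct 31-bit sub-seeds from one user seed.
derive_seed <- function(seed, k) {
  val <- ((as.numeric(seed) %% 2147483647) * 48271 + k * 69621) %% 2147483647
  as.integer(val)
}

# Atomic write: render to a temp file in the same directory, then rename.
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
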