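# FASTA input/output for protein and cDNA sequences (via Biostrings).

#' Read a protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and applies the toolkit's validation
#' contract: sequences are uppercased, wrapped lines are concatenated, ids
#' (first whitespace-delimited token of the header) must be unique, and any
#' residue outside the canonical 20 letters plus `X` is rejected with an
#' error naming the offending character and record.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return Tibble with columns `id` and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) {
    abort_ps(sprintf("file not found: %s", path), "psdosage_io_error")
  }
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) {
                    abort_ps(sprintf("FASTA parse error in %s: %s", path,
                                     conditionMessage(e)),
                             "psdosage_parse_error")
                  })
  if (length(set) == 0) {
    abort_ps(sprintf("FASTA parse error: %s contains no records", path),
             "psdosage_parse_error")
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1)
  if (anyDuplicated(ids)) {
    abort_ps(sprintf("duplicate FASTA id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "psdosage_validation_error")
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) check_sequence(seqs[i], ids[i])
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write proteins to FASTA
#'
#' @param proteins Data frame with `id` and `sequence` columns.
#' @param path Output path (written atomically).
#' @param width Line-wrap width.
#' @export
write_protein_fasta <- function(proteins, path, width = 60) {
  set <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                 proteins$id))
  write_atomic(path, function(tmp) {
    Biostrings::writeXStringSet(set, tmp, width = width)
  })
}

#' Read / write cDNA FASTA
#'
#' Same tabular shape as [read_protein_fasta()] but for transcript (DNA)
#' sequences.
#'
#' @param path FASTA path.
#' @return Tibble with `id`, `sequence`.
#' @export
read_cdna_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) {
    abort_ps(sprintf("FASTA parse error: %s contains no records", path),
             "psdosage_parse_error")
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1)
  tibble::tibble(id = ids, sequence = toupper(unname(as.character(set))))
}

#' @rdname read_cdna_fasta
#' @param cdna Tibble with `id`, `sequence`.
#' @export
write_cdna_fasta <- function(cdna, path) {
  set <- Biostrings::DNAStringSet(stats::setNames(cdna$sequence, cdna$id))
  write_atomic(path, function(tmp) Biostrings::writeXStringSet(set, tmp))
}
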